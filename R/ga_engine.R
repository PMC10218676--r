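# Tabu-augmented steady-state genetic algorithm over binary SNP masks.
# Each chromosome is a 0/1 gene vector over the candidate set; its fitness
# is the adjusted R-squared of a Bayesian ridge fit on the masked training
# columns. A tabu registry caches every mask ever scored within a run, so
# re-visits cost a lookup instead of a model fit. Mutation and crossover
# rates adapt to the sources of the last few improvements, with a hard
# floor so neither operator is ever starved.

#' GA configuration
#'
#' @param K Maximum iterations (operator applications); default 5000.
#' @param S Parent-pool size; default 10.
#' @param L Inner-loop fitness-call budget per operator application;
#'   default 10.
#' @param rate_floor Minimum probability for either operator; default 0.2.
#' @param window Number of recent improvements that drive the adaptive
#'   operator rates; default 3.
#' @param runs GA repetitions whose selected sets are intersected into the
#'   consensus; default 3.
#' @param init_max_card Upper bound on the cardinality of initial masks
#'   (capped at the candidate-set size); default 20. Small initial masks
#'   keep n - p - 1 positive and let the adjusted-R-squared penalty act.
#' @param seed Integer root seed for the run (required at [run_ga()] time).
#' @return A `ga_config` list.
#' @export
ga_config <- function(K = 5000L, S = 10L, L = 10L, rate_floor = 0.2,
                      window = 3L, runs = 3L, init_max_card = 20L,
                      seed = NULL) {
  stopifnot(K >= 0, S >= 2, L >= 1, rate_floor > 0, rate_floor <= 0.5,
            window >= 1, runs >= 1, init_max_card >= 1)
  structure(list(K = as.integer(K), S = as.integer(S), L = as.integer(L),
                 rate_floor = rate_floor, window = as.integer(window),
                 runs = as.integer(runs),
                 init_max_card = as.integer(init_max_card), seed = seed),
            class = "ga_config")
}

#' Adjusted R-squared
#'
#' `1 - (1 - r2) * (n - 1) / (n - p - 1)`: the coefficient of determination
#' penalized for the number of predictors. The formula is evaluated as
#' printed and may be negative for poor fits; `n - p - 1 <= 0` yields an
#' invalid-score signal (`NA`), which the fitness layer maps to the worst
#' possible score.
#'
#' @param r2 Coefficient of determination.
#' @param n Sample count.
#' @param p Number of predictors.
#' @return Adjusted R-squared, or `NA` when the degrees of freedom vanish.
#' @export
adjusted_r2 <- function(r2, n, p) {
  if (n - p - 1 <= 0) return(NA_real_)
  1 - (1 - r2) * (n - 1) / (n - p - 1)
}

#' Create a tabu registry
#'
#' A per-run memory of every mask whose fitness has been computed, plus
#' counters: `fits` (ridge model fits), `evals` (non-cached fitness
#' evaluations, including degenerate masks scored without a fit), and
#' `hits` (cache hits).
#'
#' @return A `tabu_registry` environment.
#' @export
new_tabu <- function() {
  t <- new.env(parent = emptyenv())
  t$map <- new.env(hash = TRUE, parent = emptyenv())
  t$hits <- 0L
  t$fits <- 0L
  t$evals <- 0L
  class(t) <- "tabu_registry"
  t
}

mask_key <- function(genes) paste(genes, collapse = "")

tabu_has <- function(tabu, genes) {
  exists(mask_key(genes), envir = tabu$map, inherits = FALSE)
}

#' Number of distinct masks scored so far
#' @param tabu A [new_tabu()] registry.
#' @export
tabu_size <- function(tabu) length(ls(tabu$map, all.names = TRUE))

worst_score <- function(p = 0L) {
  list(r2 = NA_real_, adj_r2 = -Inf, p = as.integer(p), valid = FALSE)
}

#' Score a gene mask
#'
#' If the mask has been scored before in this run, the cached score is
#' returned without refitting (a tabu hit). Otherwise the Bayesian ridge
#' is fit on the masked training columns, the in-sample R-squared is
#' computed as 1 - RSS/TSS of the training response, and [adjusted_r2()]
#' applied with p = popcount of the mask. Degenerate masks (p = 0 or
#' p >= n - 1) receive a sentinel worst score and no model fit.
#'
#' @param genes 0/1 integer vector over the candidate columns of `X`.
#' @param X Training design matrix restricted to the candidate SNPs.
#' @param y Training trait vector.
#' @param tabu A [new_tabu()] registry.
#' @return A fitness score: list with `r2`, `adj_r2`, `p`, `valid`.
#' @export
fitness <- function(genes, X, y, tabu) {
  if (length(genes) != ncol(X)) stop_gaqtl("gene vector/candidate-set length mismatch")
  key <- mask_key(genes)
  if (exists(key, envir = tabu$map, inherits = FALSE)) {
    tabu$hits <- tabu$hits + 1L
    return(get(key, envir = tabu$map, inherits = FALSE))
  }
  tabu$evals <- tabu$evals + 1L
  n <- length(y)
  p <- sum(genes)
  score <- if (p == 0L || p >= n - 1L) {
    worst_score(p)
  } else {
    fit <- fit_linear_ridge(X[, genes == 1L, drop = FALSE], y)
    tabu$fits <- tabu$fits + 1L
    rss <- sum((y - predict(fit, X[, genes == 1L, drop = FALSE]))^2)
    tss <- sum((y - mean(y))^2)
    r2 <- 1 - rss / tss
    adj <- adjusted_r2(r2, n, p)
    if (is.na(adj)) worst_score(p) else list(r2 = r2, adj_r2 = adj,
                                             p = as.integer(p), valid = TRUE)
  }
  assign(key, score, envir = tabu$map)
  score
}

# a beats b: validity first, then adjusted R2, ties toward fewer features
# (the secondary objective).
score_better <- function(a, b) {
  if (!a$valid) return(FALSE)
  if (!b$valid) return(TRUE)
  if (a$adj_r2 != b$adj_r2) return(a$adj_r2 > b$adj_r2)
  a$p < b$p
}

#' Initial parent pool
#'
#' Draws `S` masks, each with cardinality sampled uniformly in
#' `[1, min(init_max_card, m)]` and uniformly placed set bits; distinctness
#' is attempted, and duplicates are allowed with a warning when the search
#' space is too small. All masks are scored on creation.
#'
#' @param m Candidate-set size (gene-vector length).
#' @param cfg A [ga_config()].
#' @param fitness_fn Function taking a gene vector and returning a score.
#' @return List of chromosomes: `list(genes =, score =)`.
#' @export
init_population <- function(m, cfg, fitness_fn) {
  max_card <- min(cfg$init_max_card, m)
  seen <- character(0)
  pool <- vector("list", cfg$S)
  dup_warned <- FALSE
  for (i in seq_len(cfg$S)) {
    genes <- NULL
    for (attempt in seq_len(50L)) {
      card <- sample.int(max_card, 1L)
      g <- integer(m)
      g[sample.int(m, card)] <- 1L
      if (!(mask_key(g) %in% seen)) {
        genes <- g
        break
      }
      genes <- g  # keep last draw; may be a duplicate
    }
    if (mask_key(genes) %in% seen && !dup_warned) {
      warning("candidate space too small for ", cfg$S,
              " distinct initial masks; duplicates allowed")
      dup_warned <- TRUE
    }
    seen <- c(seen, mask_key(genes))
    pool[[i]] <- list(genes = genes, score = fitness_fn(genes))
  }
  pool
}

#' Crossover probability from the recent-improvement history
#'
#' `P(crossover) = clamp(c / window, rate_floor, 1 - rate_floor)` where `c`
#' counts crossover entries among the last `window` improvements; an empty
#' history gives the uninformative 0.5.
#'
#' @param history Character vector of recent improvement sources, values
#'   in `c("crossover", "mutation")`, most recent last, length <= window.
#' @param window Improvement-memory length.
#' @param rate_floor Minimum probability of either operator.
#' @return Probability of choosing crossover.
#' @export
operator_probability <- function(history, window = 3L, rate_floor = 0.2) {
  if (length(history) == 0L) return(0.5)
  clamp(sum(history == "crossover") / window, rate_floor, 1 - rate_floor)
}

#' Draw the next operator
#'
#' @inheritParams operator_probability
#' @return `"crossover"` or `"mutation"`.
#' @export
choose_operator <- function(history, window = 3L, rate_floor = 0.2) {
  p_cross <- operator_probability(history, window, rate_floor)
  if (stats::runif(1L) < p_cross) "crossover" else "mutation"
}

#' Mutate a chromosome
#'
#' Generates up to `L` variants of the parent, each differing in 1-3
#' uniformly chosen gene positions (the flip count itself uniform).
#' Variants already in the tabu registry are skipped without consuming a
#' model fit; the best-scoring non-tabu variant is returned (it may be
#' worse than the parent — pool replacement decides acceptance). If every
#' variant was tabu, the parent is returned with `noop = TRUE`.
#'
#' @param chrom Chromosome: `list(genes =, score =)`.
#' @param fitness_fn Scoring function over gene vectors.
#' @param L Fitness-call budget.
#' @param tabu A [new_tabu()] registry.
#' @return Chromosome with an added `noop` flag.
#' @export
mutate <- function(chrom, fitness_fn, L, tabu) {
  m <- length(chrom$genes)
  best <- NULL
  for (i in seq_len(L)) {
    k <- sample.int(min(3L, m), 1L)
    pos <- sample.int(m, k)
    v <- chrom$genes
    v[pos] <- 1L - v[pos]
    if (tabu_has(tabu, v)) next
    s <- fitness_fn(v)
    if (is.null(best) || score_better(s, best$score)) {
      best <- list(genes = v, score = s)
    }
  }
  if (is.null(best)) {
    c(chrom, list(noop = TRUE))
  } else {
    c(best, list(noop = FALSE))
  }
}

#' Cross two chromosomes
#'
#' Generates up to `L` children by uniform per-gene inheritance (each gene
#' copied from either parent with probability 1/2), skipping tabu children
#' without a model fit, and returns the best non-tabu child. Identical
#' parents (or an all-tabu batch) return the first parent with
#' `noop = TRUE`.
#'
#' @param gp,gd Parent chromosomes: `list(genes =, score =)`.
#' @inheritParams mutate
#' @return Child chromosome with an added `noop` flag.
#' @export
crossover <- function(gp, gd, fitness_fn, L, tabu) {
  m <- length(gp$genes)
  if (length(gd$genes) != m) stop_gaqtl("parent gene lengths differ")
  if (all(gp$genes == gd$genes)) return(c(gp, list(noop = TRUE)))
  best <- NULL
  for (i in seq_len(L)) {
    from_p <- stats::runif(m) < 0.5
    v <- ifelse(from_p, gp$genes, gd$genes)
    if (tabu_has(tabu, v)) next
    s <- fitness_fn(v)
    if (is.null(best) || score_better(s, best$score)) {
      best <- list(genes = v, score = s)
    }
  }
  if (is.null(best)) {
    c(gp, list(noop = TRUE))
  } else {
    c(best, list(noop = FALSE))
  }
}

#' Run the genetic algorithm once
#'
#' Steady-state loop: each iteration visits one pool member (round-robin),
#' applies a single operator chosen from the adaptive rates (the crossover
#' partner is a distinct pool member chosen uniformly), and replaces the
#' pool's worst member when the offspring strictly improves on it (ties
#' going to fewer features); the successful operator is then recorded in
#' the improvement history. The pool's best fitness never decreases. The
#' loop exits early if a perfect adjusted R-squared is reached. Total
#' non-cached fitness evaluations are bounded by `L * K + S`.
#'
#' @param G_train Training [genotype_matrix()] or code matrix.
#' @param y_train Training trait vector.
#' @param candidates A `candidate_set` from [preprocess_candidates()], or
#'   `NULL` to use every column of `G_train`.
#' @param cfg A [ga_config()]; `cfg$seed` must be set.
#' @return A `selection_result`: best mask, selected locus ids, score,
#'   per-iteration best-fitness trace, evaluation counters, and the seed.
#' @export
run_ga <- function(G_train, y_train, candidates = NULL, cfg = ga_config()) {
  codes <- if (inherits(G_train, "genotype_matrix")) G_train$codes else as.matrix(G_train)
  if (is.null(candidates)) {
    loci <- colnames(codes) %||% paste0("chr1_", 1000L * seq_len(ncol(codes)))
    candidates <- structure(list(indices = seq_len(ncol(codes)),
                                 scores = rep(NA_real_, ncol(codes)),
                                 alpha = 1, loci = loci),
                            class = "candidate_set")
  }
  if (length(candidates$indices) == 0L) stop_gaqtl("empty candidate set")
  if (is.null(cfg$seed)) stop_gaqtl("cfg$seed is required for a GA run")
  X <- codes[, candidates$indices, drop = FALSE]
  y <- y_train
  m <- ncol(X)

  with_seed(cfg$seed, {
    tabu <- new_tabu()
    fitness_fn <- function(genes) fitness(genes, X, y, tabu)
    pool <- init_population(m, cfg, fitness_fn)
    history <- character(0)
    trace <- numeric(0)
    pool_best <- function() {
      b <- 1L
      for (i in seq_along(pool)) {
        if (score_better(pool[[i]]$score, pool[[b]]$score)) b <- i
      }
      b
    }
    pool_worst <- function() {
      w <- 1L
      for (i in seq_along(pool)) {
        if (score_better(pool[[w]]$score, pool[[i]]$score)) w <- i
      }
      w
    }
    iterations <- 0L
    for (it in seq_len(cfg$K)) {
      iterations <- it
      member <- pool[[(it - 1L) %% cfg$S + 1L]]
      op <- choose_operator(history, cfg$window, cfg$rate_floor)
      child <- if (op == "crossover") {
        others <- setdiff(seq_len(cfg$S), (it - 1L) %% cfg$S + 1L)
        partner <- pool[[others[sample.int(length(others), 1L)]]]
        crossover(member, partner, fitness_fn, cfg$L, tabu)
      } else {
        mutate(member, fitness_fn, cfg$L, tabu)
      }
      if (!child$noop) {
        w <- pool_worst()
        if (score_better(child$score, pool[[w]]$score)) {
          pool[[w]] <- list(genes = child$genes, score = child$score)
          history <- utils::tail(c(history, op), cfg$window)
        }
      }
      best_now <- pool[[pool_best()]]$score
      trace <- c(trace, if (best_now$valid) best_now$adj_r2 else NA_real_)
      if (best_now$valid && best_now$adj_r2 >= 1 - 1e-12) break
    }
    best <- pool[[pool_best()]]
    structure(list(
      best_mask = best$genes,
      selected_loci = candidates$loci[best$genes == 1L],
      score = best$score,
      trace = trace,
      iterations = iterations,
      fitness_calls = tabu$evals,
      model_fits = tabu$fits,
      tabu_hits = tabu$hits,
      distinct_masks = tabu_size(tabu),
      candidate_loci = candidates$loci,
      seed = cfg$seed,
      config = cfg
    ), class = "selection_result")
  })
}

#' @export
#' @method print selection_result
print.selection_result <- function(x, ...) {
  cat("selection_result: ", length(x$selected_loci), " SNPs selected, ",
      "adjusted R2 = ", signif(x$score$adj_r2, 4), " after ", x$iterations,
      " iterations (", x$fitness_calls, " fitness evaluations, ",
      x$tabu_hits, " tabu hits)\n", sep = "")
  invisible(x)
}
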