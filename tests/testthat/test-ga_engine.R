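# A small instance used across GA tests: candidate columns are the whole
# (tiny) genotype matrix, with 3 planted causal SNPs.
ga_instance <- function(n = 100, m_blocks = 8, seed = 11) {
  inst <- toy_instance(n = n, n_blocks = m_blocks, block_size = 1, rho = 0,
                       k_qtl = 3, h2 = 0.8, seed = seed)
  list(X = inst$G$codes, y = inst$y, G = inst$G, truth = inst$truth)
}

test_that("adjusted_r2 evaluates the penalized formula exactly", {
  expect_equal(adjusted_r2(1, 50, 7), 1)
  expect_equal(adjusted_r2(0, 42, 0), 0)
  expect_equal(adjusted_r2(0.5, 11, 1), 1 - 0.5 * 10 / 9, tolerance = 1e-12)
  expect_true(is.na(adjusted_r2(0.5, 5, 4)))   # n - p - 1 = 0
  expect_true(is.na(adjusted_r2(0.5, 5, 6)))   # negative dof
  # poor fits may go negative; the formula is not clipped
  expect_lt(adjusted_r2(0.01, 20, 10), 0)
})

test_that("degenerate masks get the sentinel worst score", {
  gi <- ga_instance()
  tabu <- new_tabu()
  s0 <- fitness(rep(0L, ncol(gi$X)), gi$X, gi$y, tabu)
  expect_false(s0$valid)
  expect_equal(s0$adj_r2, -Inf)
  expect_equal(tabu$fits, 0L)  # no model fit for p = 0
})

test_that("tabu caching returns identical scores without refitting", {
  gi <- ga_instance()
  tabu <- new_tabu()
  mask <- c(1L, 0L, 1L, rep(0L, ncol(gi$X) - 3))
  s1 <- fitness(mask, gi$X, gi$y, tabu)
  fits_after_first <- tabu$fits
  s2 <- fitness(mask, gi$X, gi$y, tabu)
  expect_identical(s1, s2)
  expect_equal(tabu$fits, fits_after_first)
  expect_equal(tabu$hits, 1L)
  expect_equal(tabu$evals, 1L)
})

test_that("model fits count distinct masks only", {
  gi <- ga_instance()
  tabu <- new_tabu()
  set.seed(12)
  masks <- lapply(1:30, function(i) {
    g <- integer(ncol(gi$X))
    g[sample.int(ncol(gi$X), sample(0:4, 1))] <- 1L
    g
  })
  for (g in masks) fitness(g, gi$X, gi$y, tabu)
  keys <- sapply(masks, paste, collapse = "")
  nondegen <- sapply(masks, function(g) sum(g) > 0)
  expect_equal(tabu$fits, length(unique(keys[nondegen])))
  expect_equal(tabu$evals, length(unique(keys)))
  expect_equal(tabu_size(tabu), length(unique(keys)))
})

test_that("the true-support mask outscores every single-QTL mask", {
  gi <- ga_instance(n = 500, seed = 13)
  tabu <- new_tabu()
  m <- ncol(gi$X)
  full <- integer(m)
  full[gi$truth$causal_indices] <- 1L
  s_full <- fitness(full, gi$X, gi$y, tabu)
  for (j in gi$truth$causal_indices) {
    single <- integer(m)
    single[j] <- 1L
    expect_gt(s_full$adj_r2, fitness(single, gi$X, gi$y, tabu)$adj_r2)
  }
})

test_that("initial populations are deterministic, sized, and bounded", {
  gi <- ga_instance()
  cfg <- ga_config(S = 10, seed = 1)
  draw <- function() {
    set.seed(99)
    tabu <- new_tabu()
    init_population(ncol(gi$X), cfg,
                    function(g) fitness(g, gi$X, gi$y, tabu))
  }
  p1 <- draw()
  p2 <- draw()
  expect_identical(lapply(p1, `[[`, "genes"), lapply(p2, `[[`, "genes"))
  expect_length(p1, 10L)
  cards <- sapply(p1, function(c) sum(c$genes))
  expect_true(all(cards >= 1 & cards <= min(20, ncol(gi$X))))
})

test_that("a single-SNP candidate space warns and fills with duplicates", {
  set.seed(2)
  X <- matrix(sample(c(-1, 1), 40, replace = TRUE), ncol = 1)
  y <- rnorm(40)
  tabu <- new_tabu()
  cfg <- ga_config(S = 5, seed = 1)
  set.seed(7)
  expect_warning(pool <- init_population(1L, cfg,
                                         function(g) fitness(g, X, y, tabu)),
                 "duplicates")
  expect_true(all(sapply(pool, function(c) identical(c$genes, 1L))))
})

test_that("initial cardinalities are uniform on [1, 20]", {
  set.seed(42)
  cards <- integer(0)
  fake_fit <- function(g) list(r2 = 0, adj_r2 = 0, p = sum(g), valid = TRUE)
  cfg <- ga_config(S = 10, seed = 1)
  for (i in 1:100) {
    pool <- init_population(100L, cfg, fake_fit)
    cards <- c(cards, sapply(pool, function(c) sum(c$genes)))
  }
  tab <- table(factor(cards, levels = 1:20))
  expect_gt(stats::chisq.test(tab)$p.value, 0.01)
})

test_that("mutation flips between 1 and 3 positions and leaves tabu alone", {
  gi <- ga_instance()
  m <- ncol(gi$X)
  set.seed(3)
  for (i in 1:20) {
    tabu <- new_tabu()
    fitness_fn <- function(g) fitness(g, gi$X, gi$y, tabu)
    start <- integer(m)
    start[sample.int(m, 2)] <- 1L
    chrom <- list(genes = start, score = fitness_fn(start))
    child <- mutate(chrom, fitness_fn, L = 1, tabu)
    if (!child$noop) {
      d <- sum(child$genes != start)
      expect_gte(d, 1L)
      expect_lte(d, 3L)
    }
  }
  # from the all-zero mask every variant has popcount >= 1, hence evaluable
  tabu <- new_tabu()
  fitness_fn <- function(g) fitness(g, gi$X, gi$y, tabu)
  zero <- list(genes = integer(m), score = fitness_fn(integer(m)))
  child <- mutate(zero, fitness_fn, L = 5, tabu)
  expect_false(child$noop)
  expect_gte(sum(child$genes), 1L)
})

test_that("repeated mutation finds the global optimum of a 6-bit space", {
  gi <- ga_instance(m_blocks = 6, n = 60, seed = 17)
  m <- 6L
  # exhaustive oracle over all 2^6 masks
  oracle_tabu <- new_tabu()
  best_adj <- -Inf
  for (k in 0:(2^m - 1)) {
    g <- as.integer(intToBits(k)[1:m])
    s <- fitness(g, gi$X, gi$y, oracle_tabu)
    if (s$valid && s$adj_r2 > best_adj) best_adj <- s$adj_r2
  }
  for (s in 1:10) {
    set.seed(500 + s)
    tabu <- new_tabu()
    best_seen <- -Inf
    fitness_fn <- function(g) {
      sc <- fitness(g, gi$X, gi$y, tabu)
      if (sc$valid && sc$adj_r2 > best_seen) best_seen <<- sc$adj_r2
      sc
    }
    start <- integer(m)
    start[sample.int(m, 1)] <- 1L
    current <- list(genes = start, score = fitness_fn(start))
    for (it in 1:200) {
      child <- mutate(current, fitness_fn, L = 5, tabu)
      if (!child$noop &&
          (!current$score$valid ||
           (child$score$valid && child$score$adj_r2 > current$score$adj_r2))) {
        current <- list(genes = child$genes, score = child$score)
      }
      if (best_seen >= best_adj - 1e-12) break
    }
    expect_equal(best_seen, best_adj, tolerance = 1e-12)
  }
})

test_that("crossover respects per-gene parental inheritance", {
  gi <- ga_instance(m_blocks = 4, n = 60, seed = 19)
  tabu <- new_tabu()
  fitness_fn <- function(g) fitness(g, gi$X, gi$y, tabu)
  gp <- list(genes = c(1L, 1L, 0L, 0L), score = fitness_fn(c(1L, 1L, 0L, 0L)))
  gd <- list(genes = c(1L, 0L, 1L, 0L), score = fitness_fn(c(1L, 0L, 1L, 0L)))
  set.seed(4)
  for (i in 1:20) {
    child <- crossover(gp, gd, fitness_fn, L = 3, tabu)
    expect_equal(child$genes[1], 1L)  # parents agree
    expect_equal(child$genes[4], 0L)  # parents agree
    expect_true(all(child$genes == gp$genes | child$genes == gd$genes))
  }
  same <- crossover(gp, gp, fitness_fn, L = 3, tabu)
  expect_true(same$noop)
  expect_identical(same$genes, gp$genes)
})

test_that("crossover combines single-QTL parents into multi-QTL children", {
  hits <- 0L
  for (s in 1:10) {
    gi <- ga_instance(n = 200, m_blocks = 10, seed = 600 + s)
    m <- ncol(gi$X)
    tabu <- new_tabu()
    fitness_fn <- function(g) fitness(g, gi$X, gi$y, tabu)
    mk <- function(j) {
      g <- integer(m)
      g[j] <- 1L
      list(genes = g, score = fitness_fn(g))
    }
    gp <- mk(gi$truth$causal_indices[1])
    gd <- mk(gi$truth$causal_indices[2])
    set.seed(700 + s)
    found <- FALSE
    for (it in 1:50) {
      child <- crossover(gp, gd, fitness_fn, L = 3, tabu)
      if (!child$noop && sum(child$genes[gi$truth$causal_indices]) >= 2) {
        found <- TRUE
        break
      }
    }
    if (found) hits <- hits + 1L
  }
  expect_gte(hits, 9L)
})

test_that("operator probabilities follow the clamped improvement fraction", {
  expect_equal(operator_probability(character(0)), 0.5)
  expect_equal(operator_probability(c("crossover", "crossover", "mutation")),
               2 / 3)
  expect_equal(operator_probability(rep("mutation", 3)), 0.2)  # floor
  expect_equal(operator_probability(rep("crossover", 3)), 0.8) # ceiling
  # both floors hold simultaneously for every history
  for (k in 0:3) {
    h <- c(rep("crossover", k), rep("mutation", 3 - k))
    p <- operator_probability(h)
    expect_gte(min(p, 1 - p), 0.2 - 1e-12)
  }
})

test_that("run_ga respects its contracts on a small instance", {
  gi <- ga_instance(n = 100, m_blocks = 8, seed = 23)
  cfg <- ga_config(K = 100, S = 4, L = 5, seed = 31)
  r <- run_ga(gi$X, gi$y, cfg = cfg)
  # elitist trace
  expect_true(all(diff(r$trace[!is.na(r$trace)]) >= -1e-12))
  # budget: every non-cached evaluation registered one new mask
  expect_equal(r$fitness_calls, r$distinct_masks)
  expect_lte(r$fitness_calls, cfg$L * cfg$K + cfg$S)
  expect_lte(r$model_fits, r$fitness_calls)
  # selected loci are exactly the set bits
  expect_equal(r$selected_loci,
               colnames(gi$X)[r$best_mask == 1L])
  # determinism under the seed
  r2 <- run_ga(gi$X, gi$y, cfg = cfg)
  expect_identical(r$best_mask, r2$best_mask)
  expect_identical(r$trace, r2$trace)
})

test_that("K = 0 returns the best of the initial population", {
  gi <- ga_instance(n = 80, m_blocks = 6, seed = 29)
  cfg <- ga_config(K = 0, S = 6, seed = 37)
  r <- run_ga(gi$X, gi$y, cfg = cfg)
  expect_equal(r$iterations, 0L)
  expect_lte(r$fitness_calls, 6L)
  expect_true(r$score$valid)
})
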