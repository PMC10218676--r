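# Combine repeated GA runs into a consensus set, evaluate held-out
# prediction, and measure LD concordance against reference QTL lists.
# Because the GA is stochastic, single-run selections vary; the
# intersection over runs keeps only loci that every run agrees on, and the
# intersection-over-union ratio quantifies run-to-run stability.

#' Intersect repeated GA runs into a consensus set
#'
#' @param results List of `selection_result`s over the same candidate set.
#' @param config Optional configuration echo carried into reports.
#' @return A `consensus_result`: `per_run`, `consensus_loci`
#'   (intersection of selected locus ids), `union_loci`, and `iu_ratio`
#'   (|intersection| / |union|; an empty union is defined as 1, with a
#'   warning).
#' @export
intersect_runs <- function(results, config = NULL) {
  stopifnot(length(results) >= 1L)
  lapply(results, function(r) {
    if (!inherits(r, "selection_result")) stop_gaqtl("expected selection_result objects")
  })
  cand <- results[[1L]]$candidate_loci
  for (r in results[-1L]) {
    if (!identical(r$candidate_loci, cand)) {
      stop_gaqtl("runs were performed over different candidate sets")
    }
  }
  sets <- lapply(results, function(r) r$selected_loci)
  inter <- Reduce(intersect, sets)
  uni <- Reduce(union, sets)
  iu <- if (length(uni) == 0L) {
    warning("all runs selected nothing; I/U ratio defined as 1")
    1
  } else {
    length(inter) / length(uni)
  }
  structure(list(per_run = results, consensus_loci = inter,
                 union_loci = uni, iu_ratio = iu, config = config),
            class = "consensus_result")
}

#' @export
#' @method print consensus_result
print.consensus_result <- function(x, ...) {
  cat("consensus_result: ", length(x$consensus_loci), " consensus SNPs from ",
      length(x$per_run), " runs, I/U = ", signif(x$iu_ratio, 3), "\n", sep = "")
  invisible(x)
}

#' Held-out prediction evaluation
#'
#' Refits the Bayesian ridge on the training columns restricted to
#' `features`, predicts the test samples, and reports mean absolute error,
#' mean squared error, and the Pearson correlation between predicted and
#' observed phenotypes.
#'
#' @param G_train,G_test [genotype_matrix()]s (or code matrices sharing
#'   column names).
#' @param y_train,y_test Trait vectors.
#' @param features Character vector of selected locus ids (non-empty).
#' @return A `prediction_report`: `mae`, `mse`, `pcc`, `n_test`,
#'   `features_used`.
#' @export
evaluate_prediction <- function(G_train, y_train, G_test, y_test, features) {
  if (length(features) == 0L) stop_gaqtl("no features to evaluate")
  tr <- if (inherits(G_train, "genotype_matrix")) G_train$codes else as.matrix(G_train)
  te <- if (inherits(G_test, "genotype_matrix")) G_test$codes else as.matrix(G_test)
  missing_tr <- setdiff(features, colnames(tr))
  missing_te <- setdiff(features, colnames(te))
  if (length(missing_tr) || length(missing_te)) {
    stop_gaqtl("feature(s) absent from matrix: ",
               paste(utils::head(union(missing_tr, missing_te), 3L),
                     collapse = ", "))
  }
  fit <- fit_linear_ridge(tr[, features, drop = FALSE], y_train)
  pred <- predict(fit, te[, features, drop = FALSE])
  pcc <- if (stats::sd(pred) == 0) {
    warning("constant predictions; PCC reported as 0")
    0
  } else {
    pearson_corr(pred, y_test)
  }
  structure(list(mae = mean(abs(pred - y_test)),
                 mse = mean((pred - y_test)^2),
                 pcc = pcc, n_test = length(y_test),
                 features_used = features, predictions = pred),
            class = "prediction_report")
}

#' @export
#' @method print prediction_report
print.prediction_report <- function(x, ...) {
  cat("prediction_report (n_test = ", x$n_test, ", ",
      length(x$features_used), " features):\n", sep = "")
  cat(sprintf("  MAE = %.4g   MSE = %.4g   PCC = %.4g\n", x$mae, x$mse, x$pcc))
  invisible(x)
}

#' LD concordance of a detected set against a reference QTL list
#'
#' For each reference locus, the maximum r-squared between it and any
#' detected SNP. A reference locus that is itself detected scores exactly
#' 1. Reference loci not genotyped in the matrix are skipped with a
#' warning (reference lists often come from other call sets).
#'
#' @param detected Character vector of detected locus ids (non-empty).
#' @param reference Character vector (or data frame with column `id`) of
#'   reference locus ids.
#' @param G A [genotype_matrix()] holding both sets.
#' @return A `concordance_report` data frame: `id`, `max_r2` (the
#'   violin-plot distribution), with skipped loci in
#'   `attr(, "skipped")`.
#' @export
ld_concordance <- function(detected, reference, G) {
  if (length(detected) == 0L) stop_gaqtl("detected set is empty")
  if (is.data.frame(reference)) reference <- reference$id
  codes <- if (inherits(G, "genotype_matrix")) G$codes else as.matrix(G)
  absent_det <- setdiff(detected, colnames(codes))
  if (length(absent_det)) {
    stop_gaqtl("detected locus/loci absent from matrix: ",
               paste(utils::head(absent_det, 3L), collapse = ", "))
  }
  present <- reference %in% colnames(codes)
  if (any(!present)) {
    warning(sum(!present), " reference locus/loci not genotyped; skipped: ",
            paste(utils::head(reference[!present], 3L), collapse = ", "))
  }
  reference <- reference[present]
  D <- codes[, detected, drop = FALSE]
  max_r2 <- vapply(reference, function(id) {
    x <- codes[, id]
    if (stats::sd(x) == 0) return(0)
    live <- apply(D, 2L, stats::sd) > 0
    if (!any(live)) return(0)
    max(as.vector(stats::cor(x, D[, live, drop = FALSE]))^2)
  }, numeric(1))
  out <- data.frame(id = reference, max_r2 = unname(max_r2),
                    stringsAsFactors = FALSE)
  attr(out, "skipped") <- setdiff(reference, colnames(codes))
  class(out) <- c("concordance_report", "data.frame")
  out
}

# Shared core: preprocess on the training partition, run the GA `runs`
# times with consecutive seeds, intersect, evaluate on the test partition.
pipeline_core <- function(G_train, y_train, G_test, y_test, alpha, ga,
                          use_absolute_pcc = TRUE) {
  cs <- preprocess_candidates(G_train, y_train, alpha,
                              use_absolute_pcc = use_absolute_pcc)
  runs <- lapply(seq_len(ga$runs) - 1L, function(k) {
    cfg <- ga
    cfg$seed <- ga$seed + k
    run_ga(G_train, y_train, cs, cfg)
  })
  consensus <- intersect_runs(runs, config = list(alpha = alpha, K = ga$K,
                                                  S = ga$S, L = ga$L,
                                                  runs = ga$runs,
                                                  seed = ga$seed))
  fallback <- FALSE
  features <- consensus$consensus_loci
  if (length(features) == 0L) {
    # empty consensus: fall back to the single best run's set, flagged.
    best_run <- which.max(vapply(runs, function(r) {
      if (r$score$valid) r$score$adj_r2 else -Inf
    }, numeric(1)))
    features <- runs[[best_run]]$selected_loci
    fallback <- TRUE
    warning("empty consensus; evaluating the best single run's selection")
  }
  report <- evaluate_prediction(G_train, y_train, G_test, y_test, features)
  list(candidates = cs, consensus = consensus, prediction = report,
       features = features, consensus_fallback = fallback)
}

#' Run the full selection-and-evaluation pipeline
#'
#' Split by sample, preprocess on the training partition, run the GA
#' `ga$runs` times with seeds `ga$seed, ga$seed + 1, ...`, intersect the
#' runs, and evaluate held-out prediction on the consensus features (the
#' best single run's set if the consensus is empty, flagged in the
#' result).
#'
#' @param G A [genotype_matrix()].
#' @param P A [phenotype_table()].
#' @param trait Trait name.
#' @param alpha LD cutoff for pruning, in (0, 1\].
#' @param ga A [ga_config()]; if `ga$seed` is `NULL` the split seed is
#'   reused as the GA root seed.
#' @param test_fraction Held-out fraction; default 0.1.
#' @param seed Split seed (required).
#' @param use_absolute_pcc Passed to [preprocess_candidates()].
#' @return A `pipeline_result` with `consensus`, `prediction`,
#'   `candidates`, `split`, and a configuration echo.
#' @export
full_pipeline <- function(G, P, trait, alpha = 0.4, ga = ga_config(),
                          test_fraction = 0.1, seed,
                          use_absolute_pcc = TRUE) {
  if (missing(seed)) stop_gaqtl("a seed is required")
  if (is.null(ga$seed)) ga$seed <- seed
  sp <- join_and_split(G, P, trait, test_fraction = test_fraction, seed = seed)
  core <- pipeline_core(sp$G_train, sp$y_train, sp$G_test, sp$y_test,
                        alpha, ga, use_absolute_pcc = use_absolute_pcc)
  structure(c(core, list(split = sp$split, trait = trait,
                         config = list(alpha = alpha, ga = ga,
                                       test_fraction = test_fraction,
                                       seed = seed))),
            class = "pipeline_result")
}

#' @export
#' @method print pipeline_result
print.pipeline_result <- function(x, ...) {
  cat("pipeline_result for trait '", x$trait, "':\n", sep = "")
  cat("  candidates after LD pruning (alpha = ", x$candidates$alpha, "): ",
      length(x$candidates$indices), "\n", sep = "")
  print(x$consensus)
  if (x$consensus_fallback) cat("  (empty consensus: best single run used)\n")
  print(x$prediction)
  invisible(x)
}

#' K-fold cross-validation driver
#'
#' Thin wrapper around the pipeline core: usable samples are shuffled once
#' under `seed`, assigned to contiguous folds, and each fold in turn is
#' held out while preprocessing and the GA run on the remainder. Fold-level
#' MSEs are returned so any standard paired-comparison routine can be
#' applied downstream.
#'
#' @inheritParams full_pipeline
#' @param folds Number of folds; default 5.
#' @return A `cv_result`: data frame `metrics` (fold, mae, mse, pcc,
#'   n_test) and the per-fold pipeline outputs in `fold_results`.
#' @export
cv_pipeline <- function(G, P, trait, alpha = 0.4, ga = ga_config(),
                        folds = 5L, seed, use_absolute_pcc = TRUE) {
  if (missing(seed)) stop_gaqtl("a seed is required")
  if (is.null(ga$seed)) ga$seed <- seed
  y_all <- P$traits[[trait]][match(G$samples, P$samples)]
  usable <- which(!is.na(y_all))
  if (length(usable) < folds) stop_gaqtl("fewer usable samples than folds")
  perm <- with_seed(seed, sample(usable))
  assign_fold <- integer(length(y_all))
  assign_fold[perm] <- sort(rep(seq_len(folds), length.out = length(perm)))
  out <- vector("list", folds)
  metrics <- data.frame()
  for (f in seq_len(folds)) {
    te <- usable[assign_fold[usable] == f]
    tr <- setdiff(usable, te)
    G_tr <- genotype_matrix(G$codes[tr, , drop = FALSE],
                            samples = G$samples[tr], loci = G$loci)
    G_te <- genotype_matrix(G$codes[te, , drop = FALSE],
                            samples = G$samples[te], loci = G$loci)
    ga_f <- ga
    ga_f$seed <- ga$seed + 100L * f
    core <- pipeline_core(G_tr, y_all[tr], G_te, y_all[te], alpha, ga_f,
                          use_absolute_pcc = use_absolute_pcc)
    out[[f]] <- core
    metrics <- rbind(metrics, data.frame(fold = f,
                                         mae = core$prediction$mae,
                                         mse = core$prediction$mse,
                                         pcc = core$prediction$pcc,
                                         n_test = core$prediction$n_test))
  }
  structure(list(metrics = metrics, fold_results = out,
                 config = list(alpha = alpha, ga = ga, folds = folds,
                               seed = seed)),
            class = "cv_result")
}
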