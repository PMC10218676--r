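# Search-space reduction per trait: rank SNPs by (absolute) Pearson
# correlation with the trait, then scan the ranking and keep a SNP only if
# its LD r-squared with every already-kept SNP does not exceed the cutoff
# alpha. Statistics are computed on the training partition only; the
# resulting candidate set is applied to both partitions.

#' Pearson correlation between a SNP code vector and a trait
#'
#' Plain product-moment correlation, except that a constant vector returns
#' 0 rather than `NA`: constant SNPs carry no information and must neither
#' rank above informative SNPs nor block them during pruning.
#'
#' @param x,y Equal-length numeric vectors (length >= 2).
#' @return Correlation in \[-1, 1\].
#' @export
pearson_corr <- function(x, y) {
  if (length(x) != length(y)) stop_gaqtl("length mismatch")
  if (length(x) < 2L) stop_gaqtl("need at least 2 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(0)
  stats::cor(x, y)
}

#' Squared-correlation LD between two SNP code vectors
#'
#' The r-squared linkage-disequilibrium statistic for numerically coded
#' biallelic loci: the square of [pearson_corr()]. Constant columns give 0.
#'
#' @inheritParams pearson_corr
#' @return r-squared in \[0, 1\].
#' @export
pairwise_ld <- function(x, y) pearson_corr(x, y)^2

#' Rank SNPs by correlation with a trait
#'
#' @param G Training [genotype_matrix()] (or plain code matrix).
#' @param y Training trait vector.
#' @param use_absolute_pcc Rank by |PCC| (default) so that SNPs with
#'   negative effects rank as high as positive ones; set `FALSE` to rank by
#'   signed PCC.
#' @return List with `order` (column indices, score non-increasing; ties
#'   broken by ascending column index) and `scores` (ranking statistic in
#'   that order).
#' @export
rank_by_correlation <- function(G, y, use_absolute_pcc = TRUE) {
  codes <- if (inherits(G, "genotype_matrix")) G$codes else as.matrix(G)
  if (nrow(codes) != length(y)) stop_gaqtl("genotype/trait length mismatch")
  if (nrow(codes) < 2L) stop_gaqtl("need at least 2 samples")
  sds <- apply(codes, 2L, stats::sd)
  r <- rep(0, ncol(codes))
  ok <- sds > 0 & stats::sd(y) > 0
  if (any(ok)) r[ok] <- as.vector(stats::cor(codes[, ok, drop = FALSE], y))
  score <- if (use_absolute_pcc) abs(r) else r
  ord <- order(-score, seq_along(score))
  list(order = ord, scores = score[ord], pcc = r)
}

#' Greedy LD pruning of a ranked SNP list
#'
#' Scans SNPs in ranking order and keeps a SNP iff its r-squared with every
#' already-kept SNP is at most `alpha` (boundary inclusive, so `alpha = 1`
#' keeps everything). The top-ranked SNP is always kept; every dropped SNP
#' is in LD above `alpha` with at least one kept, higher-ranked SNP.
#'
#' @param ranked Integer column indices in ranking order (e.g.
#'   `rank_by_correlation(...)$order`).
#' @param G Training [genotype_matrix()] or code matrix.
#' @param alpha LD cutoff in (0, 1\].
#' @param scores Optional ranking scores aligned with `ranked`, carried
#'   into the result.
#' @return A `candidate_set`: list with `indices` (kept column indices, in
#'   ranking order), `scores`, `alpha`, and `loci` (ids, when available).
#' @export
greedy_ld_prune <- function(ranked, G, alpha, scores = NULL) {
  codes <- if (inherits(G, "genotype_matrix")) G$codes else as.matrix(G)
  if (length(ranked) == 0L) stop_gaqtl("ranked index list is empty")
  if (!is.numeric(alpha) || alpha <= 0 || alpha > 1) {
    stop_gaqtl("alpha must lie in (0, 1]")
  }
  kept <- integer(0)
  kept_scores <- numeric(0)
  X_kept <- NULL
  for (k in seq_along(ranked)) {
    j <- ranked[[k]]
    x <- codes[, j]
    keep <- if (length(kept) == 0L) {
      TRUE
    } else if (stats::sd(x) == 0) {
      TRUE  # constant column: r^2 defined as 0 against everything
    } else {
      live <- apply(X_kept, 2L, stats::sd) > 0
      r2 <- rep(0, length(kept))
      if (any(live)) {
        r2[live] <- as.vector(stats::cor(X_kept[, live, drop = FALSE], x))^2
      }
      all(r2 <= alpha)
    }
    if (keep) {
      kept <- c(kept, j)
      kept_scores <- c(kept_scores, if (is.null(scores)) NA_real_ else scores[[k]])
      X_kept <- cbind(X_kept, x)
    }
  }
  loci <- if (inherits(G, "genotype_matrix")) G$loci$id[kept] else colnames(codes)[kept]
  structure(list(indices = kept, scores = kept_scores, alpha = alpha,
                 loci = loci),
            class = "candidate_set")
}

#' @export
#' @method print candidate_set
print.candidate_set <- function(x, ...) {
  cat("candidate_set: ", length(x$indices), " SNPs kept at LD cutoff alpha = ",
      x$alpha, "\n", sep = "")
  invisible(x)
}

#' Rank and prune in one step
#'
#' Convenience wrapper: [rank_by_correlation()] followed by
#' [greedy_ld_prune()], both computed on the training partition.
#'
#' @inheritParams rank_by_correlation
#' @inheritParams greedy_ld_prune
#' @return A `candidate_set`.
#' @export
preprocess_candidates <- function(G, y, alpha, use_absolute_pcc = TRUE) {
  rk <- rank_by_correlation(G, y, use_absolute_pcc = use_absolute_pcc)
  greedy_ld_prune(rk$order, G, alpha, scores = rk$scores)
}

#' Persist / reload a candidate set as TSV
#'
#' Columns: rank, column index, locus id, ranking score, with the cutoff
#' recorded in a header comment.
#'
#' @param cs A `candidate_set`.
#' @param path File path.
#' @export
write_candidates <- function(cs, path) {
  stopifnot(inherits(cs, "candidate_set"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# alpha=", cs$alpha), con)
  tab <- data.frame(rank = seq_along(cs$indices), index = cs$indices,
                    id = cs$loci %||% NA_character_, score = cs$scores)
  utils::write.table(tab, con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_candidates
#' @export
read_candidates <- function(path) {
  header <- readLines(path, n = 1L)
  alpha <- as.numeric(sub("^# alpha=", "", header))
  tab <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                           stringsAsFactors = FALSE)
  structure(list(indices = tab$index, scores = tab$score, alpha = alpha,
                 loci = tab$id),
            class = "candidate_set")
}
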