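# LD-block genotype and planted-QTL phenotype simulator. Genotypes follow
# a first-order chain within each block: each SNP copies its left
# neighbour per sample with probability rho and is otherwise resampled
# uniformly from {-1, +1}, giving P(equal) = (1 + rho)/2, exact {-1, +1}
# marginals, and a closed-form adjacent correlation of exactly rho
# (correlation at lag d decays as rho^d). Blocks are mutually
# independent. Phenotypes are additive (optionally plus pairwise
# epistatic products) with Gaussian noise scaled to a target
# heritability.

#' Simulate an LD-block genotype matrix
#'
#' @param n Sample count.
#' @param n_blocks Number of independent LD blocks.
#' @param block_size SNPs per block.
#' @param rho Within-block chain correlation in \[0, 1); adjacent SNPs in
#'   a block correlate at `rho`, SNPs `d` apart at `rho^d`.
#' @param seed Integer seed.
#' @return A [genotype_matrix()] with loci named `chr1_P` at 1-kb spacing
#'   and a `blocks` attribute mapping columns to block indices.
#' @export
simulate_genotypes <- function(n, n_blocks = 30L, block_size = 10L,
                               rho = 0.9, seed) {
  stopifnot(n >= 2, n_blocks >= 1, block_size >= 1, rho >= 0, rho < 1)
  if (missing(seed)) stop_gaqtl("a seed is required")
  m <- n_blocks * block_size
  codes <- with_seed(seed, {
    out <- matrix(0, nrow = n, ncol = m)
    col <- 0L
    for (b in seq_len(n_blocks)) {
      x <- sample(c(-1, 1), n, replace = TRUE)
      col <- col + 1L
      out[, col] <- x
      for (j in seq_len(block_size - 1L)) {
        copy <- stats::runif(n) < rho
        fresh <- sample(c(-1, 1), n, replace = TRUE)
        x <- ifelse(copy, x, fresh)
        col <- col + 1L
        out[, col] <- x
      }
    }
    out
  })
  G <- genotype_matrix(codes,
                       samples = sprintf("S%04d", seq_len(n)),
                       loci = paste0("chr1_", 1000L * seq_len(m)))
  attr(G, "blocks") <- rep(seq_len(n_blocks), each = block_size)
  G
}

#' Simulate a quantitative trait with planted QTLs
#'
#' `y = sum_i beta_i g_i + sum_(a,b) gamma_ab g_a g_b + e`, with the noise
#' variance scaled so that the genetic share of the phenotypic variance
#' equals `h2` (`h2 = 1` means no noise). Causal loci are drawn one per
#' block where the block map is available (and `k_qtl` does not exceed the
#' block count), otherwise uniformly over columns.
#'
#' @param G A [genotype_matrix()], typically from [simulate_genotypes()].
#' @param k_qtl Number of planted additive QTLs.
#' @param effect_sizes Numeric vector of length `k_qtl`; default equal
#'   magnitudes with alternating signs (avoids sign-cancellation
#'   artifacts).
#' @param h2 Target heritability in (0, 1\].
#' @param epistatic_pairs Optional list of `list(a =, b =, effect =)` with
#'   `a`, `b` locus ids or column indices.
#' @param seed Integer seed.
#' @return List with `y` (trait vector) and `truth` (a `ground_truth`:
#'   causal locus ids and effects, epistatic pairs, and the realized
#'   heritability).
#' @export
simulate_phenotype <- function(G, k_qtl = 5L, effect_sizes = NULL, h2 = 0.8,
                               epistatic_pairs = NULL, seed) {
  stopifnot(inherits(G, "genotype_matrix"), h2 > 0, h2 <= 1)
  if (missing(seed)) stop_gaqtl("a seed is required")
  m <- ncol(G$codes)
  if (k_qtl > m) stop_gaqtl("more QTLs requested than SNPs available")
  if (is.null(effect_sizes)) {
    effect_sizes <- rep(c(1, -1), length.out = k_qtl)
  }
  if (length(effect_sizes) != k_qtl) {
    stop_gaqtl("effect_sizes must have length k_qtl")
  }
  blocks <- attr(G, "blocks")
  with_seed(seed, {
    causal <- if (!is.null(blocks) && k_qtl <= max(blocks)) {
      chosen_blocks <- sort(sample(unique(blocks), k_qtl))
      vapply(chosen_blocks, function(b) {
        cols <- which(blocks == b)
        cols[sample.int(length(cols), 1L)]
      }, integer(1))
    } else {
      sort(sample.int(m, k_qtl))
    }
    genetic <- as.vector(G$codes[, causal, drop = FALSE] %*% effect_sizes)
    epi <- NULL
    if (!is.null(epistatic_pairs)) {
      to_col <- function(z) if (is.character(z)) match(z, G$loci$id) else as.integer(z)
      for (pr in epistatic_pairs) {
        a <- to_col(pr$a); b <- to_col(pr$b)
        if (is.na(a) || is.na(b)) stop_gaqtl("epistatic locus not found")
        genetic <- genetic + pr$effect * G$codes[, a] * G$codes[, b]
        epi <- c(epi, list(list(a = G$loci$id[a], b = G$loci$id[b],
                                effect = pr$effect)))
      }
    }
    var_g <- stats::var(genetic)
    if (var_g == 0) stop_gaqtl("genetic component has zero variance")
    noise <- if (h2 < 1) {
      stats::rnorm(nrow(G$codes), sd = sqrt(var_g * (1 - h2) / h2))
    } else {
      rep(0, nrow(G$codes))
    }
    y <- genetic + noise
    truth <- structure(list(
      causal_loci = G$loci$id[causal],
      causal_indices = causal,
      effects = effect_sizes,
      epistatic_pairs = epi,
      target_h2 = h2,
      realized_h2 = stats::var(genetic) / stats::var(y)
    ), class = "ground_truth")
    list(y = y, truth = truth)
  })
}

#' @export
#' @method print ground_truth
print.ground_truth <- function(x, ...) {
  cat("ground_truth: ", length(x$causal_loci), " additive QTL(s), ",
      "target h2 = ", x$target_h2, ", realized h2 = ",
      signif(x$realized_h2, 3), "\n", sep = "")
  invisible(x)
}

#' Write a simulated dataset in the standard TSV dialects
#'
#' @param G A [genotype_matrix()].
#' @param y Trait vector.
#' @param truth A `ground_truth`.
#' @param dir Output directory (created if needed).
#' @param trait_name Column name for the trait; default `"trait"`.
#' @return Invisibly, the three file paths (genotypes, phenotypes, truth).
#' @export
write_simulation <- function(G, y, truth, dir, trait_name = "trait") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  g_path <- file.path(dir, "genotypes.tsv")
  p_path <- file.path(dir, "phenotypes.tsv")
  t_path <- file.path(dir, "truth.tsv")
  gt <- data.frame(sample = G$samples, G$codes, check.names = FALSE)
  utils::write.table(gt, g_path, sep = "\t", row.names = FALSE, quote = FALSE)
  ph <- data.frame(sample = G$samples, y)
  names(ph)[2L] <- trait_name
  utils::write.table(ph, p_path, sep = "\t", row.names = FALSE, quote = FALSE)
  tt <- data.frame(id = truth$causal_loci, effect = truth$effects,
                   realized_h2 = truth$realized_h2)
  utils::write.table(tt, t_path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(c(genotypes = g_path, phenotypes = p_path, truth = t_path))
}
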