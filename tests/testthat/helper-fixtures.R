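# Fixture builders shared across test files. Everything is generated in
# code; no binary fixtures.

# A small genotype/trait instance with planted additive QTLs.
toy_instance <- function(n = 200, n_blocks = 10, block_size = 5, rho = 0.5,
                         k_qtl = 3, h2 = 0.8, seed = 1) {
  G <- simulate_genotypes(n, n_blocks, block_size, rho, seed = seed)
  sim <- simulate_phenotype(G, k_qtl = k_qtl, h2 = h2, seed = seed + 1000)
  list(G = G, y = sim$y, truth = sim$truth)
}

# Write a genotype matrix as the canonical TSV dialect; returns the path.
write_geno_tsv <- function(G, path = tempfile(fileext = ".tsv"),
                           recode02 = FALSE) {
  codes <- G$codes
  if (recode02) codes <- (codes + 1)  # -1/+1 -> 0/2
  tab <- data.frame(sample = G$samples, codes, check.names = FALSE)
  write.table(tab, path, sep = "\t", row.names = FALSE, quote = FALSE)
  path
}

# Minimal VCF with haploid-style GT fields for the given genotype matrix.
write_geno_vcf <- function(G, path = tempfile(fileext = ".vcf"),
                           gt_override = NULL) {
  lines <- c("##fileformat=VCFv4.2",
             paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", G$samples), collapse = "\t"))
  for (j in seq_len(ncol(G$codes))) {
    gt <- ifelse(G$codes[, j] < 0, "0", "1")
    if (!is.null(gt_override) && j == gt_override$col) {
      gt[gt_override$row] <- gt_override$gt
    }
    lines <- c(lines, paste(c(G$loci$chrom[j], G$loci$pos[j], ".", "A", "T",
                              ".", "PASS", ".", "GT", gt), collapse = "\t"))
  }
  writeLines(lines, path)
  path
}

# Hand-built selection_result stub for consensus arithmetic tests.
fake_run <- function(selected, candidates, adj_r2 = 0.5, seed = 1) {
  structure(list(best_mask = as.integer(candidates %in% selected),
                 selected_loci = selected,
                 score = list(r2 = adj_r2, adj_r2 = adj_r2,
                              p = length(selected), valid = TRUE),
                 trace = adj_r2, iterations = 0L, fitness_calls = 0L,
                 model_fits = 0L, tabu_hits = 0L,
                 distinct_masks = 0L, candidate_loci = candidates,
                 seed = seed, config = NULL),
            class = "selection_result")
}

# Independent brute-force LD pruner: quadratic scan with a full r2 table.
brute_force_prune <- function(ranked, codes, alpha) {
  kept <- integer(0)
  for (j in ranked) {
    ok <- TRUE
    for (k in kept) {
      r <- suppressWarnings(stats::cor(codes[, j], codes[, k]))
      r2 <- if (is.na(r)) 0 else r^2
      if (r2 > alpha) {
        ok <- FALSE
        break
      }
    }
    if (ok) kept <- c(kept, j)
  }
  kept
}
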