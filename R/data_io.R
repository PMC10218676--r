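# Genotype/phenotype/QTL-list input, selection output, and the seeded
# train/test split. Genotypes are biallelic haploid-style codes; the
# canonical in-memory coding is -1 (reference-like allele) / +1
# (alternate-like allele). A {0,2} TSV dialect is accepted and remapped on
# read. Heterozygous or multi-allelic VCF genotypes are rejected: the
# framework targets haploid-cross designs (e.g. segregants of a two-parent
# yeast cross).

#' Construct a genotype matrix
#'
#' @param codes Numeric matrix, samples in rows and SNPs in columns, with
#'   values in \{-1, +1\}. Missing entries (`NA`) are imputed per SNP to the
#'   more frequent code (ties fall to -1); a message reports the count.
#' @param samples Character vector of sample identifiers (defaults to
#'   `rownames(codes)`).
#' @param loci Either a character vector of `chrN_P` locus identifiers
#'   (defaults to `colnames(codes)`) or a data frame with columns
#'   `chrom`, `pos`, `id`.
#' @return An object of class `genotype_matrix`: a list with elements
#'   `codes` (numeric matrix), `samples`, and `loci` (data frame with
#'   `chrom`, `pos`, `id`).
#' @export
genotype_matrix <- function(codes, samples = rownames(codes),
                            loci = colnames(codes)) {
  codes <- as.matrix(codes)
  storage.mode(codes) <- "double"
  if (nrow(codes) < 2L) stop_gaqtl("genotype matrix needs at least 2 samples")
  if (ncol(codes) < 1L) stop_gaqtl("genotype matrix needs at least 1 SNP")
  if (is.null(samples)) samples <- paste0("S", seq_len(nrow(codes)))
  samples <- as.character(samples)
  if (anyDuplicated(samples)) stop_gaqtl("duplicated sample identifiers")
  if (length(samples) != nrow(codes)) {
    stop_gaqtl("sample identifiers do not match the number of rows")
  }
  if (!is.data.frame(loci)) {
    if (is.null(loci)) loci <- paste0("chr1_", 1000L * seq_len(ncol(codes)))
    loci <- parse_locus_ids(loci)
  }
  if (nrow(loci) != ncol(codes)) {
    stop_gaqtl("locus table does not match the number of SNP columns")
  }
  if (anyDuplicated(loci$id)) stop_gaqtl("duplicated locus identifiers")
  n_missing <- sum(is.na(codes))
  if (n_missing > 0L) {
    codes <- apply(codes, 2L, function(col) {
      miss <- is.na(col)
      if (any(miss)) {
        fill <- if (sum(col[!miss] == 1) > sum(col[!miss] == -1)) 1 else -1
        col[miss] <- fill
      }
      col
    })
    message("imputed ", n_missing, " missing genotype code(s) to per-SNP mode")
  }
  bad <- !(codes %in% c(-1, 1))
  if (any(bad)) {
    stop_gaqtl("genotype codes must be -1 or +1 after canonicalization; ",
               "found ", paste(unique(codes[bad])[1:min(3, sum(bad))],
                               collapse = ", "))
  }
  dimnames(codes) <- list(samples, loci$id)
  structure(list(codes = codes, samples = samples, loci = loci),
            class = "genotype_matrix")
}

#' @export
#' @method print genotype_matrix
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix: ", nrow(x$codes), " samples x ", ncol(x$codes),
      " SNPs (codes -1/+1)\n", sep = "")
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$codes)

#' Parse `chrN_P` locus identifiers
#'
#' Splits identifiers such as `"chrXII_657536"` at the last underscore into
#' a chromosome label and a 1-based position.
#'
#' @param ids Character vector of identifiers.
#' @return Data frame with columns `chrom`, `pos` (integer), `id`.
#' @export
parse_locus_ids <- function(ids) {
  ids <- as.character(ids)
  ok <- grepl("^.+_[0-9]+$", ids)
  if (!all(ok)) {
    stop_gaqtl("malformed locus identifier(s): ",
               paste(utils::head(ids[!ok], 3L), collapse = ", "),
               " (expected chrN_P, e.g. chrIII_95776)")
  }
  pos <- as.integer(sub("^.*_", "", ids))
  if (any(pos < 1L)) stop_gaqtl("locus positions must be >= 1")
  chrom <- sub("_[0-9]+$", "", ids)
  data.frame(chrom = chrom, pos = pos, id = ids, stringsAsFactors = FALSE)
}

#' Read a genotype matrix from file
#'
#' Two dialects are supported. `tsv_matrix`: a tab- (or comma-) separated
#' table whose first column holds sample identifiers and whose remaining
#' column headers are `chrN_P` locus ids, with values in \{-1, 1\} or the
#' \{0, 2\} dosage dialect (remapped 0 to -1 and 2 to +1). `vcf`: a VCF
#' with biallelic sites and haploid-style GT fields; reference homozygotes
#' (or haploid `0`) map to -1 and alternate homozygotes to +1.
#' Heterozygous or multi-allelic genotypes raise an error naming the locus.
#'
#' @param path File path.
#' @param dialect `"vcf"`, `"tsv_matrix"`, or `"auto"` (by file extension).
#' @return A [genotype_matrix()].
#' @export
read_genotypes <- function(path, dialect = c("auto", "tsv_matrix", "vcf")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop_gaqtl("file not found: ", path)
  if (dialect == "auto") {
    dialect <- if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE)) {
      "vcf"
    } else "tsv_matrix"
  }
  if (dialect == "vcf") read_genotypes_vcf(path) else read_genotypes_tsv(path)
}

read_genotypes_tsv <- function(path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  first <- readLines(path, n = 1L)
  if (grepl(",", first) && !grepl("\t", first)) sep <- ","
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           na.strings = c("NA", ""))
  if (ncol(tab) < 2L) stop_gaqtl("genotype TSV needs a sample column plus SNPs")
  samples <- as.character(tab[[1L]])
  codes <- as.matrix(tab[, -1L, drop = FALSE])
  storage.mode(codes) <- "double"
  observed <- sort(unique(codes[!is.na(codes)]))
  if (all(observed %in% c(-1, 1))) {
    # canonical dialect
  } else if (all(observed %in% c(0, 2))) {
    codes[codes == 0] <- -1
    codes[codes == 2] <- 1
  } else {
    stop_gaqtl("unknown genotype codes in TSV: ",
               paste(setdiff(observed, c(-1, 0, 1, 2)), collapse = ", "),
               " (expected {-1,1} or {0,2})")
  }
  genotype_matrix(codes, samples = samples, loci = colnames(tab)[-1L])
}

read_genotypes_vcf <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  alt <- fix[, "ALT"]
  multi <- grepl(",", alt)
  ids <- paste0(fix[, "CHROM"], "_", fix[, "POS"])
  if (any(multi)) {
    stop_gaqtl("multi-allelic site(s) in VCF: ",
               paste(utils::head(ids[multi], 3L), collapse = ", "))
  }
  gt <- vcfR::extract.gt(vcf, element = "GT")
  gt_clean <- gsub("\\|", "/", gt)
  code_one <- function(g, id) {
    if (is.na(g) || g == "." || g == "./.") return(NA_real_)
    if (g %in% c("0", "0/0")) return(-1)
    if (g %in% c("1", "1/1")) return(1)
    stop_gaqtl("heterozygous or unsupported genotype '", g,
               "' at locus ", id, "; haploid-style biallelic GT required")
  }
  codes <- matrix(NA_real_, nrow = ncol(gt_clean), ncol = nrow(gt_clean))
  for (j in seq_len(nrow(gt_clean))) {
    codes[, j] <- vapply(gt_clean[j, ], code_one, numeric(1), id = ids[j])
  }
  genotype_matrix(codes, samples = colnames(gt_clean), loci = ids)
}

#' Read a phenotype table
#'
#' Expects a TSV/CSV with sample identifiers in the first column and one
#' numeric column per trait; empty cells are missing.
#'
#' @param path File path.
#' @return A `phenotype_table`: list with `samples` and `traits` (a data
#'   frame of numeric trait columns).
#' @export
read_phenotypes <- function(path) {
  if (!file.exists(path)) stop_gaqtl("file not found: ", path)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           na.strings = c("NA", ""))
  if (ncol(tab) < 2L) stop_gaqtl("phenotype table needs a sample column plus traits")
  samples <- as.character(tab[[1L]])
  traits <- tab[, -1L, drop = FALSE]
  for (j in seq_along(traits)) traits[[j]] <- as.numeric(traits[[j]])
  phenotype_table(samples, traits)
}

#' @rdname read_phenotypes
#' @param samples Character vector of sample identifiers.
#' @param traits Data frame of numeric trait vectors (missing allowed).
#' @export
phenotype_table <- function(samples, traits) {
  samples <- as.character(samples)
  traits <- as.data.frame(traits)
  if (anyDuplicated(samples)) stop_gaqtl("duplicated sample identifiers")
  if (nrow(traits) != length(samples)) {
    stop_gaqtl("trait vectors do not match the number of samples")
  }
  structure(list(samples = samples, traits = traits),
            class = "phenotype_table")
}

#' Read a reference QTL list
#'
#' Accepts either one `chrN_P` identifier per line or a TSV with a column
#' named `id`. Duplicates are removed with a warning.
#'
#' @param path File path.
#' @return Data frame of loci (`chrom`, `pos`, `id`), input order preserved.
#' @export
read_qtl_list <- function(path) {
  if (!file.exists(path)) stop_gaqtl("file not found: ", path)
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    return(data.frame(chrom = character(), pos = integer(),
                      id = character(), stringsAsFactors = FALSE))
  }
  if (grepl("\t", lines[[1L]]) || grepl("^id$", lines[[1L]])) {
    tab <- utils::read.table(path, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE, check.names = FALSE)
    if (!"id" %in% names(tab)) stop_gaqtl("QTL TSV needs a column named 'id'")
    ids <- as.character(tab$id)
  } else {
    ids <- lines
  }
  if (anyDuplicated(ids)) {
    warning("removed ", sum(duplicated(ids)), " duplicate QTL id(s)")
    ids <- ids[!duplicated(ids)]
  }
  parse_locus_ids(ids)
}

#' Join genotypes with a trait and split into train/test partitions
#'
#' Samples are aligned by an explicit identifier join (orphans on either
#' side are an error). Samples with a missing trait value are dropped
#' before splitting; the shuffle is a deterministic function of `seed`, so
#' the same seed always yields the same partition. The test partition holds
#' `round(test_fraction * n_usable)` samples.
#'
#' @param G A [genotype_matrix()].
#' @param P A [phenotype_table()].
#' @param trait Trait (column) name in `P`.
#' @param test_fraction Fraction of usable samples held out, in (0, 1).
#' @param seed Integer seed for the shuffle (required; it is part of the
#'   experimental record).
#' @return List with `G_train`, `y_train`, `G_test`, `y_test`, and `split`
#'   (train/test indices into the usable-sample ordering, the seed, and the
#'   test fraction).
#' @export
join_and_split <- function(G, P, trait, test_fraction = 0.1, seed) {
  stopifnot(inherits(G, "genotype_matrix"), inherits(P, "phenotype_table"))
  if (missing(seed)) stop_gaqtl("a split seed is required")
  if (!is.numeric(test_fraction) || test_fraction <= 0 || test_fraction >= 1) {
    stop_gaqtl("test_fraction must lie in (0, 1)")
  }
  if (!trait %in% names(P$traits)) {
    stop_gaqtl("trait '", trait, "' not found; available: ",
               paste(names(P$traits), collapse = ", "))
  }
  only_g <- setdiff(G$samples, P$samples)
  only_p <- setdiff(P$samples, G$samples)
  if (length(only_g) || length(only_p)) {
    stop_gaqtl("sample identifier mismatch between genotypes and phenotypes; ",
               "genotype-only: ", paste(utils::head(only_g, 3L), collapse = ","),
               "; phenotype-only: ", paste(utils::head(only_p, 3L), collapse = ","))
  }
  y_all <- P$traits[[trait]][match(G$samples, P$samples)]
  usable <- which(!is.na(y_all))
  if (length(usable) < 10L) {
    stop_gaqtl("fewer than 10 samples have a non-missing value for '", trait, "'")
  }
  n_use <- length(usable)
  n_test <- round(test_fraction * n_use)
  if (n_test < 1L || n_test >= n_use) stop_gaqtl("degenerate split size")
  perm <- with_seed(seed, sample.int(n_use))
  test_idx <- sort(perm[seq_len(n_test)])
  train_idx <- sort(perm[-seq_len(n_test)])
  take <- function(rows) {
    genotype_matrix(G$codes[usable[rows], , drop = FALSE],
                    samples = G$samples[usable[rows]], loci = G$loci)
  }
  list(
    G_train = take(train_idx), y_train = y_all[usable[train_idx]],
    G_test = take(test_idx), y_test = y_all[usable[test_idx]],
    split = list(train_indices = train_idx, test_indices = test_idx,
                 usable = usable, seed = seed, test_fraction = test_fraction)
  )
}

#' Write a consensus selection to disk
#'
#' Writes a TSV of the union of selected loci (id, chrom, pos, one logical
#' membership column per run, and a `consensus` column) and a JSON report
#' with the intersection-over-union ratio, per-run fitness, and a
#' configuration echo.
#'
#' @param result A `consensus_result` from [intersect_runs()] or
#'   [full_pipeline()].
#' @param path Output TSV path.
#' @param report_path Output JSON report path; defaults to the TSV path
#'   with a `_report.json` suffix.
#' @export
write_selection <- function(result, path,
                            report_path = paste0(
                              tools::file_path_sans_ext(path), "_report.json")) {
  stopifnot(inherits(result, "consensus_result"))
  run_sets <- lapply(result$per_run, function(r) r$selected_loci)
  union_ids <- Reduce(union, run_sets, character())
  tab <- if (length(union_ids)) {
    loc <- parse_locus_ids(union_ids)
    memb <- vapply(run_sets, function(s) union_ids %in% s,
                   logical(length(union_ids)))
    memb <- matrix(memb, nrow = length(union_ids),
                   dimnames = list(NULL, paste0("run", seq_along(run_sets))))
    cbind(loc, as.data.frame(memb),
          consensus = union_ids %in% result$consensus_loci)
  } else {
    empty <- data.frame(chrom = character(), pos = integer(), id = character())
    for (k in seq_along(run_sets)) empty[[paste0("run", k)]] <- logical()
    empty$consensus <- logical()
    empty
  }
  utils::write.table(tab, path, sep = "\t", row.names = FALSE, quote = FALSE)
  report <- list(
    iu_ratio = result$iu_ratio,
    n_consensus = length(result$consensus_loci),
    consensus_loci = result$consensus_loci,
    per_run = lapply(result$per_run, function(r) {
      list(seed = r$seed, n_selected = length(r$selected_loci),
           adj_r2 = r$score$adj_r2, r2 = r$score$r2, p = r$score$p,
           fitness_calls = r$fitness_calls, tabu_hits = r$tabu_hits)
    }),
    config = result$config
  )
  jsonlite::write_json(report, report_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(path, report_path))
}

#' Read back the locus ids of a written selection
#'
#' @param path TSV written by [write_selection()].
#' @param consensus_only Keep only consensus rows (default `TRUE`).
#' @return Data frame of loci as in [parse_locus_ids()].
#' @export
read_selection <- function(path, consensus_only = TRUE) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  if (consensus_only && "consensus" %in% names(tab)) {
    tab <- tab[tab$consensus, , drop = FALSE]
  }
  if (nrow(tab) == 0L) {
    return(data.frame(chrom = character(), pos = integer(),
                      id = character(), stringsAsFactors = FALSE))
  }
  parse_locus_ids(tab$id)
}
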