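#' Construct a genotype matrix object
#'
#' Container for SNP genotypes coded as counts of the reference allele A1
#' (0, 1, 2), with `NA` marking missing calls. Rows are individuals,
#' columns are SNPs.
#'
#' @param values integer/numeric matrix of codes in \{0, 1, 2\} or `NA`.
#' @param individual_ids character vector of unique row identifiers.
#' @param snp_ids character vector of unique column identifiers.
#' @return An object of class `genotype_matrix`: a list with elements
#'   `values`, `individual_ids`, `snp_ids`.
#' @export
genotype_matrix <- function(values, individual_ids = rownames(values),
                            snp_ids = colnames(values)) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(individual_ids)) {
    individual_ids <- paste0("ind", seq_len(nrow(values)))
  }
  if (is.null(snp_ids)) snp_ids <- paste0("snp", seq_len(ncol(values)))
  individual_ids <- as.character(individual_ids)
  snp_ids <- as.character(snp_ids)
  if (length(individual_ids) != nrow(values)) {
    stop("individual_ids length does not match the number of rows")
  }
  if (length(snp_ids) != ncol(values)) {
    stop("snp_ids length does not match the number of columns")
  }
  if (anyDuplicated(individual_ids)) stop("duplicate individual IDs")
  if (anyDuplicated(snp_ids)) stop("duplicate SNP IDs")
  bad <- !is.na(values) & !(values %in% c(0, 1, 2))
  if (any(bad)) {
    warning(sum(bad), " genotype value(s) outside {0,1,2} set to missing")
    values[bad] <- NA_real_
  }
  dimnames(values) <- list(individual_ids, snp_ids)
  structure(list(values = values, individual_ids = individual_ids,
                 snp_ids = snp_ids),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", nrow(x$values), "individuals x",
      ncol(x$values), "SNPs;",
      sprintf("%.2f%% missing\n", 100 * mean(is.na(x$values))))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$values)

#' Read genotypes from disk
#'
#' Supports two plain-text dialects: PLINK `.raw` additive coding
#' (whitespace-separated, header `FID IID PAT MAT SEX PHENOTYPE snp1_A ...`)
#' and a TSV matrix whose header row holds SNP IDs and whose first column
#' holds individual IDs. Tokens `NA`, `-9` and the empty string are read as
#' missing; any other token that is not 0, 1 or 2 is set to missing with a
#' warning.
#'
#' @param path file path.
#' @param format `"plink-raw"` or `"matrix-tsv"`.
#' @return A [genotype_matrix()].
#' @export
read_genotypes <- function(path, format = c("matrix-tsv", "plink-raw")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "plink-raw") {
    dat <- utils::read.table(path, header = TRUE, check.names = FALSE,
                             na.strings = c("NA", "-9", ""),
                             stringsAsFactors = FALSE)
    need <- c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE")
    if (ncol(dat) < 7 || !identical(names(dat)[1:6], need)) {
      stop("malformed plink-raw header: expected columns ",
           paste(need, collapse = " "))
    }
    ids <- as.character(dat$IID)
    vals <- as.matrix(dat[, -(1:6), drop = FALSE])
    # strip the counted-allele suffix plink appends, e.g. "snp1_A" -> "snp1"
    snp_ids <- sub("_[ACGT0-9]+$", "", colnames(vals))
  } else {
    dat <- utils::read.table(path, header = TRUE, sep = "\t",
                             check.names = FALSE, row.names = 1,
                             na.strings = c("NA", "-9", ""),
                             stringsAsFactors = FALSE)
    if (ncol(dat) < 1) stop("malformed matrix-tsv: no SNP columns")
    ids <- rownames(dat)
    vals <- as.matrix(dat)
    snp_ids <- colnames(dat)
  }
  suppressWarnings(storage.mode(vals) <- "double")
  genotype_matrix(vals, ids, snp_ids)
}

#' Write a genotype matrix as TSV
#'
#' Inverse of `read_genotypes(format = "matrix-tsv")`.
#'
#' @param g a [genotype_matrix()].
#' @param path output path.
#' @export
write_genotypes <- function(g, path) {
  df <- data.frame(id = g$individual_ids, g$values, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Observed allele frequencies
#'
#' Frequency of allele A1 at each SNP, computed from non-missing genotypes
#' only: p_i = (sum of codes) / (2 * number of non-missing calls).
#'
#' @param g a [genotype_matrix()].
#' @return Named numeric vector `p` of length m.
#' @export
allele_frequencies <- function(g) {
  stopifnot(inherits(g, "genotype_matrix"))
  nonmiss <- colSums(!is.na(g$values))
  if (any(nonmiss == 0)) {
    stop("SNP(s) with all genotypes missing: ",
         paste(g$snp_ids[nonmiss == 0], collapse = ", "))
  }
  p <- colSums(g$values, na.rm = TRUE) / (2 * nonmiss)
  names(p) <- g$snp_ids
  p
}

#' Per-individual genomic inbreeding
#'
#' The proportion of an individual's non-missing SNP genotypes that are
#' homozygous: f_i = 1 - (heterozygote count)/(non-missing count). This is
#' the molecular homozygosity measure used as the inbreeding-depression
#' covariate.
#'
#' @param g a [genotype_matrix()].
#' @return Named numeric vector `f` in \[0, 1\], one entry per individual.
#' @export
genomic_inbreeding <- function(g) {
  stopifnot(inherits(g, "genotype_matrix"))
  nonmiss <- rowSums(!is.na(g$values))
  if (any(nonmiss == 0)) {
    stop("individual(s) with all genotypes missing: ",
         paste(g$individual_ids[nonmiss == 0], collapse = ", "))
  }
  het <- rowSums(g$values == 1, na.rm = TRUE)
  f <- 1 - het / nonmiss
  names(f) <- g$individual_ids
  f
}

#' Write genomic inbreeding as two-column TSV
#' @param f named vector from [genomic_inbreeding()].
#' @param path output path.
#' @export
write_inbreeding <- function(f, path) {
  utils::write.table(data.frame(id = names(f), f = unname(f)), path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Mean-impute missing genotypes
#'
#' Missing codes are replaced by their locus mean 2*p_i. Imputed values are
#' used only to build relationship matrices (a mean-imputed genotype
#' contributes exactly zero to the centered additive coding); genomic
#' inbreeding is always computed from observed calls.
#'
#' @param g a [genotype_matrix()].
#' @param freqs allele frequencies computed from `g`.
#' @return Numeric matrix with no missing values.
#' @export
impute_missing <- function(g, freqs = allele_frequencies(g)) {
  stopifnot(inherits(g, "genotype_matrix"))
  if (length(freqs) != ncol(g$values)) {
    stop("frequency vector does not match the number of SNPs")
  }
  vals <- g$values
  miss <- which(is.na(vals), arr.ind = TRUE)
  if (nrow(miss)) vals[miss] <- 2 * freqs[miss[, 2]]
  vals
}

#' Apply genotype quality control
#'
#' Filters are applied in a fixed order so that removal counts are
#' reproducible: (1) individual call rate, (2) SNP call rate, (3) minor
#' allele frequency, (4) Hardy-Weinberg heterozygote excess
#' (|observed heterozygote frequency - 2pq| must not exceed `hwe_dev`,
#' with p recomputed on the surviving individuals).
#'
#' @param g a [genotype_matrix()].
#' @param ind_call_rate minimum per-individual call rate (default 0.90).
#' @param snp_call_rate minimum per-SNP call rate (default 0.90).
#' @param maf minimum minor allele frequency (default 0.05).
#' @param hwe_dev maximum |observed het freq - 2pq| (default 0.15).
#' @return List with elements `genotypes` (filtered [genotype_matrix()])
#'   and `report` (class `qc_report`).
#' @export
apply_qc <- function(g, ind_call_rate = 0.90, snp_call_rate = 0.90,
                     maf = 0.05, hwe_dev = 0.15) {
  stopifnot(inherits(g, "genotype_matrix"))
  thr <- c(ind_call_rate, snp_call_rate, maf, hwe_dev)
  if (any(!is.finite(thr)) || any(thr < 0) || any(thr > 1)) {
    stop("QC thresholds must lie in [0, 1]")
  }
  vals <- g$values
  n_ind_in <- nrow(vals); n_snp_in <- ncol(vals)

  ind_cr <- rowMeans(!is.na(vals))
  keep_ind <- ind_cr >= ind_call_rate
  vals <- vals[keep_ind, , drop = FALSE]

  snp_cr <- colMeans(!is.na(vals))
  rm_callrate <- snp_cr < snp_call_rate

  nonmiss <- colSums(!is.na(vals))
  p <- ifelse(nonmiss > 0, colSums(vals, na.rm = TRUE) / (2 * pmax(nonmiss, 1)),
              NA_real_)
  m_af <- pmin(p, 1 - p)
  rm_maf <- !rm_callrate & (is.na(m_af) | m_af < maf)

  het_obs <- colSums(vals == 1, na.rm = TRUE) / pmax(nonmiss, 1)
  hwe_gap <- abs(het_obs - 2 * p * (1 - p))
  rm_hwe <- !rm_callrate & !rm_maf & (is.na(hwe_gap) | hwe_gap > hwe_dev)

  keep_snp <- !(rm_callrate | rm_maf | rm_hwe)
  out <- genotype_matrix(vals[, keep_snp, drop = FALSE],
                         g$individual_ids[keep_ind],
                         g$snp_ids[keep_snp])
  report <- structure(list(
    n_individuals_in = n_ind_in,
    n_individuals_out = nrow(out$values),
    n_snps_in = n_snp_in,
    n_snps_out = ncol(out$values),
    removed = list(individual_call_rate = sum(!keep_ind),
                   snp_call_rate = sum(rm_callrate),
                   maf = sum(rm_maf),
                   hwe = sum(rm_hwe)),
    thresholds = list(ind_call_rate = ind_call_rate,
                      snp_call_rate = snp_call_rate,
                      maf = maf, hwe_dev = hwe_dev)
  ), class = "qc_report")
  list(genotypes = out, report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat("QC:", x$n_individuals_in, "->", x$n_individuals_out, "individuals;",
      x$n_snps_in, "->", x$n_snps_out, "SNPs\n")
  cat("  removed individuals (call rate):", x$removed$individual_call_rate, "\n")
  cat("  removed SNPs: call rate", x$removed$snp_call_rate,
      "| MAF", x$removed$maf, "| HWE", x$removed$hwe, "\n")
  invisible(x)
}

#' Write a QC report as JSON
#' @param report a `qc_report` from [apply_qc()].
#' @param path output path.
#' @export
write_qc_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
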