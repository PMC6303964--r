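#' Additive (VanRaden) incidence matrix
#'
#' Centered gene-content coding: for a SNP with A1 frequency p the three
#' genotypes A1A1, A1A2, A2A2 code as 2-2p, 1-2p, -2p, i.e. code - 2p.
#' Because p is the observed frequency of the analyzed set, every column
#' sums to zero exactly. Mean-imputed (fractional) genotypes likewise
#' contribute code - 2p, which is zero for an imputed entry.
#'
#' @param g imputed genotype matrix (numeric, no `NA`), or a
#'   [genotype_matrix()] (imputed internally).
#' @param freqs observed allele frequencies, one per SNP column.
#' @return Object of class `incidence_matrix` with `values`, `kind = "additive"`
#'   and the frequencies used.
#' @export
additive_incidence <- function(g, freqs) {
  vals <- resolve_imputed(g, freqs)
  M <- sweep(vals, 2, 2 * freqs, "-")
  structure(list(values = M, kind = "additive", freqs = freqs),
            class = "incidence_matrix")
}

#' Dominance (NOIA, HWE) incidence matrix
#'
#' Heterosis coding orthogonal to the additive coding under HWE: genotypes
#' A1A1, A1A2, A2A2 code as -2q^2, 2pq, -2p^2. Entries that were missing in
#' the raw genotypes are set to 0, the HWE-expected value of this coding
#' (no information contributes nothing).
#'
#' @inheritParams additive_incidence
#' @return Object of class `incidence_matrix` with `kind = "dominance"`.
#' @export
dominance_incidence <- function(g, freqs) {
  if (inherits(g, "genotype_matrix")) {
    raw <- g$values
  } else {
    raw <- as.matrix(g)
  }
  if (length(freqs) != ncol(raw)) stop("frequency/SNP dimension mismatch")
  q <- 1 - freqs
  n <- nrow(raw)
  W <- matrix(0, n, ncol(raw), dimnames = dimnames(raw))
  # exact codes for the three integer genotypes; anything else (missing or
  # fractional from imputation) stays at the zero HWE expectation
  for (code in 0:2) {
    idx <- which(!is.na(raw) & raw == code, arr.ind = TRUE)
    if (!nrow(idx)) next
    colcode <- switch(as.character(code),
                      "2" = -2 * q^2,
                      "1" = 2 * freqs * q,
                      "0" = -2 * freqs^2)
    W[idx] <- colcode[idx[, 2]]
  }
  structure(list(values = W, kind = "dominance", freqs = freqs),
            class = "incidence_matrix")
}

resolve_imputed <- function(g, freqs) {
  if (inherits(g, "genotype_matrix")) {
    vals <- impute_missing(g, freqs)
  } else {
    vals <- as.matrix(g)
    if (anyNA(vals)) stop("imputed genotype matrix contains NA")
  }
  if (length(freqs) != ncol(vals)) stop("frequency/SNP dimension mismatch")
  vals
}

new_relationship_matrix <- function(values, component, normalization) {
  values <- (values + t(values)) / 2   # symmetrize against rounding
  structure(list(values = values, component = component,
                 normalization = normalization,
                 ids = rownames(values)),
            class = "relationship_matrix")
}

#' @export
print.relationship_matrix <- function(x, ...) {
  cat("relationship_matrix [", x$component, "]: ",
      nrow(x$values), " x ", ncol(x$values),
      "; mean diag = ", sprintf("%.4f", mean(diag(x$values))), "\n", sep = "")
  invisible(x)
}

#' Additive genomic relationship matrix
#'
#' G_A = MM' / (2 * sum(p_i q_i)), the VanRaden construction, where the sum
#' runs over the SNPs retained in M. Monomorphic SNPs contribute zero
#' columns and are excluded from the denominator (with a warning).
#'
#' @param M an additive `incidence_matrix` from [additive_incidence()].
#' @return A `relationship_matrix` with `component = "A"`.
#' @export
grm_additive <- function(M) {
  stopifnot(inherits(M, "incidence_matrix"), M$kind == "additive")
  p <- M$freqs; q <- 1 - p
  poly <- p > 0 & p < 1
  if (!all(poly)) {
    warning(sum(!poly), " monomorphic SNP(s) excluded from the denominator")
  }
  denom <- 2 * sum(p[poly] * q[poly])
  if (denom <= 0) stop("all SNPs monomorphic: additive denominator is zero")
  new_relationship_matrix(tcrossprod(M$values) / denom, "A", denom)
}

#' Dominance genomic relationship matrix
#'
#' G_D = WW' / (4 * sum(p_i^2 q_i^2)); same monomorphic handling as
#' [grm_additive()].
#'
#' @param W a dominance `incidence_matrix` from [dominance_incidence()].
#' @return A `relationship_matrix` with `component = "D"`.
#' @export
grm_dominance <- function(W) {
  stopifnot(inherits(W, "incidence_matrix"), W$kind == "dominance")
  p <- W$freqs; q <- 1 - p
  poly <- p > 0 & p < 1
  if (!all(poly)) {
    warning(sum(!poly), " monomorphic SNP(s) excluded from the denominator")
  }
  denom <- 4 * sum((p[poly] * q[poly])^2)
  if (denom <= 0) stop("all SNPs monomorphic: dominance denominator is zero")
  new_relationship_matrix(tcrossprod(W$values) / denom, "D", denom)
}

#' Trace-normalized Hadamard (epistatic) relationship matrix
#'
#' For pairwise epistatic interactions, the covariance structure is the
#' elementwise (Hadamard) product of the parent matrices rescaled so that
#' its mean diagonal is one: G_XY = (G_X o G_Y) / (tr(G_X o G_Y)/n).
#' Components combine as A\*A -> AA, A\*D -> AD, D\*D -> DD.
#'
#' @param Gx,Gy `relationship_matrix` objects of equal dimension with
#'   components in \{A, D\}.
#' @return A `relationship_matrix` whose trace equals its dimension exactly.
#' @export
epistatic_grm <- function(Gx, Gy) {
  stopifnot(inherits(Gx, "relationship_matrix"),
            inherits(Gy, "relationship_matrix"))
  if (!identical(dim(Gx$values), dim(Gy$values))) {
    stop("relationship matrices differ in dimension")
  }
  comp <- paste0(sort(c(Gx$component, Gy$component), decreasing = FALSE),
                 collapse = "")
  comp <- switch(comp, "AA" = "AA", "AD" = "AD", "DD" = "DD",
                 stop("epistatic products are defined for A and D inputs"))
  H <- Gx$values * Gy$values
  n <- nrow(H)
  tr <- sum(diag(H))
  if (tr <= 0) stop("trace of the Hadamard product is not positive")
  new_relationship_matrix(H / (tr / n), comp, tr / n)
}

#' Ridge-regularize a relationship matrix
#'
#' Adds `epsilon` to the diagonal so that the matrix is safely positive
#' definite before inversion/factorization in the sampler and the
#' mixed-model solver.
#'
#' @param G a `relationship_matrix`.
#' @param epsilon positive diagonal shift (default 1e-6).
#' @return The shifted `relationship_matrix`; `$epsilon` records the shift.
#' @export
regularize <- function(G, epsilon = 1e-6) {
  stopifnot(inherits(G, "relationship_matrix"), epsilon > 0)
  out <- new_relationship_matrix(G$values + diag(epsilon, nrow(G$values)),
                                 G$component, G$normalization)
  out$ids <- G$ids
  out$epsilon <- epsilon
  out
}

#' Build the full set of genomic relationship matrices
#'
#' Convenience wrapper: computes observed allele frequencies, the M and W
#' incidence matrices, and the five relationship matrices A, D, AA, AD, DD.
#'
#' @param g a [genotype_matrix()].
#' @param components character subset of c("A","D","AA","AD","DD").
#' @param epsilon regularization added to each matrix (default 1e-6);
#'   `NULL` to skip.
#' @return Named list of `relationship_matrix` objects.
#' @export
build_grms <- function(g, components = c("A", "D", "AA", "AD", "DD"),
                       epsilon = 1e-6) {
  freqs <- allele_frequencies(g)
  out <- list()
  GA <- grm_additive(additive_incidence(g, freqs))
  rownames(GA$values) <- g$individual_ids
  GA$ids <- g$individual_ids
  need_D <- any(c("D", "AD", "DD") %in% components)
  GD <- NULL
  if (need_D) {
    GD <- grm_dominance(dominance_incidence(g, freqs))
    rownames(GD$values) <- g$individual_ids
    GD$ids <- g$individual_ids
  }
  if ("A" %in% components) out$A <- GA
  if ("D" %in% components) out$D <- GD
  if ("AA" %in% components) out$AA <- epistatic_grm(GA, GA)
  if ("AD" %in% components) out$AD <- epistatic_grm(GA, GD)
  if ("DD" %in% components) out$DD <- epistatic_grm(GD, GD)
  for (k in names(out)) out[[k]]$ids <- g$individual_ids
  if (!is.null(epsilon)) out <- lapply(out, regularize, epsilon = epsilon)
  out
}

#' Write a relationship matrix as dense TSV
#'
#' Header comment lines record the component tag and normalization
#' constant; the first row holds individual IDs.
#'
#' @param G a `relationship_matrix`.
#' @param path output path.
#' @export
write_grm_tsv <- function(G, path) {
  stopifnot(inherits(G, "relationship_matrix"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# component: %s", G$component), con)
  writeLines(sprintf("# normalization: %.17g", G$normalization), con)
  ids <- if (!is.null(G$ids)) G$ids else paste0("ind", seq_len(nrow(G$values)))
  writeLines(paste(ids, collapse = "\t"), con)
  utils::write.table(format(G$values, digits = 17, trim = TRUE), con,
                     sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a relationship matrix written by [write_grm_tsv()]
#' @param path input path.
#' @return A `relationship_matrix`.
#' @export
read_grm_tsv <- function(path) {
  lines <- readLines(path)
  comp <- sub("^# component: ", "", lines[1])
  norm <- as.numeric(sub("^# normalization: ", "", lines[2]))
  ids <- strsplit(lines[3], "\t", fixed = TRUE)[[1]]
  vals <- as.matrix(utils::read.table(text = lines[-(1:3)], sep = "\t"))
  dimnames(vals) <- list(ids, ids)
  out <- new_relationship_matrix(vals, comp, norm)
  out$ids <- ids
  out
}
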