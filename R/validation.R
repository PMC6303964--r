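#' Whole/partial forward split of repeated records
#'
#' Partitions records at a time cutoff: records with `period < cutoff`
#' form the partial set. Individuals with records on both sides of the
#' cutoff are excluded entirely (from the whole set too). Candidates are
#' the individuals whose records all fall at or after the cutoff — they
#' carry no phenotypic information in the partial data, mimicking
#' selection candidates at birth.
#'
#' @param records phenotype `data.frame` with columns `id` and `period`.
#' @param cutoff numeric cutoff period.
#' @return List of class `split_plan`: `whole` and `partial` record
#'   subsets, `candidates`, `excluded`, `cutoff`.
#' @export
time_split <- function(records, cutoff) {
  if (!all(c("id", "period") %in% names(records))) {
    stop("records must have columns 'id' and 'period'")
  }
  id <- as.character(records$id)
  before <- records$period < cutoff
  ids_before <- unique(id[before])
  ids_after <- unique(id[!before])
  excluded <- intersect(ids_before, ids_after)
  candidates <- setdiff(ids_after, ids_before)
  keep <- !(id %in% excluded)
  whole <- records[keep, , drop = FALSE]
  partial <- records[keep & before, , drop = FALSE]
  if (length(candidates) == 0) {
    stop("no candidate individuals: every individual has records before ",
         "the cutoff")
  }
  structure(list(whole = whole, partial = partial,
                 candidates = candidates, excluded = excluded,
                 cutoff = cutoff),
            class = "split_plan")
}

#' @export
print.split_plan <- function(x, ...) {
  cat("split_plan: cutoff", x$cutoff, "|", nrow(x$whole), "whole records,",
      nrow(x$partial), "partial records,", length(x$candidates),
      "candidates,", length(x$excluded), "excluded individuals\n")
  invisible(x)
}

#' Method-R cross-validation statistics
#'
#' Compares candidate breeding values estimated from the whole data
#' (`g_whole`) with those from the partial data (`g_partial`):
#' * b0 = mean(g_whole) - mean(g_partial): bias, 0 under unbiasedness;
#' * b1 = Cov(g_whole, g_partial)/Var(g_partial): dispersion, 1 expected;
#' * rho = Pearson correlation: relative gain in accuracy.
#' Sample (n-1) covariances over the candidate set are used.
#'
#' @param g_whole,g_partial named EBV vectors containing the candidates.
#' @param candidates character vector of candidate IDs (size >= 3).
#' @param sigma_a optional additive genetic SD used to express b0 in
#'   genetic-SD units.
#' @return List of class `method_r`: `b0`, `b1`, `rho`, `n`, and
#'   `b0_scaled` when `sigma_a` is given.
#' @export
method_r <- function(g_whole, g_partial, candidates, sigma_a = NULL) {
  candidates <- as.character(candidates)
  if (length(candidates) < 3) stop("need at least 3 candidates")
  miss <- setdiff(candidates, intersect(names(g_whole), names(g_partial)))
  if (length(miss)) stop("candidate(s) missing from EBV vectors: ",
                         paste(utils::head(miss, 5), collapse = ", "))
  gw <- g_whole[candidates]
  gp <- g_partial[candidates]
  vp <- stats::var(gp)
  if (vp == 0) stop("zero variance in partial-data EBV")
  out <- list(b0 = mean(gw) - mean(gp),
              b1 = stats::cov(gw, gp) / vp,
              rho = stats::cor(gw, gp),
              n = length(candidates))
  if (!is.null(sigma_a)) {
    out$b0_scaled <- out$b0 / sigma_a
    out$sigma_a <- sigma_a
  }
  class(out) <- "method_r"
  out
}

#' @export
print.method_r <- function(x, ...) {
  cat(sprintf("method R over %d candidates: b0 = %.4f%s, b1 = %.3f, rho = %.3f\n",
              x$n, x$b0,
              if (!is.null(x$b0_scaled))
                sprintf(" (%.3f sigma_A)", x$b0_scaled) else "",
              x$b1, x$rho))
  invisible(x)
}

#' Predictive ability of corrected phenotypes
#'
#' Pearson correlation of corrected phenotypes y* with predictions yhat,
#' and the OLS regression slope of y* on yhat, over candidate records.
#'
#' @param y_star corrected phenotypes (whole-data fit).
#' @param y_hat predicted corrected observations (partial-data fit).
#' @return List of class `predictive_ability`: `correlation`, `slope`, `n`.
#' @export
predictive_ability <- function(y_star, y_hat) {
  if (length(y_star) != length(y_hat)) stop("vectors differ in length")
  if (length(y_star) < 3) stop("need at least 3 paired records")
  vh <- stats::var(y_hat)
  if (vh == 0) stop("zero variance in predictions")
  structure(list(correlation = stats::cor(y_star, y_hat),
                 slope = stats::cov(y_star, y_hat) / vh,
                 n = length(y_star)),
            class = "predictive_ability")
}

#' @export
print.predictive_ability <- function(x, ...) {
  cat(sprintf("predictive ability over %d records: cor = %.3f, slope = %.3f\n",
              x$n, x$correlation, x$slope))
  invisible(x)
}

#' Write a validation report as JSON
#' @param report list combining `method_r` and `predictive_ability` pieces.
#' @param path output path.
#' @export
write_validation_report <- function(report, path) {
  jsonlite::write_json(lapply(report, unclass), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
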