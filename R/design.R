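#' Specify a genetic model
#'
#' The genetic terms follow the nested ladder A, A+D, A+D+AA, A+D+AA+AD,
#' A+D+AA+AD+DD: dominance requires additive, each epistatic term requires
#' the previous one. The permanent environmental effect is always present
#' for repeated records.
#'
#' @param terms character subset of c("A","D","AA","AD","DD") respecting
#'   the nesting.
#' @param inbreeding_covariate include genomic inbreeding f as a
#'   regression covariate (inbreeding depression)?
#' @param fixed_effects names of the factor columns in the phenotype
#'   records used as fixed effects (default parity and contemporary
#'   group).
#' @return A list of class `model_spec`.
#' @export
model_spec <- function(terms = c("A", "D", "AA", "AD", "DD"),
                       inbreeding_covariate = TRUE,
                       fixed_effects = c("parity", "group")) {
  ladder <- c("A", "D", "AA", "AD", "DD")
  terms <- as.character(terms)
  if (!all(terms %in% ladder)) {
    stop("unknown genetic term(s): ",
         paste(setdiff(terms, ladder), collapse = ", "))
  }
  terms <- ladder[ladder %in% terms]
  k <- length(terms)
  if (!identical(terms, ladder[seq_len(k)])) {
    stop("terms must follow the nesting A, A+D, A+D+AA, A+D+AA+AD, ",
         "A+D+AA+AD+DD")
  }
  if (k == 0) stop("at least the additive term A is required")
  structure(list(terms = terms,
                 inbreeding_covariate = isTRUE(inbreeding_covariate),
                 fixed_effects = fixed_effects),
            class = "model_spec")
}

#' Build the record-level design for a model
#'
#' Constructs the fixed-effect design matrix (intercept plus dummy-coded
#' factors with the first level dropped), the record-to-individual map,
#' and the centered record-level inbreeding covariate.
#'
#' @param records phenotype `data.frame` with columns `id`, `y`, and the
#'   factors named in `spec$fixed_effects`.
#' @param spec a [model_spec()].
#' @param f named per-individual genomic inbreeding vector (required when
#'   `spec$inbreeding_covariate`).
#' @param individuals roster of genotyped individual IDs defining the
#'   order of the genetic-effect vectors (default: `names(f)` or the IDs
#'   appearing in the records).
#' @return A list of class `design_set`: `y`, `X`, `fcov` (centered, or
#'   `NULL`), `id` (1-based individual index per record), `individuals`,
#'   `spec`.
#' @export
build_design <- function(records, spec, f = NULL,
                         individuals = NULL) {
  stopifnot(inherits(spec, "model_spec"))
  if (!all(c("id", "y") %in% names(records))) {
    stop("records must have columns 'id' and 'y'")
  }
  if (is.null(individuals)) {
    individuals <- if (!is.null(f)) names(f) else unique(as.character(records$id))
  }
  id <- match(as.character(records$id), individuals)
  if (anyNA(id)) {
    stop("record(s) refer to unknown individuals: ",
         paste(unique(records$id[is.na(id)]), collapse = ", "))
  }
  X <- matrix(1, nrow(records), 1, dimnames = list(NULL, "(Intercept)"))
  for (fe in spec$fixed_effects) {
    if (!fe %in% names(records)) stop("fixed effect column missing: ", fe)
    fac <- factor(records[[fe]])
    if (nlevels(fac) > 1) {
      D <- stats::model.matrix(~fac)[, -1, drop = FALSE]
      colnames(D) <- paste0(fe, levels(fac)[-1])
      X <- cbind(X, D)
    }
  }
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    drop_cols <- qrX$pivot[-seq_len(qrX$rank)]
    warning("dropping ", length(drop_cols),
            " rank-deficient fixed-effect column(s): ",
            paste(colnames(X)[drop_cols], collapse = ", "))
    X <- X[, -drop_cols, drop = FALSE]
  }
  fcov <- NULL
  if (spec$inbreeding_covariate) {
    if (is.null(f)) stop("inbreeding covariate requested but f not supplied")
    miss <- setdiff(individuals, names(f))
    if (length(miss)) stop("f missing for individuals: ",
                           paste(utils::head(miss, 5), collapse = ", "))
    fcov <- unname(f[individuals][id])
    fcov <- fcov - mean(fcov)
  }
  structure(list(y = as.numeric(records$y), X = X, fcov = fcov, id = id,
                 individuals = individuals, spec = spec),
            class = "design_set")
}
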