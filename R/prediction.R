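#' Solve GBLUP at fixed variance components
#'
#' Builds and solves the mixed-model equations for the declared genetic
#' terms, the permanent environmental effect and the fixed effects
#' (including the inbreeding covariate when present), by a direct dense
#' Cholesky factorization:
#'
#'   (T'T/ve + blockdiag(0, Ginv_t/vt, I/vpe)) sol = T'y/ve
#'
#' where T = \[X | f | Z ... Z | Z\].
#'
#' @param design a [build_design()] result.
#' @param grms named list of regularized `relationship_matrix` objects
#'   covering the design's terms.
#' @param variances named numeric vector/list of fixed variances with
#'   entries for each term plus `pe` and `e`.
#' @param has_pe fit the permanent environmental block (default TRUE).
#' @return Object of class `solution_set`: `beta`, `b` (or `NULL`), `g`
#'   (matrix individuals x terms), `pe`, `variances`, and the relative MME
#'   residual `mme_residual`.
#' @export
solve_gblup <- function(design, grms, variances, has_pe = TRUE) {
  stopifnot(inherits(design, "design_set"))
  terms <- design$spec$terms
  variances <- unlist(variances)
  need <- c(terms, if (has_pe) "pe", "e")
  if (!all(need %in% names(variances))) {
    stop("variances must name: ", paste(need, collapse = ", "))
  }
  if (any(variances[need] <= 0)) stop("fixed variances must be positive")
  n <- length(design$individuals)
  N <- length(design$y)
  ve <- variances[["e"]]

  Z <- matrix(0, N, n)
  Z[cbind(seq_len(N), design$id)] <- 1
  Tmat <- design$X
  if (!is.null(design$fcov)) Tmat <- cbind(Tmat, f = design$fcov)
  p <- ncol(Tmat)
  blocks <- lapply(terms, function(t) Z)
  if (has_pe) blocks <- c(blocks, list(Z))
  Tall <- do.call(cbind, c(list(Tmat), blocks))

  C <- crossprod(Tall) / ve
  off <- p
  for (t in terms) {
    G <- grms[[t]]$values
    if (!identical(dim(G), c(n, n))) {
      stop("GRM for term ", t, " does not match the individual roster")
    }
    Qt <- tryCatch(chol2inv(chol(G)),
                   error = function(err) stop("singular GRM block for term ",
                                              t, ": ", conditionMessage(err)))
    idx <- off + seq_len(n)
    C[idx, idx] <- C[idx, idx] + Qt / variances[[t]]
    off <- off + n
  }
  if (has_pe) {
    idx <- off + seq_len(n)
    C[idx, idx] <- C[idx, idx] + diag(1 / variances[["pe"]], n)
  }
  rhs <- crossprod(Tall, design$y) / ve
  sol <- tryCatch(drop(chol2inv(chol(C)) %*% rhs),
                  error = function(err) stop("singular mixed-model equations: ",
                                             conditionMessage(err)))
  resid <- drop(C %*% sol) - drop(rhs)
  rel_res <- sqrt(sum(resid^2)) / max(sqrt(sum(rhs^2)), .Machine$double.eps)

  beta <- sol[seq_len(ncol(design$X))]
  names(beta) <- colnames(design$X)
  b <- if (!is.null(design$fcov)) sol[ncol(design$X) + 1] else NULL
  off <- p
  gmat <- matrix(0, n, length(terms),
                 dimnames = list(design$individuals, terms))
  for (j in seq_along(terms)) {
    gmat[, j] <- sol[off + seq_len(n)]
    off <- off + n
  }
  pe <- if (has_pe) stats::setNames(sol[off + seq_len(n)],
                                    design$individuals) else NULL
  structure(list(beta = beta, b = b, g = gmat, pe = pe,
                 variances = variances[need], mme_residual = rel_res,
                 spec = design$spec),
            class = "solution_set")
}

#' @export
print.solution_set <- function(x, ...) {
  cat("solution_set:", ncol(x$g), "genetic term(s) over", nrow(x$g),
      "individuals; relative MME residual",
      format(x$mme_residual, digits = 3), "\n")
  invisible(x)
}

#' Corrected phenotypes
#'
#' y* = y - X betahat - f bhat: the record-level phenotype with the fixed
#' effects and the inbreeding-depression regression removed, using
#' whole-data solutions.
#'
#' @param design the [build_design()] result the solutions came from.
#' @param solutions a `solution_set`.
#' @return Numeric vector of corrected phenotypes, one per record.
#' @export
corrected_phenotype <- function(design, solutions) {
  stopifnot(inherits(design, "design_set"), inherits(solutions, "solution_set"))
  ystar <- design$y - as.numeric(design$X %*% solutions$beta)
  if (!is.null(design$fcov)) {
    if (is.null(solutions$b)) stop("design has f but solutions lack bhat")
    ystar <- ystar - design$fcov * solutions$b
  }
  unname(ystar)
}

#' Predicted corrected observations
#'
#' yhat = sum of the estimated genetic values of the declared terms plus
#' the estimated permanent environmental effect, mapped to record level.
#' Individuals with no records in the fitting data carry a zero (prior
#' mean) permanent environmental effect.
#'
#' @param solutions a `solution_set` from the partial-data fit.
#' @param spec the [model_spec()] whose terms to sum (defaults to the
#'   solution's own spec).
#' @param ids character vector of individual IDs, one per record to
#'   predict.
#' @return Numeric vector of predictions aligned with `ids`.
#' @export
predict_observation <- function(solutions, ids, spec = solutions$spec) {
  stopifnot(inherits(solutions, "solution_set"))
  missing_terms <- setdiff(spec$terms, colnames(solutions$g))
  if (length(missing_terms)) {
    stop("solutions lack term(s): ", paste(missing_terms, collapse = ", "))
  }
  idx <- match(as.character(ids), rownames(solutions$g))
  if (anyNA(idx)) {
    stop("unknown individual(s): ",
         paste(unique(ids[is.na(idx)]), collapse = ", "))
  }
  gtot <- rowSums(solutions$g[, spec$terms, drop = FALSE])
  yhat <- gtot[idx]
  if (!is.null(solutions$pe)) yhat <- yhat + solutions$pe[idx]
  unname(yhat)
}

#' Write a solution set as TSV
#' @param solutions a `solution_set`.
#' @param path output path.
#' @export
write_solutions <- function(solutions, path) {
  rows <- data.frame(effect = "fixed", level = names(solutions$beta),
                     estimate = unname(solutions$beta))
  if (!is.null(solutions$b)) {
    rows <- rbind(rows, data.frame(effect = "inbreeding_b", level = "f",
                                   estimate = solutions$b))
  }
  for (t in colnames(solutions$g)) {
    rows <- rbind(rows, data.frame(effect = t, level = rownames(solutions$g),
                                   estimate = solutions$g[, t]))
  }
  if (!is.null(solutions$pe)) {
    rows <- rbind(rows, data.frame(effect = "pe", level = names(solutions$pe),
                                   estimate = unname(solutions$pe)))
  }
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
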