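#' Gibbs chain configuration
#'
#' The reference protocol is 200,000 iterations with a 10,000-iteration
#' burn-in and thinning of 100, retaining 1900 samples. A scaled-down
#' chain (`chain_config(20000, 2000, 10)`) is convenient for continuous
#' testing.
#'
#' @param n_iter total iterations.
#' @param burn_in iterations discarded before retention.
#' @param thin keep every `thin`-th post-burn-in sample.
#' @param seed integer seed applied before sampling (`NULL` to use the
#'   current RNG state).
#' @return A list of class `chain_config`.
#' @export
chain_config <- function(n_iter = 200000, burn_in = 10000, thin = 100,
                         seed = NULL) {
  stopifnot(n_iter > burn_in, thin >= 1)
  structure(list(n_iter = as.integer(n_iter), burn_in = as.integer(burn_in),
                 thin = as.integer(thin),
                 seed = if (is.null(seed)) NULL else as.integer(seed)),
            class = "chain_config")
}

#' Variance priors
#'
#' Scaled-inverse-chi-square priors per variance component. The flat
#' default (S = 0, nu = -2) makes each full-conditional draw equal to
#' (sum of squares)/chisq_{dim + nu} and keeps posterior modes comparable
#' to REML estimates.
#'
#' @param S named numeric vector of scales (recycled default 0).
#' @param nu named numeric vector of degrees of freedom (default -2).
#' @return A list of class `vc_priors`.
#' @export
vc_priors <- function(S = 0, nu = -2) {
  structure(list(S = S, nu = nu), class = "vc_priors")
}

prior_for <- function(priors, comp, field, default) {
  v <- priors[[field]]
  if (!is.null(names(v)) && comp %in% names(v)) return(v[[comp]])
  if (length(v) == 1 && is.null(names(v))) return(v)
  default
}

#' Gibbs sampling of the variance-component model
#'
#' Fits the repeated-record mixed model with the genetic terms declared in
#' the design's [model_spec()], a permanent environmental effect, and
#' optionally the genomic-inbreeding covariate, by single-site Gibbs
#' sampling. Each genomic relationship matrix is inverted once (after
#' regularization) and reused every iteration.
#'
#' @param design a [build_design()] result.
#' @param grms named list of `relationship_matrix` objects covering
#'   `design$spec$terms`, regularized (see [regularize()]).
#' @param priors a [vc_priors()].
#' @param cfg a [chain_config()].
#' @param has_pe fit a permanent environmental effect (default TRUE).
#' @param update_location,update_variances internal switches for
#'   distributional checks: hold location effects or variances fixed at
#'   their initial values.
#' @param init_var optional named starting variances.
#' @param var_floor lower bound preventing absorbing states (1e-12).
#' @return Object of class `posterior_chain`: retained samples of all
#'   variance components, the inbreeding-depression coefficient, fixed
#'   effects and deviance, plus accumulated posterior means of every
#'   location parameter.
#' @export
gibbs_sample <- function(design, grms, priors = vc_priors(),
                         cfg = chain_config(), has_pe = TRUE,
                         update_location = TRUE, update_variances = TRUE,
                         init_var = NULL, var_floor = 1e-12) {
  stopifnot(inherits(design, "design_set"), inherits(cfg, "chain_config"))
  terms <- design$spec$terms
  missing_terms <- setdiff(terms, names(grms))
  if (length(missing_terms)) {
    stop("GRM missing for term(s): ", paste(missing_terms, collapse = ", "))
  }
  n <- length(design$individuals)
  # one eigendecomposition per GRM, reused every iteration: the genetic
  # block is sampled in the eigenbasis where its prior is i.i.d. normal
  Vmats <- lapply(terms, function(t) {
    G <- grms[[t]]$values
    if (!identical(dim(G), c(n, n))) {
      stop("GRM for term ", t, " does not match the individual roster")
    }
    eg <- eigen(G, symmetric = TRUE)
    eg$vectors %*% diag(sqrt(pmax(eg$values, 0)), n)
  })
  comp_names <- c(terms, if (has_pe) "pe", "e")
  dims <- c(rep(n, length(terms)), if (has_pe) n, length(design$y))
  S <- vapply(comp_names, prior_for, numeric(1), priors = priors,
              field = "S", default = 0)
  nu <- vapply(comp_names, prior_for, numeric(1), priors = priors,
               field = "nu", default = -2)
  if (is.null(init_var)) {
    vy <- stats::var(design$y)
    init_var <- stats::setNames(rep(vy / length(comp_names), length(comp_names)),
                                comp_names)
    init_var["e"] <- vy / 2
  } else {
    init_var <- init_var[comp_names]
    if (anyNA(init_var)) stop("init_var must name every component: ",
                              paste(comp_names, collapse = ", "))
  }
  has_f <- !is.null(design$fcov)
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  raw <- gibbs_sampler_cpp(
    y = design$y, X = design$X,
    fcov = if (has_f) design$fcov else numeric(0), has_f = has_f,
    id0 = design$id - 1L, n_ind = n,
    V_list = Vmats, has_pe = has_pe,
    prior_S = unname(S), prior_nu = unname(nu),
    n_iter = cfg$n_iter, burn_in = cfg$burn_in, thin = cfg$thin,
    update_location = update_location, update_variances = update_variances,
    init_var = unname(init_var), var_floor = var_floor)
  vs <- raw$var_samples
  colnames(vs) <- comp_names
  gm <- raw$g_mean
  colnames(gm) <- terms
  rownames(gm) <- design$individuals
  structure(list(
    variances = vs,
    b = if (has_f) as.numeric(raw$b_samples) else NULL,
    beta = structure(raw$beta_samples,
                     dimnames = list(NULL, colnames(design$X))),
    deviance = as.numeric(raw$deviance),
    beta_mean = stats::setNames(as.numeric(raw$beta_mean), colnames(design$X)),
    b_mean = if (has_f) as.numeric(raw$b_mean) else NULL,
    g_mean = gm,
    pe_mean = if (has_pe) stats::setNames(as.numeric(raw$pe_mean),
                                          design$individuals) else NULL,
    fitted_mean = as.numeric(raw$fitted_mean),
    n_retained = raw$n_retained,
    spec = design$spec, has_pe = has_pe, has_f = has_f,
    config = cfg, priors = list(S = S, nu = nu), dims = dims,
    y = design$y
  ), class = "posterior_chain")
}

#' @export
print.posterior_chain <- function(x, ...) {
  cat("posterior_chain:", x$n_retained, "retained samples; components:",
      paste(colnames(x$variances), collapse = ", "), "\n")
  print(round(colMeans(x$variances), 4))
  invisible(x)
}

#' Posterior variance ratios and diagnostics
#'
#' Computes per-sample phenotypic variance (sum of all genetic components,
#' the permanent environmental variance and the residual variance), then
#' the narrow-sense heritability h2 = sigma2_A/sigma2_P, the dominance
#' ratio d2 = sigma2_D/sigma2_P, and the total epistatic ratio i2 (sum of
#' the fitted epistatic variances over sigma2_P), averaged over retained
#' samples with posterior SDs, plus effective sample sizes, DIC and pD.
#'
#' @param chain a `posterior_chain`.
#' @return A list of class `variance_summary` with elements `components`
#'   (mean/sd/ESS per variance), `ratios` (mean/sd of h2, d2, i2 as
#'   available), `b` (mean/sd when fitted), `dic`, `pD`.
#' @export
variance_ratios <- function(chain) {
  stopifnot(inherits(chain, "posterior_chain"))
  vs <- chain$variances
  sigmaP <- rowSums(vs)
  terms <- chain$spec$terms
  ratios <- list(h2 = vs[, "A"] / sigmaP)
  if ("D" %in% terms) ratios$d2 <- vs[, "D"] / sigmaP
  epi <- intersect(c("AA", "AD", "DD"), terms)
  if (length(epi)) {
    ratios$i2 <- rowSums(vs[, epi, drop = FALSE]) / sigmaP
  }
  comp <- data.frame(
    component = colnames(vs),
    mean = colMeans(vs),
    sd = apply(vs, 2, stats::sd),
    ess = apply(vs, 2, effective_sample_size),
    row.names = NULL)
  ratio_tab <- data.frame(
    ratio = names(ratios),
    mean = vapply(ratios, mean, numeric(1)),
    sd = vapply(ratios, stats::sd, numeric(1)),
    row.names = NULL)
  d <- dic(chain)
  out <- list(components = comp, ratios = ratio_tab,
              b = if (chain$has_f) c(mean = mean(chain$b),
                                     sd = stats::sd(chain$b)) else NULL,
              dic = d[["DIC"]], pD = d[["pD"]],
              sigmaP_mean = mean(sigmaP),
              samples = ratios)
  class(out) <- "variance_summary"
  out
}

#' @export
print.variance_summary <- function(x, ...) {
  cat("Variance components (posterior mean +/- SD, ESS):\n")
  print(transform(x$components, mean = round(mean, 4), sd = round(sd, 4),
                  ess = round(ess)))
  cat("\nRatios of phenotypic variance:\n")
  print(transform(x$ratios, mean = round(mean, 4), sd = round(sd, 4)))
  if (!is.null(x$b)) {
    cat(sprintf("\nInbreeding depression b = %.3f +/- %.3f\n",
                x$b["mean"], x$b["sd"]))
  }
  cat(sprintf("\nDIC = %.1f (pD = %.1f)\n", x$dic, x$pD))
  invisible(x)
}

#' Deviance information criterion
#'
#' DIC = Dbar + pD with pD = Dbar - D(thetahat): Dbar is the posterior
#' mean of the conditional deviance -2 log N(y | fitted, sigma2_e) over
#' retained samples, and D(thetahat) evaluates the deviance at the
#' posterior means of all location parameters and of sigma2_e.
#'
#' @param chain a `posterior_chain`.
#' @return Named numeric vector `c(DIC = , pD = )`.
#' @export
dic <- function(chain) {
  stopifnot(inherits(chain, "posterior_chain"))
  Dbar <- mean(chain$deviance)
  ve <- mean(chain$variances[, "e"])
  res <- chain$y - chain$fitted_mean
  N <- length(chain$y)
  Dhat <- N * (log(2 * pi) + log(ve)) + sum(res^2) / ve
  pD <- Dbar - Dhat
  c(DIC = Dbar + pD, pD = pD)
}

#' Effective sample size
#'
#' ESS = S / (1 + 2 * sum of autocorrelations), with the autocorrelation
#' sum truncated by Geyer's initial-positive-sequence rule: consecutive
#' autocorrelation pairs are summed while their pairwise sums stay
#' positive.
#'
#' @param x numeric chain of retained samples (length >= 50 recommended).
#' @return Estimated effective sample size.
#' @export
effective_sample_size <- function(x) {
  S <- length(x)
  if (stats::sd(x) == 0 || S < 4) {
    warning("constant (or too short) chain: reporting nominal sample size")
    return(S)
  }
  maxlag <- min(S - 1, max(50, floor(10 * log10(S)) * 5))
  rho <- stats::acf(x, lag.max = maxlag, plot = FALSE,
                    demean = TRUE)$acf[, 1, 1]
  # rho[1] is lag 0 = 1; pair lags (1,2), (3,4), ... per Geyer
  tau <- 1
  m <- 1
  while (m + 1 <= maxlag) {
    gam <- rho[m + 1] + rho[m + 2]
    if (is.na(gam) || gam <= 0) break
    tau <- tau + 2 * gam
    m <- m + 2
  }
  max(1, S / tau)
}
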