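#' Simulation configuration
#'
#' Defaults emulate a pig maternal-line litter-size study: mean phenotype
#' 12.7 piglets, residual variance 7.05, permanent-environmental variance
#' 0.45, genetic variances (A, D, AA, AD, DD) = (0.84, 0.17, 0.14, 0.12,
#' 0.09), inbreeding depression b = -12.33 phenotype units per unit of
#' genomic inbreeding, sows with 2-6 litters each, biallelic SNPs in
#' Hardy-Weinberg and linkage equilibrium with allele frequencies drawn
#' from Uniform(0.05, 0.95).
#'
#' @param n_individuals number of genotyped individuals (sows).
#' @param m_snps number of SNPs.
#' @param records_range integer range of records per individual
#'   (uniform; default 2:6).
#' @param freq_range allele-frequency range for Uniform sampling.
#' @param inbreeding either 0 (no latent inbreeding) or
#'   `list(shape1=, shape2=, scale=)` for a scaled Beta distribution of
#'   the per-individual latent inbreeding parameter F.
#' @param var_A,var_D,var_AA,var_AD,var_DD,var_pe,var_e target variances.
#' @param b_inbreeding inbreeding-depression regression coefficient.
#' @param mean_phenotype grand mean of the trait.
#' @param n_parities,n_groups number of parity classes and contemporary
#'   (farm-year-month-like) groups.
#' @param parity_sd,group_sd standard deviations of the fixed parity and
#'   contemporary-group effects.
#' @param n_pairs number of random locus pairs carrying each type of
#'   pairwise epistatic effect.
#' @param scaling `"exact"` rescales each generated effect vector so its
#'   realized variance matches the target exactly; `"expected"` scales
#'   only in expectation.
#' @param prop_late proportion of individuals whose records all fall in
#'   the late period block (selection candidates for forward validation).
#' @param n_periods_early,n_periods_late number of record periods in each
#'   block; the late block starts at `n_periods_early + 1`.
#' @param seed integer seed used by [simulate_dataset()].
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_individuals = 1000, m_snps = 2000,
                       records_range = 2:6,
                       freq_range = c(0.05, 0.95),
                       inbreeding = 0,
                       var_A = 0.84, var_D = 0.17, var_AA = 0.14,
                       var_AD = 0.12, var_DD = 0.09,
                       var_pe = 0.45, var_e = 7.05,
                       b_inbreeding = -12.33,
                       mean_phenotype = 12.7,
                       n_parities = 6, n_groups = 25,
                       parity_sd = 0.3, group_sd = 0.5,
                       n_pairs = 5000,
                       scaling = c("exact", "expected"),
                       prop_late = 1 / 3,
                       n_periods_early = 5, n_periods_late = 5,
                       seed = 1L) {
  scaling <- match.arg(scaling)
  vars <- c(var_A, var_D, var_AA, var_AD, var_DD, var_pe, var_e)
  if (any(vars < 0)) stop("target variances must be non-negative")
  structure(as.list(environment()), class = "sim_config")
}

#' Simulate HWE/LE genotypes
#'
#' Per SNP an allele frequency p is drawn from the configured range; each
#' individual with latent inbreeding parameter F draws its genotype with
#' P(A1A1) = p^2 + Fpq, P(het) = 2pq(1-F), P(A2A2) = q^2 + Fpq. Loci are
#' independent (linkage equilibrium).
#'
#' @param cfg a [sim_config()].
#' @return A [genotype_matrix()]; attributes `freqs` (the generating p)
#'   and `latent_F` (the per-individual F) are attached for test harnesses.
#' @export
simulate_genotypes <- function(cfg) {
  n <- cfg$n_individuals; m <- cfg$m_snps
  p <- stats::runif(m, cfg$freq_range[1], cfg$freq_range[2])
  q <- 1 - p
  Fv <- latent_inbreeding(cfg)
  pq <- p * q
  # genotype probabilities as n x m matrices via outer products
  P2 <- matrix(p^2, n, m, byrow = TRUE) + outer(Fv, pq)
  Phet <- outer(1 - Fv, 2 * pq)
  u <- matrix(stats::runif(n * m), n, m)
  codes <- ifelse(u < P2, 2, ifelse(u < P2 + Phet, 1, 0))
  g <- genotype_matrix(codes)
  attr(g, "freqs") <- p
  attr(g, "latent_F") <- Fv
  g
}

latent_inbreeding <- function(cfg) {
  n <- cfg$n_individuals
  ib <- cfg$inbreeding
  if (is.list(ib)) {
    scale <- if (is.null(ib$scale)) 0.3 else ib$scale
    scale * stats::rbeta(n, ib$shape1, ib$shape2)
  } else {
    rep(as.numeric(ib), n)
  }
}

#' Simulate marker effects and true genetic values
#'
#' Allele substitution effects and dominance effects are i.i.d. normal
#' across loci; pairwise epistatic effects are attached to `n_pairs`
#' random locus pairs with incidence equal to the elementwise product of
#' the corresponding centered additive (M) and/or dominance (W) columns,
#' mirroring the orthogonal decomposition the estimator assumes under
#' HWE/LE. Each genetic-value vector is rescaled to its target variance
#' (`scaling = "exact"`) or scaled in expectation (`"expected"`).
#'
#' @param g a [genotype_matrix()] from [simulate_genotypes()].
#' @param cfg a [sim_config()].
#' @return List of class `true_values`: per-individual vectors `g_A`,
#'   `g_D`, `g_AA`, `g_AD`, `g_DD`, realized variances, and `b`.
#' @export
simulate_effects <- function(g, cfg) {
  freqs <- allele_frequencies(g)
  M <- additive_incidence(g, freqs)$values
  W <- dominance_incidence(g, freqs)$values
  n <- nrow(M); m <- ncol(M)
  if (m < 2 && any(c(cfg$var_AA, cfg$var_AD, cfg$var_DD) > 0)) {
    stop("epistatic targets require at least two loci")
  }
  p <- freqs; q <- 1 - p
  exact <- cfg$scaling == "exact"

  main_value <- function(B, target, denom) {
    if (target <= 0) return(numeric(n))
    eff <- stats::rnorm(m, 0, if (exact) 1 else sqrt(target / denom))
    scale_value(drop(B %*% eff), target, exact)
  }
  pair_value <- function(B1, B2, target) {
    if (target <= 0) return(numeric(n))
    k1 <- sample.int(m, cfg$n_pairs, replace = TRUE)
    k2 <- sample.int(m, cfg$n_pairs, replace = TRUE)
    swap <- k1 == k2
    if (any(swap)) k2[swap] <- 1 + (k2[swap] %% m)
    H <- B1[, k1, drop = FALSE] * B2[, k2, drop = FALSE]
    sd0 <- if (exact) 1 else sqrt(target / sum(colMeans(H^2)))
    scale_value(drop(H %*% stats::rnorm(cfg$n_pairs, 0, sd0)), target, exact)
  }

  tv <- list(
    g_A = main_value(M, cfg$var_A, 2 * sum(p * q)),
    g_D = main_value(W, cfg$var_D, 4 * sum((p * q)^2)),
    g_AA = pair_value(M, M, cfg$var_AA),
    g_AD = pair_value(M, W, cfg$var_AD),
    g_DD = pair_value(W, W, cfg$var_DD)
  )
  tv <- lapply(tv, stats::setNames, g$individual_ids)
  tv$realized_variances <- vapply(tv[c("g_A", "g_D", "g_AA", "g_AD", "g_DD")],
                                  stats::var, numeric(1))
  names(tv$realized_variances) <- c("A", "D", "AA", "AD", "DD")
  tv$b <- cfg$b_inbreeding
  class(tv) <- "true_values"
  tv
}

scale_value <- function(v, target, exact) {
  if (!exact) return(v)
  s <- stats::sd(v)
  if (s == 0) stop("cannot rescale a degenerate genetic-value vector")
  v * sqrt(target) / s
}

#' Simulate repeated phenotype records
#'
#' Each individual receives a uniform number of records; record-level
#' phenotype = grand mean + parity effect + contemporary-group effect +
#' b (f_i - mean f) + sum of true genetic values + permanent environment +
#' residual. The inbreeding covariate f is the realized genomic
#' homozygosity of the simulated genotypes, not the latent F. Individuals
#' are split into an early and a late period cohort so that a forward
#' (whole/partial) validation split exists by construction.
#'
#' @param g a [genotype_matrix()].
#' @param true_values a `true_values` list from [simulate_effects()].
#' @param cfg a [sim_config()].
#' @return `data.frame` with columns `id`, `parity`, `group`, `period`,
#'   `y`; attributes `pe`, `f`, `parity_effects`, `group_effects`.
#' @export
simulate_phenotypes <- function(g, true_values, cfg) {
  n <- cfg$n_individuals
  ids <- g$individual_ids
  nrec <- sample(cfg$records_range, n, replace = TRUE)
  id_rec <- rep(seq_len(n), nrec)
  parity <- unlist(lapply(nrec, function(k) pmin(seq_len(k), cfg$n_parities)))
  group <- sample.int(cfg$n_groups, length(id_rec), replace = TRUE)
  late <- stats::runif(n) < cfg$prop_late
  period <- integer(length(id_rec))
  early_periods <- seq_len(cfg$n_periods_early)
  late_periods <- cfg$n_periods_early + seq_len(cfg$n_periods_late)
  period[!late[id_rec]] <- sample(early_periods, sum(!late[id_rec]), TRUE)
  period[late[id_rec]] <- sample(late_periods, sum(late[id_rec]), TRUE)

  parity_eff <- stats::rnorm(cfg$n_parities, 0, cfg$parity_sd)
  group_eff <- stats::rnorm(cfg$n_groups, 0, cfg$group_sd)
  pe <- stats::rnorm(n, 0, sqrt(cfg$var_pe))
  if (cfg$scaling == "exact" && cfg$var_pe > 0) {
    pe <- pe * sqrt(cfg$var_pe) / stats::sd(pe)
  }
  f <- genomic_inbreeding(g)
  gtot <- true_values$g_A + true_values$g_D + true_values$g_AA +
    true_values$g_AD + true_values$g_DD
  e <- stats::rnorm(length(id_rec), 0, sqrt(cfg$var_e))
  y <- cfg$mean_phenotype + parity_eff[parity] + group_eff[group] +
    cfg$b_inbreeding * (f[id_rec] - mean(f)) +
    gtot[id_rec] + pe[id_rec] + e
  rec <- data.frame(id = ids[id_rec], parity = parity, group = group,
                    period = period, y = y, stringsAsFactors = FALSE)
  attr(rec, "pe") <- stats::setNames(pe, ids)
  attr(rec, "f") <- f
  attr(rec, "parity_effects") <- parity_eff
  attr(rec, "group_effects") <- group_eff
  rec
}

#' Simulate a complete dataset
#'
#' Seeds the RNG from `cfg$seed` and runs [simulate_genotypes()],
#' [simulate_effects()] and [simulate_phenotypes()].
#'
#' @param cfg a [sim_config()].
#' @return List with `genotypes`, `records`, `true_values`, `config`.
#' @export
simulate_dataset <- function(cfg) {
  set.seed(cfg$seed)
  g <- simulate_genotypes(cfg)
  tv <- simulate_effects(g, cfg)
  rec <- simulate_phenotypes(g, tv, cfg)
  list(genotypes = g, records = rec, true_values = tv, config = cfg)
}

#' Paper-like simulation scenario
#'
#' Bundles the default study conditions: 1000 sows, 2000 SNPs, litter-size
#' variance targets, directional inbreeding depression, and two period
#' blocks so that a forward validation split exists.
#'
#' @param seed integer seed.
#' @param ... overrides passed to [sim_config()].
#' @return As [simulate_dataset()].
#' @export
scenario_paper_like <- function(seed = 1L, ...) {
  cfg <- sim_config(seed = as.integer(seed), ...)
  simulate_dataset(cfg)
}

#' Write true simulated values as TSV
#' @param true_values a `true_values` list.
#' @param path output path.
#' @export
write_true_values <- function(true_values, path) {
  df <- data.frame(id = names(true_values$g_A),
                   g_A = true_values$g_A, g_D = true_values$g_D,
                   g_AA = true_values$g_AA, g_AD = true_values$g_AD,
                   g_DD = true_values$g_DD)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
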