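test_that("model specs enforce the nested term ladder", {
  expect_equal(model_spec(c("D", "A"))$terms, c("A", "D"))
  expect_error(model_spec(c("A", "AA")), "nesting")
  expect_error(model_spec(c("A", "D", "DD")), "nesting")
  expect_error(model_spec(character(0)), "additive")
  expect_error(model_spec("Z"), "unknown")
})

test_that("design construction dummy-codes factors and centers f", {
  rec <- data.frame(id = c("a", "a", "b", "c"),
                    parity = c(1, 2, 1, 1),
                    group = c("g1", "g2", "g1", "g2"),
                    y = c(10, 11, 12, 13))
  f <- c(a = 0.30, b = 0.20, c = 0.10)
  spec <- model_spec("A")
  des <- build_design(rec, spec, f)
  expect_equal(ncol(des$X), 3)    # intercept + parity2 + groupg2
  expect_equal(des$id, c(1L, 1L, 2L, 3L))
  expect_equal(mean(des$fcov), 0)
  expect_equal(des$fcov[1] - des$fcov[3], 0.1)

  des2 <- build_design(rec, model_spec("A", inbreeding_covariate = FALSE), f)
  expect_null(des2$fcov)

  bad <- rbind(rec, data.frame(id = "zz", parity = 1, group = "g1", y = 1))
  expect_error(build_design(bad, spec, f), "zz")
})

test_that("same seed gives a bit-identical chain", {
  set.seed(201)
  cfg <- recovery_config(201, n = 60, m = 120)
  d <- simulate_dataset(cfg)
  grms <- build_grms(d$genotypes, components = c("A", "D"))
  des <- build_design(d$records, model_spec(c("A", "D")),
                      genomic_inbreeding(d$genotypes),
                      individuals = d$genotypes$individual_ids)
  ch1 <- gibbs_sample(des, grms, cfg = chain_config(400, 100, 2, seed = 9))
  ch2 <- gibbs_sample(des, grms, cfg = chain_config(400, 100, 2, seed = 9))
  expect_identical(ch1$variances, ch2$variances)
  expect_identical(ch1$g_mean, ch2$g_mean)
  expect_identical(ch1$deviance, ch2$deviance)
})

test_that("intercept-only posterior mean matches the closed form", {
  set.seed(211)
  n <- 80
  ids <- paste0("i", 1:n)
  rec <- data.frame(id = ids, y = rnorm(n, 5, 2))
  spec <- model_spec("A", inbreeding_covariate = FALSE,
                     fixed_effects = character(0))
  des <- build_design(rec, spec, individuals = ids)
  grm <- list(A = regularize(structure(
    list(values = diag(n), component = "A", normalization = 1, ids = ids),
    class = "relationship_matrix")))
  ch <- gibbs_sample(des, grm, cfg = chain_config(4000, 500, 2, seed = 3),
                     has_pe = FALSE)
  mu <- ch$beta[, 1]
  mcse <- sd(mu) / sqrt(effective_sample_size(mu))
  expect_lt(abs(mean(mu) - mean(rec$y)), 3 * mcse + 1e-12)
})

test_that("with locations held fixed the residual variance draws follow
           the conjugate scaled chi-square", {
  set.seed(221)
  n <- 2000
  ids <- paste0("i", 1:n)
  rec <- data.frame(id = ids, y = rnorm(n))
  spec <- model_spec("A", inbreeding_covariate = FALSE,
                     fixed_effects = character(0))
  des <- build_design(rec, spec, individuals = ids)
  grm <- list(A = regularize(structure(
    list(values = diag(n), component = "A", normalization = 1, ids = ids),
    class = "relationship_matrix")))
  ch <- gibbs_sample(des, grm, cfg = chain_config(1900, 0, 1, seed = 5),
                     has_pe = FALSE, update_location = FALSE)
  draws <- ch$variances[, "e"]
  sse <- sum(rec$y^2)            # location effects stay at zero
  ref <- sse / rchisq(20000, df = n)
  ks <- suppressWarnings(ks.test(draws, ref))
  expect_gt(ks$p.value, 0.001)
})

test_that("variance ratios partition the phenotypic variance exactly", {
  set.seed(231)
  cfg <- recovery_config(231, n = 60, m = 120)
  d <- simulate_dataset(cfg)
  grms <- build_grms(d$genotypes, components = c("A", "D", "AA"))
  des <- build_design(d$records, model_spec(c("A", "D", "AA")),
                      genomic_inbreeding(d$genotypes),
                      individuals = d$genotypes$individual_ids)
  ch <- gibbs_sample(des, grms, cfg = chain_config(600, 100, 2, seed = 4))
  s <- variance_ratios(ch)
  # per-sample ratios over the same sample's sigma_P sum to one
  sigmaP <- rowSums(ch$variances)
  ratios <- s$samples$h2 + s$samples$d2 + s$samples$i2 +
    ch$variances[, "pe"] / sigmaP + ch$variances[, "e"] / sigmaP
  expect_lt(max(abs(ratios - 1)), 1e-10)
  expect_setequal(s$ratios$ratio, c("h2", "d2", "i2"))

  # A-only model reports no d2/i2
  desA <- build_design(d$records, model_spec("A"),
                       genomic_inbreeding(d$genotypes),
                       individuals = d$genotypes$individual_ids)
  chA <- gibbs_sample(desA, grms["A"], cfg = chain_config(400, 100, 2,
                                                          seed = 4))
  sA <- variance_ratios(chA)
  expect_equal(sA$ratios$ratio, "h2")
})

test_that("DIC reduces to hand arithmetic and degenerates to zero pD on a
           frozen chain", {
  fake <- structure(list(
    deviance = c(100, 102),
    variances = matrix(1 / (2 * pi), 2, 1, dimnames = list(NULL, "e")),
    y = 0, fitted_mean = 0), class = "posterior_chain")
  out <- dic(fake)
  # Dhat = log(2 pi ve) + 0 = 0, Dbar = 101 -> pD = 101, DIC = 202
  expect_equal(unname(out["pD"]), 101)
  expect_equal(unname(out["DIC"]), 202)

  set.seed(241)
  ids <- paste0("i", 1:20)
  rec <- data.frame(id = ids, y = rnorm(20))
  spec <- model_spec("A", inbreeding_covariate = FALSE,
                     fixed_effects = character(0))
  des <- build_design(rec, spec, individuals = ids)
  grm <- list(A = regularize(structure(
    list(values = diag(20), component = "A", normalization = 1, ids = ids),
    class = "relationship_matrix")))
  frozen <- gibbs_sample(des, grm, cfg = chain_config(50, 0, 1, seed = 2),
                         has_pe = FALSE, update_location = FALSE,
                         update_variances = FALSE,
                         init_var = c(A = 1, e = 1))
  out2 <- dic(frozen)
  expect_equal(unname(out2["pD"]), 0, tolerance = 1e-8)
  expect_equal(unname(out2["DIC"]), frozen$deviance[1], tolerance = 1e-8)
})

test_that("effective sample size calibrates on white noise, AR(1) and
           constant chains", {
  set.seed(251)
  ess_wn <- effective_sample_size(rnorm(1900))
  expect_gt(ess_wn, 1500)
  expect_lt(ess_wn, 2300)

  S <- 20000
  rho <- 0.5
  x <- as.numeric(arima.sim(list(ar = rho), S))
  ess_ar <- effective_sample_size(x)
  target <- S * (1 - rho) / (1 + rho)
  expect_lt(abs(ess_ar - target) / target, 0.25)

  expect_warning(ess_const <- effective_sample_size(rep(2, 100)),
                 "constant")
  expect_equal(ess_const, 100)
})

test_that("priors shift the variance full conditional as configured", {
  set.seed(261)
  n <- 50
  ids <- paste0("i", 1:n)
  rec <- data.frame(id = ids, y = rnorm(n))
  spec <- model_spec("A", inbreeding_covariate = FALSE,
                     fixed_effects = character(0))
  des <- build_design(rec, spec, individuals = ids)
  grm <- list(A = regularize(structure(
    list(values = diag(n), component = "A", normalization = 1, ids = ids),
    class = "relationship_matrix")))
  # an informative prior with huge df pins the variance near its scale
  ch <- gibbs_sample(des, grm,
                     priors = vc_priors(S = c(A = 0.5, pe = 0, e = 0),
                                        nu = c(A = 1e6, pe = -2, e = -2)),
                     cfg = chain_config(300, 100, 1, seed = 6),
                     has_pe = FALSE)
  expect_equal(mean(ch$variances[, "A"]), 0.5, tolerance = 0.05)
})
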