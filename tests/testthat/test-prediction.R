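test_that("GBLUP with an identity GRM equals ridge regression", {
  set.seed(301)
  n <- 5
  ids <- paste0("i", 1:n)
  rec <- data.frame(id = ids, y = rnorm(n, 10, 2))
  spec <- model_spec("A", inbreeding_covariate = FALSE,
                     fixed_effects = character(0))
  des <- build_design(rec, spec, individuals = ids)
  grm <- list(A = structure(list(values = diag(n), component = "A",
                                 normalization = 1, ids = ids),
                            class = "relationship_matrix"))
  v <- c(A = 2, e = 4)
  sol <- solve_gblup(des, grm, v, has_pe = FALSE)
  # ridge with lambda = ve/vA on the centered problem
  lambda <- v[["e"]] / v[["A"]]
  X <- matrix(1, n, 1)
  C <- rbind(cbind(crossprod(X), t(X)),
             cbind(X, diag(n) + diag(lambda, n)))
  rhs <- c(crossprod(X, rec$y), rec$y)
  ref <- solve(C, rhs)
  expect_equal(unname(sol$beta), ref[1], tolerance = 1e-10)
  expect_equal(unname(sol$g[, "A"]), ref[-1], tolerance = 1e-10)
})

test_that("MME solutions match the dense-covariance oracle and satisfy the
           equations", {
  set.seed(311)
  for (rep in 1:4) {
    n <- sample(20:60, 1)
    cfg <- recovery_config(300 + rep, n = n, m = 80)
    d <- simulate_dataset(cfg)
    grms <- build_grms(d$genotypes, components = c("A", "D"))
    des <- build_design(d$records, model_spec(c("A", "D")),
                        genomic_inbreeding(d$genotypes),
                        individuals = d$genotypes$individual_ids)
    v <- c(A = 0.8, D = 0.2, pe = 0.6, e = 7)
    sol <- solve_gblup(des, grms, v)
    ref <- dense_blup_oracle(des, grms, v)
    expect_lt(sol$mme_residual, 1e-8)
    expect_equal(unname(sol$g[, "A"]), ref$g$A, tolerance = 1e-6)
    expect_equal(unname(sol$g[, "D"]), ref$g$D, tolerance = 1e-6)
    expect_equal(unname(sol$pe), ref$pe, tolerance = 1e-6)
  }
})

test_that("vanishing genetic and pe variances shrink solutions to GLS", {
  set.seed(321)
  cfg <- recovery_config(321, n = 40, m = 60)
  d <- simulate_dataset(cfg)
  grms <- build_grms(d$genotypes, components = "A")
  des <- build_design(d$records, model_spec("A"),
                      genomic_inbreeding(d$genotypes),
                      individuals = d$genotypes$individual_ids)
  sol <- solve_gblup(des, grms, c(A = 1e-10, pe = 1e-10, e = 7))
  expect_lt(max(abs(sol$g[, "A"])), 1e-6)
  expect_lt(max(abs(sol$pe)), 1e-6)
  Tmat <- cbind(des$X, des$fcov)
  ols <- drop(solve(crossprod(Tmat), crossprod(Tmat, des$y)))
  expect_equal(unname(c(sol$beta, sol$b)), unname(ols), tolerance = 1e-4)
})

test_that("duplicating every record leaves the fixed effects unchanged", {
  set.seed(331)
  cfg <- recovery_config(331, n = 30, m = 50)
  d <- simulate_dataset(cfg)
  grms <- build_grms(d$genotypes, components = "A")
  spec <- model_spec("A")
  f <- genomic_inbreeding(d$genotypes)
  des1 <- build_design(d$records, spec, f,
                       individuals = d$genotypes$individual_ids)
  rec2 <- rbind(d$records, d$records)
  des2 <- build_design(rec2, spec, f,
                       individuals = d$genotypes$individual_ids)
  v <- c(A = 0.8, pe = 0.6, e = 7)
  # doubling all records equals halving the residual variance
  s1 <- solve_gblup(des1, grms, c(A = 0.8, pe = 0.6, e = 3.5))
  s2 <- solve_gblup(des2, grms, v)
  expect_equal(s1$beta, s2$beta, tolerance = 1e-8)
})

test_that("Gibbs posterior means at fixed variances agree with GBLUP", {
  set.seed(341)
  cfg <- recovery_config(341, n = 100, m = 200)
  d <- simulate_dataset(cfg)
  grms <- build_grms(d$genotypes, components = "A")
  des <- build_design(d$records, model_spec("A"),
                      genomic_inbreeding(d$genotypes),
                      individuals = d$genotypes$individual_ids)
  v <- c(A = 0.8, pe = 0.6, e = 7)
  sol <- solve_gblup(des, grms, v)
  ch <- gibbs_sample(des, grms, cfg = chain_config(4000, 500, 2, seed = 8),
                     update_variances = FALSE, init_var = v)
  expect_gt(cor(sol$g[, "A"], ch$g_mean[, "A"]), 0.98)
  mu <- ch$beta[, 1]
  mcse <- sd(mu) / sqrt(effective_sample_size(mu))
  expect_lt(abs(mean(mu) - sol$beta[1]), 4 * mcse + 1e-10)
})

test_that("corrected phenotypes strip exactly the fixed part", {
  set.seed(351)
  cfg <- recovery_config(351, n = 30, m = 50)
  d <- simulate_dataset(cfg)
  grms <- build_grms(d$genotypes, components = "A")
  des <- build_design(d$records, model_spec("A"),
                      genomic_inbreeding(d$genotypes),
                      individuals = d$genotypes$individual_ids)
  sol <- solve_gblup(des, grms, c(A = 0.8, pe = 0.6, e = 7))
  ystar <- corrected_phenotype(des, sol)
  expect_equal(ystar,
               des$y - as.numeric(des$X %*% sol$beta) - des$fcov * sol$b)

  # beta = 0, b = 0 leaves y untouched
  sol0 <- sol
  sol0$beta[] <- 0
  sol0$b <- 0
  expect_equal(corrected_phenotype(des, sol0), des$y)

  # shifting intercept by c and y by -c leaves y* unchanged
  desc <- des
  desc$y <- des$y - 1
  solc <- sol
  solc$beta["(Intercept)"] <- sol$beta["(Intercept)"] - 1
  expect_equal(corrected_phenotype(desc, solc), ystar)
})

test_that("predicted observations sum the declared terms plus pe", {
  g <- matrix(c(1, 2, 3, 10, 20, 30), 3, 2,
              dimnames = list(c("a", "b", "c"), c("A", "D")))
  sol <- structure(list(beta = c(0), b = NULL, g = g,
                        pe = c(a = 0.1, b = 0.2, c = 0),
                        spec = model_spec(c("A", "D"))),
                   class = "solution_set")
  yhat <- predict_observation(sol, ids = c("b", "a", "b"))
  expect_equal(yhat, c(22.2, 11.1, 22.2))
  yA <- predict_observation(sol, ids = "c", spec = model_spec("A"))
  expect_equal(yA, 3)
  expect_error(predict_observation(sol, ids = "a",
                                   spec = model_spec(c("A", "D", "AA"))),
               "AA")
  expect_error(predict_observation(sol, ids = "zz"), "zz")
})

test_that("solutions export as a tidy TSV", {
  set.seed(361)
  cfg <- recovery_config(361, n = 20, m = 40, freq_range = c(0.25, 0.75))
  d <- simulate_dataset(cfg)
  grms <- build_grms(d$genotypes, components = "A")
  des <- build_design(d$records, model_spec("A"),
                      genomic_inbreeding(d$genotypes),
                      individuals = d$genotypes$individual_ids)
  sol <- solve_gblup(des, grms, c(A = 0.8, pe = 0.6, e = 7))
  path <- tempfile(fileext = ".tsv")
  write_solutions(sol, path)
  back <- read.delim(path)
  expect_setequal(unique(back$effect), c("fixed", "inbreeding_b", "A", "pe"))
  expect_equal(back$estimate[back$effect == "A"], unname(sol$g[, "A"]))
})
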