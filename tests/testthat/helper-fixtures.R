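# small in-code fixtures shared across test files

# 3 individuals x 2 SNPs, both loci at p = 0.5; the worked toy used for
# hand-checkable relationship matrices
toy_genotypes <- function() {
  genotype_matrix(rbind(c(2, 0), c(1, 1), c(0, 2)),
                  individual_ids = c("a", "b", "c"),
                  snp_ids = c("s1", "s2"))
}

# random genotype matrix with HWE sampling at uniform frequencies
random_genotypes <- function(n, m, freq_range = c(0.1, 0.9)) {
  p <- runif(m, freq_range[1], freq_range[2])
  codes <- sapply(p, function(pi) rbinom(n, 2, pi))
  genotype_matrix(matrix(codes, n, m))
}

# brute-force relationship matrices by explicit loops (independent oracle)
brute_grm_additive <- function(codes, p) {
  n <- nrow(codes); m <- ncol(codes)
  M <- matrix(0, n, m)
  for (i in seq_len(n)) for (k in seq_len(m)) M[i, k] <- codes[i, k] - 2 * p[k]
  G <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    s <- 0
    for (k in seq_len(m)) s <- s + M[i, k] * M[j, k]
    G[i, j] <- s
  }
  G / (2 * sum(p * (1 - p)))
}

brute_grm_dominance <- function(codes, p) {
  n <- nrow(codes); m <- ncol(codes)
  q <- 1 - p
  W <- matrix(0, n, m)
  for (i in seq_len(n)) for (k in seq_len(m)) {
    W[i, k] <- switch(as.character(codes[i, k]),
                      "2" = -2 * q[k]^2,
                      "1" = 2 * p[k] * q[k],
                      "0" = -2 * p[k]^2)
  }
  G <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    s <- 0
    for (k in seq_len(m)) s <- s + W[i, k] * W[j, k]
    G[i, j] <- s
  }
  G / (4 * sum((p * q)^2))
}

# dense-covariance GLS/BLUP oracle: solves the same model as solve_gblup
# through the inverse of the full record-level covariance matrix
dense_blup_oracle <- function(design, grms, variances, has_pe = TRUE) {
  N <- length(design$y)
  n <- length(design$individuals)
  Z <- matrix(0, N, n)
  Z[cbind(seq_len(N), design$id)] <- 1
  V <- diag(variances[["e"]], N)
  for (t in design$spec$terms) {
    V <- V + variances[[t]] * (Z %*% grms[[t]]$values %*% t(Z))
  }
  if (has_pe) V <- V + variances[["pe"]] * tcrossprod(Z)
  Tmat <- design$X
  if (!is.null(design$fcov)) Tmat <- cbind(Tmat, design$fcov)
  Vi <- solve(V)
  beta <- solve(t(Tmat) %*% Vi %*% Tmat, t(Tmat) %*% Vi %*% design$y)
  r <- design$y - Tmat %*% beta
  g <- lapply(design$spec$terms, function(t) {
    as.numeric(variances[[t]] * grms[[t]]$values %*% t(Z) %*% Vi %*% r)
  })
  names(g) <- design$spec$terms
  pe <- if (has_pe) as.numeric(variances[["pe"]] * t(Z) %*% Vi %*% r) else NULL
  list(beta = as.numeric(beta), g = g, pe = pe)
}

# simulation configuration used by the recovery-style tests: a scaled-down
# sow design with 3 records per sow
recovery_config <- function(seed, n = 300, m = 800, ...) {
  sim_config(n_individuals = n, m_snps = m, records_range = 3:3,
             var_A = 0.8, var_D = 0.2, var_AA = 0.15, var_AD = 0,
             var_DD = 0, var_pe = 0.6, var_e = 7.0,
             b_inbreeding = 0, inbreeding = 0,
             n_groups = 15, seed = seed, ...)
}

test_chain <- function(seed = 1, n_iter = 5000, burn_in = 1000, thin = 5) {
  chain_config(n_iter, burn_in, thin, seed = seed)
}

central_interval <- function(x, level = 0.95) {
  a <- (1 - level) / 2
  stats::quantile(x, c(a, 1 - a), names = FALSE)
}
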