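# Small fully-specified generative setups shared across test files.

# Region with two causal SNPs of controlled mutual r2 plus independent
# extras; used by the heterogeneity tests.
sim_region <- function(n, seed, betas = c(0, 0), r2_snps = 0.1,
                       n_extra = 8) {
  set.seed(seed)
  maf <- 0.3
  g1 <- rbinom(n, 2, maf)
  rho <- sqrt(r2_snps)
  z <- rho * scale(g1) + sqrt(1 - rho^2) * rnorm(n)
  g2 <- as.integer(cut(rank(z, ties.method = "random"),
                       quantile(seq_len(n), c(0, (1 - maf)^2,
                                              1 - maf^2, 1)),
                       include.lowest = TRUE)) - 1L
  extras <- matrix(rbinom(n * n_extra, 2, maf), n, n_extra)
  X <- cbind(g1, g2, extras)
  colnames(X) <- sprintf("snp%02d", seq_len(ncol(X)))
  y <- betas[1] * g1 + betas[2] * g2 + rnorm(n)
  list(y = y, X = X)
}

# Confounded instrumental-variable system: U -> x, U -> y; g a valid
# instrument for x. Used by the MR tests.
sim_mr <- function(n, beta_causal, conf = 1, r2_gx = 0.03, seed = 1) {
  set.seed(seed)
  g <- rbinom(n, 2, 0.3)
  b_gx <- sqrt(r2_gx / (1 - r2_gx) / (2 * 0.3 * 0.7))
  u <- rnorm(n)
  x <- b_gx * g + conf * u + rnorm(n)
  y <- beta_causal * x + conf * u + rnorm(n)
  list(g = g, x = x, y = y)
}
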