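# Shared fixtures and independent oracles used across the test files.

# compound-symmetry matrix built independently of build_case_omega()
cs_matrix <- function(p, off, diag_val = 1) {
  m <- matrix(off, p, p)
  diag(m) <- diag_val
  m
}

# Monte Carlo rejection rate of the Fisher-z test normalized by the
# augmented SE, on data generated through the operational-covariance draw.
# Bivariate data are generated from the operational correlation directly
# (scale does not affect a correlation test).
mc_power_oracle <- function(r, N, dispersion, reps = 10000L, alpha = 0.05) {
  om <- matrix(c(1, r, r, 1), 2, 2)
  sig <- draw_operational_cov(om, dispersion, ndraws = reps, simplify = FALSE)
  rho <- sig[1, 2, ] / sqrt(sig[1, 1, ] * sig[2, 2, ])
  z1 <- matrix(stats::rnorm(N * reps), N)
  z2 <- matrix(stats::rnorm(N * reps), N)
  y <- t(t(z1) * rho) + t(t(z2) * sqrt(1 - rho^2))
  rhat <- vapply(seq_len(reps), function(i) stats::cor(z1[, i], y[, i]),
                 numeric(1))
  crit <- stats::qnorm(1 - alpha / 2) * augmented_se_z(N, dispersion)
  mean(atanh(rhat) > crit)
}
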