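test_that("implied covariance reproduces the population templates", {
  sp <- factor_model_spec(4)
  # loadings .70, residuals .51 imply the 0.49 compound-symmetry matrix
  sig <- implied_cov(list(loadings = rep(0.7, 4),
                          residual_variances = rep(0.51, 4),
                          factor_variance = 1), sp)
  expect_equal(unname(sig), cs_matrix(4, 0.49))

  # zero loadings give a diagonal matrix
  sig0 <- implied_cov(list(loadings = rep(0, 4),
                           residual_variances = rep(0.3, 4),
                           factor_variance = 1), sp)
  expect_equal(unname(sig0), diag(0.3, 4))

  # MIMIC: phi_x = 1, b = .5, lambda = .7, psi = .75 gives cov(X, Yj) = .35
  spm <- factor_model_spec(4, has_predictor = TRUE)
  sigm <- implied_cov(list(loadings = rep(0.7, 4),
                           residual_variances = rep(0.51, 4),
                           structural_coeff = 0.5, predictor_variance = 1,
                           disturbance = 0.75), spm)
  expect_equal(unname(sigm), unname(build_case_omega("case2")))

  expect_error(implied_cov(list(loadings = rep(0.7, 4),
                                residual_variances = rep(-1, 4),
                                factor_variance = 1), sp), "positive")
})

test_that("the ML discrepancy matches hand-computed values and its symmetries", {
  sig <- cs_matrix(4, 0.49)
  expect_equal(fml_discrepancy(sig, sig), 0)

  # S = 2I, Sigma = I, p = 2: F = 0 + 4 - 2 log 2 - 2
  expect_equal(fml_discrepancy(2 * diag(2), diag(2)), 2 - 2 * log(2))

  # permutation invariance
  set.seed(3)
  s <- draw_sample_cov(sig, 100)
  perm <- c(2, 4, 1, 3)
  expect_equal(fml_discrepancy(s, sig),
               fml_discrepancy(s[perm, perm], sig[perm, perm]))

  # non-negative on random draws
  set.seed(4)
  draws <- draw_sample_cov(sig, 40, ndraws = 25, simplify = FALSE)
  expect_true(all(apply(draws, 3, fml_discrepancy, implied = sig) >= 0))

  expect_error(fml_discrepancy(diag(3), diag(2)), "dimension")
})

test_that("ML fit recovers population parameters exactly at perfect fit", {
  # one-factor on the compound-symmetry matrix
  fit <- fit_ml(cs_matrix(4, 0.49), factor_model_spec(4))
  expect_true(fit$converged)
  expect_equal(fit$params$loadings, rep(0.7, 4), tolerance = 1e-6)
  expect_equal(fit$params$residual_variances, rep(0.51, 4), tolerance = 1e-6)
  expect_lt(fit$discrepancy, 1e-10)

  # MIMIC on the five-variable template: b = cov(X,Y)/lambda = .35/.70 = .50
  fitm <- fit_ml(build_case_omega("case2"),
                 factor_model_spec(4, has_predictor = TRUE))
  expect_true(fitm$converged)
  expect_equal(fitm$params$structural_coeff, 0.5, tolerance = 1e-5)
  expect_equal(fitm$params$loadings, rep(0.7, 4), tolerance = 1e-5)
  expect_equal(fitm$params$predictor_variance, 1, tolerance = 1e-5)

  # diagonal input: loadings shrink to ~0, residuals saturate the fit
  fitd <- fit_ml(diag(0.8, 4), factor_model_spec(4))
  expect_lt(max(abs(fitd$params$loadings)), 0.01)
  expect_lt(fitd$discrepancy, 1e-6)
})

test_that("identification conventions imply the same covariance matrix and fit", {
  set.seed(21)
  s <- draw_sample_cov(build_case_omega("case2"), 300)
  dimnames(s) <- dimnames(build_case_omega("case2"))
  fu <- fit_ml(s, factor_model_spec(4, has_predictor = TRUE,
                                    identification = "unit_factor_variance"))
  fm <- fit_ml(s, factor_model_spec(4, has_predictor = TRUE,
                                    identification = "marker_loading"))
  expect_equal(fu$implied, fm$implied, tolerance = 1e-8)
  expect_equal(fu$discrepancy, fm$discrepancy, tolerance = 1e-10)
  # marker convention fixes the first loading at 1
  expect_equal(fm$params$loadings[1], 1)
  # reported parameters reproduce the same implied matrix through implied_cov
  imp_m <- implied_cov(fm$params,
                       factor_model_spec(4, has_predictor = TRUE,
                                         identification = "marker_loading"))
  expect_equal(unname(imp_m), unname(fu$implied), tolerance = 1e-6)
})

test_that("fitted discrepancy is a local minimum", {
  set.seed(31)
  s <- draw_sample_cov(cs_matrix(4, 0.49), 150)
  fit <- fit_ml(s, factor_model_spec(4))
  f0 <- fml_discrepancy(s, fit$implied)
  for (i in 1:20) {
    lam <- fit$params$loadings + rnorm(4, 0, 0.02)
    res <- fit$params$residual_variances * exp(rnorm(4, 0, 0.02))
    imp <- tcrossprod(lam) + diag(res)
    expect_gte(fml_discrepancy(s, imp), f0 - 1e-10)
  }
})

test_that("regression score weights match the closed-form and normal-equation oracles", {
  fit <- fit_ml(cs_matrix(4, 0.49), factor_model_spec(4))
  w <- fit$score_weights
  # closed-form: compound symmetry 0.51 I + 0.49 J has row sums 2.47,
  # so each weight is 0.70 / 2.47
  expect_equal(w, rep(0.7 / 2.47, 4), tolerance = 1e-6)
  expect_equal(round(w, 4), rep(0.2834, 4))

  # normal equations: Sigma w = lambda var(theta)
  expect_equal(as.vector(fit$implied %*% w), fit$params$loadings,
               tolerance = 1e-6)

  # invariance under permutation of exchangeable indicators
  expect_equal(w, w[c(4, 1, 3, 2)])

  # near-single-indicator limit: dominant indicator takes nearly all weight
  sig1 <- implied_cov(list(loadings = c(0.99, 0.05, 0.05),
                           residual_variances = c(0.02, 0.997, 0.997),
                           factor_variance = 1), factor_model_spec(3))
  f1 <- fit_ml(sig1, factor_model_spec(3))
  expect_gt(f1$score_weights[1] / sum(abs(f1$score_weights)), 0.9)
})

test_that("fit summaries serialize to JSON and back", {
  fit <- fit_ml(cs_matrix(4, 0.49), factor_model_spec(4))
  js <- jsonlite::toJSON(list(params = fit$params,
                              discrepancy = fit$discrepancy,
                              converged = fit$converged),
                         auto_unbox = TRUE, digits = NA)
  back <- jsonlite::fromJSON(js)
  expect_equal(back$params$loadings, fit$params$loadings)
  expect_true(back$converged)
})
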