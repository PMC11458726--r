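test_that("Fisher z transform and its inverse behave", {
  expect_equal(fisher_z(0), 0)
  expect_equal(round(fisher_z(0.25), 4), 0.2554)
  expect_equal(fisher_z_inv(fisher_z(0.7)), 0.7, tolerance = 1e-12)
  rs <- seq(-0.95, 0.95, by = 0.05)
  expect_equal(fisher_z_inv(fisher_z(rs)), rs, tolerance = 1e-12)
  expect_error(fisher_z(1), "< 1")
})

test_that("augmented SE has the right value, asymptote and exact TAUF ratio", {
  expect_equal(augmented_se_z(103, 0), 0.1)
  expect_equal(round(augmented_se_z(124, 0.0064), 4), 0.1215)
  # asymptote sqrt(1/m)
  expect_equal(augmented_se_z(1e9, 0.0064), 0.08, tolerance = 1e-6)
  expect_equal(augmented_se_z(1e9, 0.0025), 0.05, tolerance = 1e-6)
  # algebraic identity: augmented / traditional = tauf, on a grid
  for (N in c(4, 10, 47, 124, 533, 10000)) {
    for (d in c(0, 0.0025, 0.0064, 0.02)) {
      expect_equal(augmented_se_z(N, d) / sqrt(1 / (N - 3)), tauf(d, N),
                   tolerance = 1e-12)
    }
  }
  expect_error(augmented_se_z(3, 0.0064), "N must be")
})

test_that("traditional sample sizes match the reference calculations", {
  expect_equal(required_n_traditional(0.25)$n1, 124L)
  expect_equal(required_n_traditional(0.40)$n1, 47L)
  # tiny effect needs close to 20,000 observations
  n002 <- required_n_traditional(0.02)$n1
  expect_gt(n002, 19500)
  expect_lt(n002, 19700)
  # r near 1 collapses to the minimum supported N
  expect_lt(required_n_traditional(0.999)$n1_unrounded, 4.1)
  expect_error(required_n_traditional(-0.2), "r_alt")
})

test_that("power at the traditional N drops to the published values under adventitious error", {
  n25 <- required_n_traditional(0.25)$n1_unrounded
  n40 <- required_n_traditional(0.40)$n1_unrounded
  expect_equal(round(power_with_ae(0.25, n25, 0.0064), 2), 0.55)
  expect_equal(round(power_with_ae(0.40, n40, 0.0064), 2), 0.69)
  # no adventitious error: the defining equation returns the target power
  expect_equal(power_with_ae(0.25, n25, 0), 0.80, tolerance = 1e-10)
  expect_equal(power_with_ae(0.40, n40, 0), 0.80, tolerance = 1e-10)
  # monotone: increasing in N, decreasing in dispersion
  expect_true(all(diff(power_with_ae(0.3, c(50, 100, 400, 2000), 0.0064)) > 0))
  expect_true(all(diff(sapply(c(0, 0.0025, 0.0064, 0.02),
                              function(d) power_with_ae(0.3, 200, d))) < 0))
})

test_that("corrected sample sizes follow the scale-up identity", {
  n25 <- required_n_traditional(0.25)$n1_unrounded
  n40 <- required_n_traditional(0.40)$n1_unrounded
  expect_equal(required_n_adventitious(n25, 0.0064)$n2, 533L)
  expect_equal(required_n_adventitious(n40, 0.0064)$n2, 65L)
  # dispersion 0 is the identity
  expect_equal(required_n_adventitious(n25, 0)$n2_unrounded, n25)
  # inversion: power at the corrected unrounded N equals the target
  for (r in c(0.25, 0.3, 0.4)) {
    n1 <- required_n_traditional(r)$n1_unrounded
    n2 <- required_n_adventitious(n1, 0.0064)$n2_unrounded
    expect_equal(power_with_ae(r, n2, 0.0064), 0.80, tolerance = 1e-9)
  }
  # below the attainability threshold there is no finite solution
  n1_small <- required_n_traditional(0.10)$n1_unrounded
  res <- required_n_adventitious(n1_small, 0.0064)
  expect_false(res$attainable)
  expect_true(is.na(res$n2))
})

test_that("attainability and significance thresholds match the benchmark values", {
  th64 <- power_threshold_r(0.0064)
  expect_equal(round(th64$z_threshold, 3), 0.224)
  expect_equal(round(th64$r_threshold, 3), 0.220)
  expect_equal(round(power_threshold_r(0.0025)$r_threshold, 3), 0.139)
  # rounded-quantile compatibility mode uses 0.84 for the power term
  th_rounded <- power_threshold_r(0.0064, exact_quantile = FALSE)
  expect_equal(th_rounded$z_threshold, (0.84 + qnorm(0.975)) * 0.08)
  expect_equal(round(th_rounded$z_threshold, 3), 0.224)

  expect_equal(round(significance_threshold(0.0064)$z_threshold, 3), 0.157)
  expect_equal(round(significance_threshold(0.0025)$z_threshold, 3), 0.098)
  expect_equal(significance_threshold(0)$z_threshold, 0)
})

test_that("asymptotic confidence intervals cannot beat the dispersion floor", {
  expect_equal(round(asymptotic_ci(0.25, 0.0064), 3),
               c(lower = 0.098, upper = 0.390))
  expect_equal(round(asymptotic_ci(0.25, 0.0025), 3),
               c(lower = 0.156, upper = 0.339))
  ci0 <- asymptotic_ci(0, 0.01)
  expect_equal(unname(ci0[1]), -unname(ci0[2]))
})

test_that("the curve table is internally consistent and flags unattainable cells", {
  tab <- figure3_curves(c(0.02, 0.1, 0.22, 0.25, 0.4),
                        dispersions = c(0, 0.0064))
  d0 <- tab[tab$dispersion == 0, ]
  expect_equal(d0$n1_unrounded,
               required_n_traditional(d0$r)$n1_unrounded)
  expect_equal(d0$n2_unrounded, d0$n1_unrounded)
  d64 <- tab[tab$dispersion == 0.0064, ]
  # below r = .220 the corrected N does not exist
  expect_false(any(d64$attainable[d64$r < 0.22]))
  expect_true(all(d64$attainable[d64$r > 0.22]))
  # n2 decreasing in r where defined
  expect_true(all(diff(d64$n2[d64$attainable]) < 0))
})

test_that("the full power analysis assembles the pieces coherently", {
  pa <- power_analysis(0.25, 0.0064)
  expect_equal(pa$n1, 124L)
  expect_equal(pa$n2, 533L)
  expect_equal(pa$se_asymptote, 0.08)
  expect_equal(pa$se_augmented / pa$se_traditional,
               tauf(0.0064, pa$n1_unrounded))
  expect_output(print(pa), "533")
})
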