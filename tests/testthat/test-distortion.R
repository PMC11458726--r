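test_that("RMSEA / dispersion / df conversions are mutually consistent", {
  sp <- rmsea_to_spec(0.08)
  expect_equal(sp$dispersion, 0.0064)
  expect_equal(sp$df, 156.25)
  expect_equal(sp$rmsea_equiv, 0.08)

  expect_equal(rmsea_to_spec(0.05)$dispersion, 0.0025)

  sp0 <- rmsea_to_spec(0)
  expect_equal(sp0$dispersion, 0)
  expect_identical(sp0$df, Inf)

  # round trip on a grid
  for (r in c(0.01, 0.03, 0.08, 0.3)) {
    sp <- rmsea_to_spec(r)
    expect_equal(sp$dispersion * sp$df, 1)
    expect_equal(sp$rmsea_equiv, r)
  }

  expect_error(rmsea_to_spec(-0.1), "rmsea")
  expect_error(adventitious_spec(-1), "non-negative")
})

test_that("the augmented uncertainty factor matches its closed form and limits", {
  expect_equal(round(tauf(0.0064, 200), 2), 1.51)
  expect_equal(round(tauf(0.0064, 1000), 2), 2.72)
  expect_equal(tauf(0, 200), 1)
  expect_equal(tauf(0, 17), 1)

  # monotone in both arguments
  ds <- c(0.001, 0.0025, 0.0064, 0.02)
  expect_true(all(diff(sapply(ds, tauf, N = 300)) > 0))
  expect_true(all(diff(tauf(0.0064, c(10, 50, 200, 1000, 5000))) > 0))

  expect_error(tauf(0.0064, 1), "N must be")
})

test_that("operational draws are positive definite, reproducible, and centred per the IW mean", {
  om <- build_case_omega("part3")
  set.seed(101)
  draws <- draw_operational_cov(om, 0.0064, ndraws = 200, simplify = FALSE)
  expect_true(all(apply(draws, 3, function(s) !inherits(try(chol(s), silent = TRUE), "try-error"))))
  expect_true(all(apply(draws, 3, isSymmetric)))

  # bit-reproducibility under the same seed
  set.seed(101)
  draws2 <- draw_operational_cov(om, 0.0064, ndraws = 200, simplify = FALSE)
  expect_identical(draws, draws2)

  # IW mean m*Omega/(m - p - 1): p = 2, Omega = I, m = 100 gives diag 100/97
  set.seed(5)
  d2 <- draw_operational_cov(diag(2), adventitious_spec(1 / 100),
                             ndraws = 20000, simplify = FALSE)
  diag_mean <- mean(c(d2[1, 1, ], d2[2, 2, ]))
  expect_equal(diag_mean, 100 / 97, tolerance = 0.01)

  # dispersion 0 passes omega through unchanged
  expect_equal(draw_operational_cov(om, 0), om, ignore_attr = TRUE)

  expect_error(draw_operational_cov(om, adventitious_spec(1 / 2)), "df")
  expect_error(draw_operational_cov(matrix(c(1, 2, 2, 1), 2), 0.01),
               "positive definite")
})

test_that("sample covariance draws are unbiased Wishart draws with the right spread", {
  set.seed(7)
  draws <- draw_sample_cov(diag(2), N = 50, ndraws = 10000, simplify = FALSE)
  expect_equal(apply(draws, c(1, 2), mean), diag(2), tolerance = 0.02,
               ignore_attr = TRUE)

  # var of the (1,1) element is 2 sigma^4 / n = 0.2 at n = 10, sigma = I
  set.seed(8)
  d10 <- draw_sample_cov(diag(2), N = 11, ndraws = 20000, simplify = FALSE)
  expect_equal(var(d10[1, 1, ]), 0.2, tolerance = 0.015)

  # consistency: huge N draw close to sigma
  om <- build_case_omega("case1")
  set.seed(9)
  s <- draw_sample_cov(om, N = 2e5)
  expect_equal(s, om, tolerance = 0.02, ignore_attr = TRUE)

  expect_error(draw_sample_cov(diag(2), N = 1), "N must be")
})

test_that("average absolute distortion scales with the dispersion and vanishes at zero", {
  om <- cs_matrix(4, 0.49)
  set.seed(11)
  mad1 <- mean_abs_deviation_study(om, 0.0064, reps = 600)
  mad4 <- mean_abs_deviation_study(om, 4 * 0.0064, reps = 600)
  # IW spread scales like sqrt(dispersion): 4x dispersion ~ 2x deviation
  expect_equal(as.numeric(mad4) / as.numeric(mad1), 2, tolerance = 0.2)
  expect_equal(as.numeric(mean_abs_deviation_study(om, 0, reps = 10)), 0)

  # invariant under relabeling for exchangeable omega
  set.seed(12)
  m_a <- mean_abs_deviation_study(om, 0.0064, reps = 800)
  perm <- c(3, 1, 4, 2)
  set.seed(13)
  m_b <- mean_abs_deviation_study(om[perm, perm], 0.0064, reps = 800)
  expect_equal(as.numeric(m_a), as.numeric(m_b), tolerance = 0.05)

  expect_error(mean_abs_deviation_study(om, 0.0064, reps = 0), "reps")
})

test_that("case templates carry the stated population values", {
  c1 <- build_case_omega("case1")
  expect_equal(dim(c1), c(2L, 2L))
  expect_equal(c1[1, 2], 0.25)

  c2 <- build_case_omega("case2")
  expect_equal(dim(c2), c(5L, 5L))
  expect_equal(unname(c2[1, 2:5]), rep(0.35, 4))
  expect_equal(unname(c2[2, 3]), 0.49)   # 0.70 * 0.70
  expect_equal(unname(diag(c2)), rep(1, 5))

  p3 <- build_case_omega("part3")
  expect_equal(unname(p3), cs_matrix(4, 0.49))

  expect_error(build_case_omega("case9"))
})

test_that("covariance matrices round-trip through CSV and JSON", {
  om <- build_case_omega("case2")
  csv <- tempfile(fileext = ".csv")
  write_cov_csv(om, csv)
  back <- read_cov_csv(csv)
  expect_equal(back, om)
  expect_equal(colnames(back), c("X", paste0("Y", 1:4)))

  js <- cov_to_json(om)
  expect_equal(cov_from_json(js), om)
  unlink(csv)
})

test_that("derived child seeds are pure, distinct and valid R seeds", {
  s1 <- derive_seed(1L, 1L)
  expect_identical(s1, derive_seed(1L, 1L))
  seeds <- vapply(1:50, function(k) derive_seed(123L, k), integer(1))
  expect_equal(anyDuplicated(seeds), 0L)
  expect_true(all(seeds >= 0 & seeds < 2^31))
})
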