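## Fisher-z power and sample-size machinery under adventitious error.
##
## Conventions: tests are evaluated one-tailed at alpha/2 (the chance of a
## significant result in the wrong direction is ignored), matching the usual
## power-analysis treatment of a two-sided alpha = .05 test of a positive
## correlation.  N is treated as real-valued internally; ceilings are only
## applied to the reported integer sample sizes.

#' Fisher z transformation
#'
#' `fisher_z(r) = atanh(r)`; `fisher_z_inv()` is `tanh()`.
#'
#' @param r correlation, `|r| < 1`.
#' @param z value on the Fisher z scale.
#' @return The transformed value (vectorized).
#' @export
fisher_z <- function(r) {
  if (any(abs(r) >= 1)) stop("|r| must be < 1", call. = FALSE)
  atanh(r)
}

#' @rdname fisher_z
#' @export
fisher_z_inv <- function(z) tanh(z)

#' Augmented standard error on the Fisher z scale
#'
#' Without adventitious error the SE of `z(r)` is `sqrt(1/(N - 3))`.  With
#' adventitious dispersion `1/m` it becomes
#' \deqn{\sqrt{\frac{N-1}{N-3}\,\frac{1}{m} + \frac{1}{N-3}},}
#' whose ratio to the traditional SE equals the augmented uncertainty factor
#' [tauf()] exactly, and which tends to `sqrt(1/m)` (not zero) as `N` grows.
#'
#' @param N sample size, at least 4; real values are allowed.
#' @param dispersion adventitious dispersion `1/m` (or [adventitious_spec()]).
#' @return The augmented SE (vectorized over `N`).
#' @examples
#' augmented_se_z(103, 0)        # 0.1
#' augmented_se_z(1e9, 0.0064)   # ~0.08, the asymptote sqrt(1/m)
#' @export
augmented_se_z <- function(N, dispersion) {
  spec <- as_spec(dispersion)
  if (any(N < 4)) stop("N must be >= 4", call. = FALSE)
  sqrt(((N - 1) / (N - 3)) * spec$dispersion + 1 / (N - 3))
}

z_power <- function(target_power, exact_quantile = TRUE) {
  if (exact_quantile) stats::qnorm(target_power) else
    round(stats::qnorm(target_power), 2)
}

#' Sample size required for a correlation, ignoring adventitious error
#'
#' Solves `z(r) * sqrt(N - 3) = z_{1 - alpha/2} + z_{power}` for `N`: the
#' usual Fisher-z sample-size formula for one-tailed power at `alpha/2`.
#'
#' @param r_alt alternative-hypothesis correlation, positive.
#' @param alpha two-sided significance level (default .05; the test is
#'   assessed one-tailed at `alpha/2`).
#' @param target_power desired power (default .80).
#' @return List with `n1_unrounded` (real solution) and `n1` (ceiling).
#' @examples
#' required_n_traditional(0.25)$n1   # 124
#' required_n_traditional(0.40)$n1   # 47
#' @export
required_n_traditional <- function(r_alt, alpha = 0.05, target_power = 0.80) {
  if (any(r_alt <= 0) || any(r_alt >= 1))
    stop("r_alt must be in (0, 1)", call. = FALSE)
  zc <- stats::qnorm(1 - alpha / 2) + z_power(target_power)
  n <- pmax(3 + (zc / fisher_z(r_alt))^2, 4)
  list(n1_unrounded = n, n1 = as.integer(ceiling(n)))
}

#' Power with the adventitious-error-augmented standard error
#'
#' One-tailed power `Phi(z(r) / SE_aug - z_{1 - alpha/2})` where `SE_aug` is
#' [augmented_se_z()]; the rejection region in the wrong direction is
#' ignored (set `two_sided_regions = TRUE` to add it).
#'
#' @inheritParams augmented_se_z
#' @param r alternative-hypothesis correlation.
#' @param alpha two-sided significance level.
#' @param two_sided_regions also count rejections in the negative tail?
#' @return The power (vectorized).
#' @examples
#' n1 <- required_n_traditional(0.25)$n1_unrounded
#' power_with_ae(0.25, n1, 0.0064)   # .55: the .80 design is overoptimistic
#' @export
power_with_ae <- function(r, N, dispersion, alpha = 0.05,
                          two_sided_regions = FALSE) {
  se <- augmented_se_z(N, dispersion)
  zc <- stats::qnorm(1 - alpha / 2)
  pw <- stats::pnorm(fisher_z(r) / se - zc)
  if (two_sided_regions) pw <- pw + stats::pnorm(-fisher_z(r) / se - zc)
  pw
}

#' Sample size required when adventitious error is considered
#'
#' Scales the unrounded traditional requirement `N1` up so the augmented SE
#' at `N2` equals the traditional SE at `N1`:
#' \deqn{N_2 = \frac{N_1 - (N_1 - 3)(1/m)}{1 - (N_1 - 3)(1/m)}.}
#' When `(N1 - 3) / m >= 1` the two SEs cannot be equal at any positive
#' `N2` — the target power is unattainable at any sample size — and the
#' result is flagged with `attainable = FALSE` and `NA` sample sizes.
#'
#' @param n1_unrounded unrounded traditional sample size (from
#'   [required_n_traditional()]).
#' @param dispersion adventitious dispersion `1/m` (or [adventitious_spec()]).
#' @return List with `n2_unrounded`, `n2` (ceiling) and `attainable`.
#' @examples
#' n1 <- required_n_traditional(0.25)$n1_unrounded
#' required_n_adventitious(n1, 0.0064)$n2   # 533 (up from 124)
#' @export
required_n_adventitious <- function(n1_unrounded, dispersion) {
  spec <- as_spec(dispersion)
  denom <- 1 - (n1_unrounded - 3) * spec$dispersion
  att <- denom > 0
  n2 <- ifelse(att,
               (n1_unrounded - (n1_unrounded - 3) * spec$dispersion) / denom,
               NA_real_)
  list(n2_unrounded = n2,
       n2 = ifelse(att, as.integer(ceiling(n2)), NA_integer_),
       attainable = att)
}

#' Smallest correlation for which a power target is attainable
#'
#' As `N` grows, the augmented SE tends to `sqrt(1/m)`, so power at any
#' sample size is capped.  The target power is attainable only when the
#' Fisher z of the alternative correlation exceeds
#' `(z_{power} + z_{1 - alpha/2}) * sqrt(1/m)`.
#'
#' @inheritParams required_n_adventitious
#' @param target_power desired power.
#' @param alpha two-sided significance level.
#' @param exact_quantile use the exact normal quantile for the power term
#'   (0.8416 at power .80); `FALSE` uses the conventional rounded 0.84,
#'   which changes the third decimal of the z-scale threshold.
#' @return List with `z_threshold` and `r_threshold`.
#' @examples
#' power_threshold_r(0.0064)$r_threshold   # .220
#' power_threshold_r(0.0025)$r_threshold   # .139
#' @export
power_threshold_r <- function(dispersion, target_power = 0.80, alpha = 0.05,
                              exact_quantile = TRUE) {
  spec <- as_spec(dispersion)
  zt <- (z_power(target_power, exact_quantile) + stats::qnorm(1 - alpha / 2)) *
    sqrt(spec$dispersion)
  list(z_threshold = zt, r_threshold = fisher_z_inv(zt))
}

#' Smallest correlation that can ever reach significance
#'
#' The augmented SE is bounded below by its `N -> Inf` limit `sqrt(1/m)`, so
#' an observed correlation whose Fisher z falls below
#' `z_{1 - alpha/2} * sqrt(1/m)` cannot lead to rejection of the null in a
#' single study of any size.  The z-scale value is the headline number (the
#' benchmark thresholds .157 and .098 are on the z scale); the tanh
#' back-transform is reported alongside.
#'
#' @inheritParams power_threshold_r
#' @return List with `z_threshold` and `r_threshold`.
#' @examples
#' significance_threshold(0.0064)$z_threshold   # 0.157
#' @export
significance_threshold <- function(dispersion, alpha = 0.05) {
  spec <- as_spec(dispersion)
  zt <- stats::qnorm(1 - alpha / 2) * sqrt(spec$dispersion)
  list(z_threshold = zt, r_threshold = fisher_z_inv(zt))
}

#' Narrowest achievable confidence interval for a correlation
#'
#' With adventitious error the SE of `z(r)` cannot fall below `sqrt(1/m)`,
#' so no sample size yields a CI narrower than
#' `tanh(atanh(r) +/- z * sqrt(1/m))`.
#'
#' @param r_obs observed correlation.
#' @param dispersion adventitious dispersion `1/m` (or [adventitious_spec()]).
#' @param level confidence level (default .95).
#' @return Numeric vector `c(lower, upper)` on the correlation scale.
#' @examples
#' asymptotic_ci(0.25, 0.0064)   # [.098, .390]
#' @export
asymptotic_ci <- function(r_obs, dispersion, level = 0.95) {
  spec <- as_spec(dispersion)
  zc <- stats::qnorm((1 + level) / 2)
  ci <- fisher_z_inv(fisher_z(r_obs) + c(-1, 1) * zc * sqrt(spec$dispersion))
  names(ci) <- c("lower", "upper")
  ci
}

#' Full power analysis for one correlation
#'
#' Convenience wrapper combining the traditional and adventitious-error
#' sample sizes, the power shortfall at the traditional `N`, the SE
#' asymptote and attainability/significance thresholds, and the narrowest
#' achievable CI at `r_alt`.
#'
#' @inheritParams required_n_traditional
#' @param dispersion adventitious dispersion `1/m` (or [adventitious_spec()]).
#' @param level confidence level for the asymptotic CI.
#' @return A `power_result` object.
#' @examples
#' power_analysis(0.25, 0.0064)
#' @export
power_analysis <- function(r_alt, dispersion, alpha = 0.05,
                           target_power = 0.80, level = 0.95) {
  spec <- as_spec(dispersion)
  n1 <- required_n_traditional(r_alt, alpha, target_power)
  n2 <- required_n_adventitious(n1$n1_unrounded, spec)
  structure(
    list(r_alt = r_alt, dispersion = spec$dispersion, alpha = alpha,
         target_power = target_power,
         n1_unrounded = n1$n1_unrounded, n1 = n1$n1,
         n2_unrounded = n2$n2_unrounded, n2 = n2$n2,
         attainable = n2$attainable,
         power_at_n1_with_ae = power_with_ae(r_alt, n1$n1_unrounded, spec, alpha),
         se_traditional = sqrt(1 / (n1$n1_unrounded - 3)),
         se_augmented = augmented_se_z(n1$n1_unrounded, spec),
         se_asymptote = sqrt(spec$dispersion),
         power_threshold = power_threshold_r(spec, target_power, alpha),
         significance_threshold = significance_threshold(spec, alpha),
         ci_level = level,
         ci_asymptotic = asymptotic_ci(r_alt, spec, level)),
    class = "power_result")
}

#' @export
print.power_result <- function(x, ...) {
  cat("Power analysis under adventitious error\n")
  cat(sprintf("  r_alt = %.3f, dispersion 1/m = %g, alpha = %g (one-tailed at alpha/2), target power = %g\n",
              x$r_alt, x$dispersion, x$alpha, x$target_power))
  cat(sprintf("  N ignoring adventitious error : %d (unrounded %.2f)\n",
              x$n1, x$n1_unrounded))
  if (isTRUE(x$attainable)) {
    cat(sprintf("  N considering it              : %d (unrounded %.2f)\n",
                x$n2, x$n2_unrounded))
  } else {
    cat("  N considering it              : unattainable at any sample size\n")
  }
  cat(sprintf("  power at traditional N        : %.3f\n", x$power_at_n1_with_ae))
  cat(sprintf("  SE asymptote sqrt(1/m)        : %.3f\n", x$se_asymptote))
  cat(sprintf("  attainability threshold       : z %.3f / r %.3f\n",
              x$power_threshold$z_threshold, x$power_threshold$r_threshold))
  cat(sprintf("  significance threshold        : z %.3f / r %.3f\n",
              x$significance_threshold$z_threshold,
              x$significance_threshold$r_threshold))
  cat(sprintf("  narrowest %g%% CI at r_alt     : [%.3f, %.3f]\n",
              100 * x$ci_level, x$ci_asymptotic[1], x$ci_asymptotic[2]))
  invisible(x)
}

#' Required-sample-size and power curves over a correlation grid
#'
#' For every combination of `r` in `r_grid` and dispersion in `dispersions`,
#' tabulates the traditional sample size `n1`, the power actually achieved
#' at `n1` once adventitious error is considered, and the corrected sample
#' size `n2` (NA where the target power is unattainable at any `N`).
#'
#' @param r_grid correlations in (0, 1).
#' @param dispersions adventitious dispersions (0 allowed).
#' @param target_power desired power.
#' @param alpha two-sided significance level.
#' @param path optional CSV output path.
#' @return A data frame with one row per (r, dispersion) pair.
#' @export
figure3_curves <- function(r_grid, dispersions = c(0, 0.0025, 0.0064),
                           target_power = 0.80, alpha = 0.05, path = NULL) {
  if (any(r_grid <= 0) || any(r_grid >= 1))
    stop("r_grid must lie in (0, 1)", call. = FALSE)
  rows <- lapply(dispersions, function(d) {
    n1 <- required_n_traditional(r_grid, alpha, target_power)
    n2 <- required_n_adventitious(n1$n1_unrounded, d)
    data.frame(r = r_grid, dispersion = d,
               n1_unrounded = n1$n1_unrounded, n1 = n1$n1,
               power_at_n1_with_ae =
                 power_with_ae(r_grid, n1$n1_unrounded, d, alpha),
               n2_unrounded = n2$n2_unrounded, n2 = n2$n2,
               attainable = n2$attainable)
  })
  out <- do.call(rbind, rows)
  if (!is.null(path)) utils::write.csv(out, path, row.names = FALSE)
  out
}
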