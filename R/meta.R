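## Heterogeneity on the Cohen's d scale attributable to adventitious error.

#' Convert a correlation to Cohen's d (and back)
#'
#' `d = 2 r / (1 - r^2)`, the standard conversion used when correlations are
#' meta-analyzed on the Cohen's d scale; `d_to_r()` is its closed-form
#' inverse `r = (sqrt(1 + d^2) - 1) / d`.
#'
#' @param r correlation, `|r| < 1`.
#' @param d effect size on the Cohen's d scale.
#' @return The converted effect size (vectorized).
#' @examples
#' r_to_d(0.49)   # 1.290, a very large effect
#' @export
r_to_d <- function(r) {
  if (any(abs(r) >= 1)) stop("|r| must be < 1", call. = FALSE)
  2 * r / (1 - r^2)
}

#' @rdname r_to_d
#' @export
d_to_r <- function(d) {
  ifelse(d == 0, 0, (sqrt(1 + d^2) - 1) / d)
}

#' Single-study standard error of a correlation on the d scale
#'
#' `SE(d) = 2 / sqrt((N - 1)(1 - r^2))`: the sampling standard error, on the
#' Cohen's d scale, of a correlation observed in one study of size `N`.
#'
#' @inheritParams r_to_d
#' @param N sample size, at least 2.
#' @return The standard error (vectorized over `r` and `N`).
#' @examples
#' se_d(0.49, 200)   # 0.163
#' @export
se_d <- function(r, N) {
  if (any(abs(r) >= 1)) stop("|r| must be < 1", call. = FALSE)
  if (any(N < 2)) stop("N must be >= 2", call. = FALSE)
  2 / sqrt((N - 1) * (1 - r^2))
}

#' Heterogeneity (tau) attributable to adventitious error
#'
#' Treats the SE surplus created by adventitious error as between-study
#' heterogeneity: the augmented SE is `SE(d) * q` with `q` the theoretical
#' augmented uncertainty factor ([tauf()]); the surplus variance
#' `tau^2 = (SE * q)^2 - SE^2` is attributed to a single study (S = 1), and
#' `tau` is its square root, on the standardized Cohen's d scale.  All
#' intermediates are kept unrounded; the print method also shows the 3-dp
#' rounded chain for comparison with hand calculations.
#'
#' @inheritParams se_d
#' @param dispersion adventitious dispersion `1/m` (or an
#'   [adventitious_spec()]).
#' @return A `heterogeneity_report` with fields `r`, `N`, `dispersion`, `d`,
#'   `se_d`, `q`, `se_d_augmented`, `var_samp`, `var_total`, `tau2`, `tau`.
#' @examples
#' tau_from_adventitious(0.49, 200, 0.0064)$tau   # 0.184
#' tau_from_adventitious(0.25, 200, 0.0064)$tau   # 0.165
#' @export
tau_from_adventitious <- function(r, N, dispersion) {
  spec <- as_spec(dispersion)
  se <- se_d(r, N)
  q <- tauf(spec, N)
  se_aug <- se * q
  tau2 <- se_aug^2 - se^2
  structure(
    list(r = r, N = N, dispersion = spec$dispersion,
         d = r_to_d(r), se_d = se, q = q, se_d_augmented = se_aug,
         var_samp = se^2, var_total = se_aug^2,
         tau2 = tau2, tau = sqrt(tau2)),
    class = "heterogeneity_report")
}

#' @export
print.heterogeneity_report <- function(x, ...) {
  cat("Heterogeneity attributable to adventitious error (single study)\n")
  cat(sprintf("  r = %.3f, N = %d, dispersion 1/m = %g\n",
              x$r, as.integer(x$N), x$dispersion))
  cat(sprintf("  d          = %.3f\n", x$d))
  cat(sprintf("  SE(d)      = %.4f   (rounded chain: %.3f)\n", x$se_d,
              round(x$se_d, 3)))
  cat(sprintf("  q (TAUF)   = %.4f\n", x$q))
  cat(sprintf("  SE(d) * q  = %.4f\n", x$se_d_augmented))
  cat(sprintf("  variances  : sampling %.4f, total %.4f   (rounded: %.3f, %.3f)\n",
              x$var_samp, x$var_total, round(x$se_d, 3)^2,
              round(x$se_d_augmented, 3)^2))
  cat(sprintf("  tau^2      = %.4f, tau = %.3f\n", x$tau2, x$tau))
  invisible(x)
}
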