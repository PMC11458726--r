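## Simulation-based augmented uncertainty factors (SAUF).
##
## For each replicate the theoretical matrix is distorted into an
## operational matrix, one dataset is generated from it, and the effect of
## interest is estimated; the SD of the estimates across replicates is the
## simulation-based augmented SE.  Repeating the generation from the
## undistorted matrix gives the simulation-based traditional SE, and the
## ratio of the two SDs is the SAUF, the Monte Carlo counterpart of the
## closed-form factor q from tauf().

#' Configuration for one SAUF simulation cell
#'
#' @param case `"case1"` (simple regression of Y on X), `"case2a"` (MIMIC
#'   model, latent outcome), or `"case2b"` (regression of the summed score
#'   Y1 + ... + Y4 on X).
#' @param N per-dataset sample size (>= 10).
#' @param dispersion adventitious dispersion `1/m`.
#' @param reps Monte Carlo replicates (>= 2; 2000 for the reference table).
#' @param seed integer seed for the whole cell.
#' @param identification identification convention whose structural
#'   coefficient is the headline case-2a effect; the alternative convention
#'   is always reported alongside.
#' @param denominator how the traditional SE in the SAUF denominator is
#'   estimated: SD of the undistorted-replicate estimates (default), or the
#'   median estimated SE across the distorted or undistorted replicates.
#' @return A `case_config` list.
#' @export
case_config <- function(case = c("case1", "case2a", "case2b"),
                        N = 200L, dispersion = 0.0064, reps = 2000L,
                        seed = 1L,
                        identification = c("unit_factor_variance",
                                           "marker_loading"),
                        denominator = c("sd_undistorted",
                                        "median_se_distorted",
                                        "median_se_undistorted")) {
  case <- match.arg(case)
  if (reps < 2) stop("reps must be >= 2 (an SD is undefined otherwise)",
                     call. = FALSE)
  if (N < 10) stop("N must be >= 10", call. = FALSE)
  structure(list(case = case, N = as.integer(N), dispersion = dispersion,
                 reps = as.integer(reps), seed = as.integer(seed),
                 identification = match.arg(identification),
                 denominator = match.arg(denominator)),
            class = "case_config")
}

#' Estimate the case-specific effect from one dataset
#'
#' * `case1`: OLS slope of Y on X (column layout X, Y).
#' * `case2a`: ML structural coefficient of X on the latent outcome from the
#'   MIMIC fit ([fit_ml()]); returns both identification conventions.
#' * `case2b`: OLS slope of the summed score Y1 + ... + Y4 on X.
#'
#' The OLS slope is computed directly as `cov(x, y) / var(x)`, the same
#' estimator a regression fit returns.
#'
#' @param data numeric matrix with the case's column layout (X first).
#' @param case case tag.
#' @return For the regression cases a single slope; for `case2a` a named
#'   vector `c(unit = ..., marker = ...)` with attributes `converged`.
#' @export
estimate_effect <- function(data, case = c("case1", "case2a", "case2b")) {
  case <- match.arg(case)
  x <- data[, 1L]
  vx <- stats::var(x)
  if (!is.finite(vx) || vx <= 0)
    stop("predictor X has zero variance", call. = FALSE)
  switch(case,
    case1 = stats::cov(x, data[, 2L]) / vx,
    case2b = stats::cov(x, rowSums(data[, -1L, drop = FALSE])) / vx,
    case2a = {
      fit <- fit_ml(stats::cov(data),
                    factor_model_spec(ncol(data) - 1L, has_predictor = TRUE))
      b_unit <- fit$unit_structural
      structure(c(unit = b_unit, marker = b_unit * fit$unit_loadings[1L]),
                converged = fit$converged)
    })
}

# generate one dataset from sigma, with per-variable means drawn N(0, 0.5^2)
# (inert for covariance-based estimates, kept for fidelity to the design)
gen_dataset <- function(sigma, N) {
  mu <- stats::rnorm(ncol(sigma), 0, 0.5)
  MASS::mvrnorm(N, mu, sigma)
}

#' Run one SAUF simulation cell
#'
#' Executes the four-step design: (1) draw `reps` operational matrices at
#' the configured dispersion, (2) generate one `N`-row multivariate-normal
#' dataset per matrix, (3) estimate the effect in each dataset and take the
#' SD across replicates (the augmented SE), (4) repeat the generation from
#' the undistorted theoretical matrix and take the SD again (the traditional
#' SE).  The SAUF is the ratio of the two SDs, reported next to the
#' closed-form reference [tauf()].
#'
#' @param config a [case_config()].
#' @return A `sauf_result` with `sd_with_ae`, `sd_without_ae`, `sauf`,
#'   `tauf_reference`, `n_dropped` (non-convergent fits, excluded from the
#'   SDs) and, for case 2a, `sauf_alt` under the other identification
#'   convention.  A warning is attached if more than 5% of case-2a fits
#'   failed to converge.
#' @examples
#' \donttest{
#' res <- run_sauf(case_config("case1", N = 200, reps = 500, seed = 7))
#' res$sauf               # close to tauf(0.0064, 200) = 1.51
#' }
#' @export
run_sauf <- function(config) {
  stopifnot(inherits(config, "case_config"))
  omega <- build_case_omega(if (config$case == "case1") "case1" else "case2")
  set.seed(config$seed)
  two_conventions <- config$case == "case2a"

  run_arm <- function(distort) {
    sig_draws <- if (distort)
      draw_operational_cov(omega, config$dispersion, ndraws = config$reps,
                           simplify = FALSE)
    else NULL
    est <- matrix(NA_real_, config$reps, if (two_conventions) 2L else 1L)
    ses <- rep(NA_real_, config$reps)
    conv <- rep(TRUE, config$reps)
    for (i in seq_len(config$reps)) {
      sig <- if (distort) sig_draws[, , i] else omega
      dat <- gen_dataset(sig, config$N)
      e <- estimate_effect(dat, config$case)
      est[i, ] <- e
      if (two_conventions) {
        conv[i] <- isTRUE(attr(e, "converged"))
      } else {
        # analytic OLS slope SE for this replicate
        x <- dat[, 1L]
        y <- if (config$case == "case1") dat[, 2L] else
          rowSums(dat[, -1L, drop = FALSE])
        vx <- stats::var(x)
        ses[i] <- sqrt(max(stats::var(y) - e[1L]^2 * vx, 0) /
                         ((config$N - 2) * vx))
      }
    }
    list(est = est, ses = ses, conv = conv)
  }

  with_ae <- run_arm(TRUE)
  without_ae <- run_arm(FALSE)
  keep_w <- with_ae$conv
  keep_o <- without_ae$conv
  n_dropped <- sum(!keep_w) + sum(!keep_o)

  col <- if (two_conventions && config$identification == "marker_loading") 2L else 1L
  sd_with <- stats::sd(with_ae$est[keep_w, col])
  sd_without <- stats::sd(without_ae$est[keep_o, col])

  if (config$denominator != "sd_undistorted") {
    # median per-replicate analytic SE (regression cases only)
    if (config$case == "case2a") {
      warning("median-SE denominators are available for the regression ",
              "cases only; using the undistorted-replicate SD")
    } else {
      arm <- if (config$denominator == "median_se_distorted") with_ae else
        without_ae
      sd_without <- stats::median(arm$ses)
    }
  }

  sauf <- sd_with / sd_without
  res <- structure(
    list(config = config,
         sd_with_ae = sd_with, sd_without_ae = sd_without,
         sauf = sauf,
         tauf_reference = tauf(config$dispersion, config$N),
         n_dropped = n_dropped),
    class = "sauf_result")
  if (two_conventions) {
    alt <- if (col == 1L) 2L else 1L
    res$sauf_alt <- stats::sd(with_ae$est[keep_w, alt]) /
      stats::sd(without_ae$est[keep_o, alt])
  }
  if (n_dropped > 0.05 * 2 * config$reps)
    warning(sprintf("%d of %d factor-model fits did not converge",
                    n_dropped, 2L * config$reps))
  res
}

#' @export
print.sauf_result <- function(x, ...) {
  cat(sprintf("SAUF for %s, N = %d, dispersion = %g, reps = %d\n",
              x$config$case, x$config$N, x$config$dispersion, x$config$reps))
  cat(sprintf("  SD with adventitious error    : %.3f\n", x$sd_with_ae))
  cat(sprintf("  SD without adventitious error : %.3f\n", x$sd_without_ae))
  cat(sprintf("  SAUF = %.2f   (TAUF reference %.2f)\n", x$sauf,
              x$tauf_reference))
  if (!is.null(x$sauf_alt))
    cat(sprintf("  SAUF, other identification    : %.2f\n", x$sauf_alt))
  if (x$n_dropped > 0)
    cat(sprintf("  non-convergent fits dropped   : %d\n", x$n_dropped))
  invisible(x)
}

# Joint runner for cases 2a and 2b at one sample size: both analyses are
# applied to the same generated five-variable datasets (one operational draw
# and one dataset per replicate serve both the factor-model and the
# summed-score regression), as the four-step design prescribes.
sauf_case2_cell <- function(N, dispersion, reps, seed) {
  omega <- build_case_omega("case2")
  set.seed(seed)
  run_arm <- function(distort) {
    sig_draws <- if (distort)
      draw_operational_cov(omega, dispersion, ndraws = reps, simplify = FALSE)
    b_unit <- b_marker <- b_sum <- rep(NA_real_, reps)
    conv <- rep(TRUE, reps)
    for (i in seq_len(reps)) {
      sig <- if (distort) sig_draws[, , i] else omega
      dat <- gen_dataset(sig, N)
      e2a <- estimate_effect(dat, "case2a")
      b_unit[i] <- e2a[["unit"]]
      b_marker[i] <- e2a[["marker"]]
      conv[i] <- isTRUE(attr(e2a, "converged"))
      b_sum[i] <- estimate_effect(dat, "case2b")
    }
    list(b_unit = b_unit, b_marker = b_marker, b_sum = b_sum, conv = conv)
  }
  w <- run_arm(TRUE)
  o <- run_arm(FALSE)
  sds <- function(v, keep) stats::sd(v[keep])
  list(
    sd_2a_unit = c(with_ae = sds(w$b_unit, w$conv),
                   without_ae = sds(o$b_unit, o$conv)),
    sd_2a_marker = c(with_ae = sds(w$b_marker, w$conv),
                     without_ae = sds(o$b_marker, o$conv)),
    sd_2b = c(with_ae = stats::sd(w$b_sum), without_ae = stats::sd(o$b_sum)),
    n_dropped = sum(!w$conv) + sum(!o$conv))
}

#' Tabulate theoretical and simulation-based uncertainty factors
#'
#' Assembles the reference-table layout over cases and sample sizes:
#' per-cell simulation SDs (3 decimals), SAUF (2 decimals) and the TAUF
#' reference.  Cases 2a and 2b are estimated from the same generated
#' datasets at each sample size (the summed-score regression and the
#' factor model are two analyses of one dataset per replicate), and case 2a
#' is reported under both identification conventions.
#'
#' @param Ns sample sizes (default `c(200, 1000)`).
#' @param dispersion adventitious dispersion `1/m`.
#' @param reps replicates per cell.
#' @param seed master seed; each cell runs on a seed derived from it.
#' @param path optional CSV output path.
#' @param verbose log per-cell progress to stderr?
#' @return A data frame with one row per case x N cell (case 2a twice, once
#'   per identification convention), plus unrounded columns.
#' @export
table1_report <- function(Ns = c(200L, 1000L), dispersion = 0.0064,
                          reps = 2000L, seed = 1L, path = NULL,
                          verbose = FALSE) {
  rows <- list()
  add_row <- function(case, ident, N, sd_w, sd_o, n_dropped) {
    rows[[length(rows) + 1L]] <<- data.frame(
      case = case, identification = ident, N = N,
      tauf = round(tauf(dispersion, N), 2),
      sd_with_ae = round(sd_w, 3), sd_without_ae = round(sd_o, 3),
      sauf = round(sd_w / sd_o, 2), sauf_unrounded = sd_w / sd_o,
      n_dropped = n_dropped)
  }
  for (i in seq_along(Ns)) {
    N <- Ns[i]
    if (verbose) message(sprintf("table1: case 1, N = %d ...", N))
    res1 <- run_sauf(case_config("case1", N = N, dispersion = dispersion,
                                 reps = reps, seed = derive_seed(seed, i)))
    add_row("case1", NA_character_, N, res1$sd_with_ae, res1$sd_without_ae, 0L)
    if (verbose) message(sprintf("table1: cases 2a/2b, N = %d ...", N))
    res2 <- sauf_case2_cell(N, dispersion, reps,
                            seed = derive_seed(seed, 100L + i))
    add_row("case2a", "unit_factor_variance", N,
            res2$sd_2a_unit[["with_ae"]], res2$sd_2a_unit[["without_ae"]],
            res2$n_dropped)
    add_row("case2a", "marker_loading", N,
            res2$sd_2a_marker[["with_ae"]], res2$sd_2a_marker[["without_ae"]],
            res2$n_dropped)
    add_row("case2b", NA_character_, N,
            res2$sd_2b[["with_ae"]], res2$sd_2b[["without_ae"]], 0L)
  }
  out <- do.call(rbind, rows)
  if (!is.null(path)) utils::write.csv(out, path, row.names = FALSE)
  out
}
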