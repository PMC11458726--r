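#' advwish: adventitious error and augmented uncertainty
#'
#' Adventitious error treats the population covariance matrix that governs a
#' particular study as a random distortion of a theoretical covariance matrix
#' Omega: the operational matrix Sigma_s is drawn from an inverse-Wishart
#' distribution IW(m * Omega, m), and the observed covariance matrix is then
#' sampled from a Wishart distribution centred at Sigma_s.  The dispersion
#' 1/m of the distortion equals the squared RMSEA, so an RMSEA benchmark of
#' 0.08 corresponds to dispersion 0.0064 and df m = 156.25.
#'
#' The package provides the generative simulator, the closed-form augmented
#' uncertainty factor and augmented standard errors, heterogeneity (tau) on
#' the Cohen's d scale, Fisher-z power and sample-size machinery, a small
#' maximum-likelihood factor-model fitter with Thurstone regression factor
#' scores, and the two Monte Carlo studies built on top of these pieces
#' ([run_sauf()]/[table1_report()] and [run_measurement_study()]).
#'
#' @keywords internal
#' @aliases advwish-package
"_PACKAGE"

## ---- validation helpers ----------------------------------------------------

#' Validate a covariance matrix
#'
#' Checks that `x` is a square, symmetric, numeric matrix and (optionally)
#' positive definite.  Returns the matrix invisibly so it can be used in
#' pipelines; stops with an informative error otherwise.
#'
#' @param x matrix to validate.
#' @param require_pd require all eigenvalues > 0 (via Cholesky)?
#' @param arg name used in error messages.
#' @return `x`, invisibly.
#' @export
check_cov <- function(x, require_pd = TRUE, arg = "covariance matrix") {
  if (!is.matrix(x) || !is.numeric(x) || nrow(x) != ncol(x))
    stop(arg, " must be a square numeric matrix", call. = FALSE)
  if (!isSymmetric(unname(x), tol = 1e-8))
    stop(arg, " must be symmetric", call. = FALSE)
  if (require_pd) {
    ch <- tryCatch(chol(x), error = function(e) NULL)
    if (is.null(ch))
      stop(arg, " must be positive definite (Cholesky failed)", call. = FALSE)
  }
  invisible(x)
}

is_pd <- function(x) !is.null(tryCatch(chol(x), error = function(e) NULL))

## ---- adventitious specification --------------------------------------------

#' Specify an adventitious-error rate
#'
#' The single knob of the framework: the inverse-Wishart dispersion `1/m`.
#' `adventitious_spec()` builds the specification from the dispersion itself;
#' [rmsea_to_spec()] builds it from an RMSEA value using dispersion = RMSEA^2.
#' A dispersion of 0 is the exact "no adventitious error" case: draws pass
#' Omega through unchanged rather than taking an infinite-df limit.
#'
#' @param dispersion inverse-Wishart dispersion `1/m`, non-negative.
#' @return An object of class `adventitious_spec` with fields `dispersion`,
#'   `df` (`m = 1/dispersion`, `Inf` at dispersion 0) and `rmsea_equiv`
#'   (`sqrt(dispersion)`).
#' @examples
#' adventitious_spec(0.0064)    # benchmark rate, RMSEA 0.08, m = 156.25
#' rmsea_to_spec(0.05)          # dispersion 0.0025
#' @export
adventitious_spec <- function(dispersion) {
  if (!is.numeric(dispersion) || length(dispersion) != 1L || is.na(dispersion) ||
      dispersion < 0)
    stop("dispersion must be a single non-negative number", call. = FALSE)
  structure(
    list(dispersion = dispersion,
         df = if (dispersion > 0) 1 / dispersion else Inf,
         rmsea_equiv = sqrt(dispersion)),
    class = "adventitious_spec")
}

#' @rdname adventitious_spec
#' @param rmsea RMSEA value in `[0, 1)`; its square is the dispersion.
#' @export
rmsea_to_spec <- function(rmsea) {
  if (!is.numeric(rmsea) || length(rmsea) != 1L || is.na(rmsea) ||
      rmsea < 0 || rmsea >= 1)
    stop("rmsea must be a single value in [0, 1)", call. = FALSE)
  adventitious_spec(rmsea^2)
}

#' @export
print.adventitious_spec <- function(x, ...) {
  cat("Adventitious-error specification\n")
  cat(sprintf("  dispersion 1/m : %g\n", x$dispersion))
  cat(sprintf("  df m           : %g\n", x$df))
  cat(sprintf("  RMSEA equiv.   : %g\n", x$rmsea_equiv))
  invisible(x)
}

as_spec <- function(spec) {
  if (inherits(spec, "adventitious_spec")) spec else adventitious_spec(spec)
}

## ---- theoretical augmented uncertainty factor -------------------------------

#' Theoretical augmented uncertainty factor (TAUF)
#'
#' In the presence of adventitious error with dispersion `1/m`, standard
#' errors of parameter estimates grow by the factor
#' \deqn{q = \sqrt{(1/m + 1/n) / (1/n)}, \quad n = N - 1,}
#' so the augmented SE is the traditional SE times `q`.  The factor is 1
#' exactly when the dispersion is 0 and grows with both the dispersion and
#' the sample size (the `1/m` term does not shrink as `N` grows, so the
#' *relative* inflation increases with `N`).
#'
#' @param dispersion adventitious dispersion `1/m` (or an
#'   [adventitious_spec()] object).
#' @param N sample size, at least 2; `n = N - 1` is used internally.
#' @return The inflation factor `q >= 1` (vectorized over `N`).
#' @examples
#' tauf(0.0064, 200)    # 1.51
#' tauf(0.0064, 1000)   # 2.72
#' @export
tauf <- function(dispersion, N) {
  spec <- as_spec(dispersion)
  if (any(!is.finite(N)) || any(N < 2))
    stop("N must be >= 2", call. = FALSE)
  sqrt(1 + spec$dispersion * (N - 1))
}

## ---- generative draws -------------------------------------------------------

#' Draw operational population covariance matrices
#'
#' Draws `ndraws` matrices `Sigma_s ~ IW(m * Omega, m)`: the operational
#' covariance matrix of an individual study, randomly perturbed from the
#' theoretical matrix `Omega` with dispersion `1/m`.  Sampling goes through
#' the Bartlett decomposition of the Wishart distribution (via
#' [stats::rWishart()]), which supports the fractional degrees of freedom the
#' exact dispersion implies (m = 156.25 at the benchmark rate); the draw is
#' then inverted.  The scale matrix is `m * Omega` exactly, so the IW mean is
#' `m * Omega / (m - p - 1)` — slightly above `Omega` — rather than `Omega`
#' itself; no bias correction is applied.
#'
#' At dispersion 0 the theoretical matrix is returned unchanged for every
#' draw (the degenerate no-distortion case).
#'
#' @param omega theoretical covariance matrix (symmetric positive definite).
#' @param spec dispersion `1/m` or an [adventitious_spec()].
#' @param ndraws number of independent draws.
#' @param simplify if `TRUE` (default) and `ndraws == 1`, return a single
#'   `p x p` matrix instead of a `p x p x 1` array.
#' @return A `p x p` matrix or a `p x p x ndraws` array with attribute
#'   `dispersion`.
#' @examples
#' omega <- build_case_omega("part3")
#' set.seed(1)
#' sigma_s <- draw_operational_cov(omega, 0.0064)
#' @export
draw_operational_cov <- function(omega, spec, ndraws = 1L, simplify = TRUE) {
  check_cov(omega, arg = "omega")
  spec <- as_spec(spec)
  p <- nrow(omega)
  if (spec$dispersion == 0) {
    out <- array(omega, dim = c(p, p, ndraws))
  } else {
    m <- spec$df
    if (m <= p - 1)
      stop("inverse-Wishart df m = ", m, " must exceed p - 1 = ", p - 1,
           call. = FALSE)
    w <- stats::rWishart(ndraws, df = m, Sigma = chol2inv(chol(m * omega)))
    out <- array(apply(w, 3L, chol2inv_sym), dim = c(p, p, ndraws))
  }
  if (!is.null(dimnames(omega)))
    dimnames(out) <- c(dimnames(omega), list(NULL))
  attr(out, "dispersion") <- spec$dispersion
  if (simplify && ndraws == 1L) {
    out <- out[, , 1L]
    attr(out, "dispersion") <- spec$dispersion
  }
  out
}

# invert an SPD matrix and force exact symmetry
chol2inv_sym <- function(x) {
  inv <- chol2inv(chol(x))
  (inv + t(inv)) / 2
}

#' Draw sample covariance matrices
#'
#' Draws `S ~ W(Sigma / n, n)` with `n = N - 1`: the sampling distribution of
#' the empirical covariance matrix of `N` multivariate-normal observations
#' with population covariance `Sigma`.  `E[S] = Sigma` (unbiasedness).
#'
#' @param sigma population covariance matrix of the study (operational or
#'   theoretical).
#' @param N sample size, at least 2.
#' @param ndraws number of draws.
#' @param simplify return a matrix when `ndraws == 1`?
#' @return A `p x p` matrix or `p x p x ndraws` array with attributes `N` and
#'   `n`.
#' @export
draw_sample_cov <- function(sigma, N, ndraws = 1L, simplify = TRUE) {
  check_cov(sigma, arg = "sigma")
  if (length(N) != 1L || !is.finite(N) || N < 2)
    stop("N must be a single integer >= 2", call. = FALSE)
  n <- N - 1
  out <- stats::rWishart(ndraws, df = n, Sigma = sigma / n)
  if (!is.null(dimnames(sigma)))
    dimnames(out) <- c(dimnames(sigma), list(NULL))
  attr(out, "N") <- N
  attr(out, "n") <- n
  if (simplify && ndraws == 1L) {
    out <- out[, , 1L]
    attr(out, "N") <- N
    attr(out, "n") <- n
  }
  out
}

## ---- distortion-magnitude mini-study ---------------------------------------

#' Average absolute distortion of the operational covariance matrix
#'
#' Draws `reps` operational matrices at the given dispersion and returns the
#' mean over all draws and all `p^2` cells (diagonal included) of the
#' absolute deviation from the theoretical matrix.  At the benchmark
#' dispersion 0.0064 and the 4 x 4 compound-symmetry matrix with 0.49
#' off-diagonals, this average is about 0.079 with 1000 replications.
#'
#' @inheritParams draw_operational_cov
#' @param reps number of replications, at least 1.
#' @return The mean absolute deviation (a single number), with attribute
#'   `per_rep` holding the per-replication means.
#' @export
mean_abs_deviation_study <- function(omega, spec, reps = 1000L) {
  if (length(reps) != 1L || !is.finite(reps) || reps < 1)
    stop("reps must be >= 1", call. = FALSE)
  spec <- as_spec(spec)
  reps <- as.integer(reps)
  if (spec$dispersion == 0) {
    per <- numeric(reps)
  } else {
    draws <- draw_operational_cov(omega, spec, ndraws = reps, simplify = FALSE)
    per <- apply(draws, 3L, function(s) mean(abs(s - omega)))
  }
  structure(mean(per), per_rep = per)
}

## ---- case templates ---------------------------------------------------------

#' Theoretical covariance matrices for the worked cases
#'
#' Builds the population correlation matrices used throughout the package's
#' simulation studies.  All variables have unit variance.
#'
#' * `"case1"` — 2 x 2 for a simple regression of Y on X, `cov(X, Y) = 0.25`.
#' * `"case2"` — 5 x 5 with X first and four indicators Y1..Y4:
#'   `cov(X, Yj) = 0.35`, indicator loadings 0.70 hence
#'   `cov(Yj, Yk) = 0.49`.  Used for both the latent-outcome (2a) and
#'   summed-score (2b) analyses.
#' * `"part3"` — 4 x 4 compound symmetry with 0.49 off-diagonals, implied by
#'   a one-factor model with loadings 0.70 and residual variances 0.51.
#'
#' @param case one of `"case1"`, `"case2"`, `"part3"`.
#' @return A covariance matrix with variable names as dimnames.
#' @export
build_case_omega <- function(case = c("case1", "case2", "part3")) {
  case <- match.arg(case)
  switch(case,
    case1 = {
      om <- matrix(c(1, 0.25, 0.25, 1), 2, 2)
      dimnames(om) <- list(c("X", "Y"), c("X", "Y"))
      om
    },
    case2 = {
      om <- matrix(0.49, 5, 5)
      om[1, ] <- om[, 1] <- 0.35
      diag(om) <- 1
      nm <- c("X", paste0("Y", 1:4))
      dimnames(om) <- list(nm, nm)
      om
    },
    part3 = {
      om <- matrix(0.49, 4, 4)
      diag(om) <- 1
      nm <- paste0("Y", 1:4)
      dimnames(om) <- list(nm, nm)
      om
    })
}

## ---- covariance I/O ---------------------------------------------------------

#' Read and write covariance matrices
#'
#' CSV round-trip for covariance matrices: the header row carries the
#' variable names, rows are unlabeled.  `cov_to_json()`/`cov_from_json()` use
#' a small JSON object with `variables` and row-major `values`.
#'
#' @param x covariance matrix.
#' @param path file path.
#' @return `read_cov_csv()` and `cov_from_json()` return the matrix;
#'   the writers return `path` invisibly.
#' @export
write_cov_csv <- function(x, path) {
  check_cov(x, require_pd = FALSE)
  df <- as.data.frame(x)
  names(df) <- colnames(x) %||% paste0("V", seq_len(ncol(x)))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cov_csv
#' @export
read_cov_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  m <- as.matrix(df)
  dimnames(m) <- list(colnames(m), colnames(m))
  check_cov(m, require_pd = FALSE)
  m
}

#' @rdname write_cov_csv
#' @export
cov_to_json <- function(x, path = NULL) {
  check_cov(x, require_pd = FALSE)
  obj <- list(variables = colnames(x) %||% paste0("V", seq_len(ncol(x))),
              p = ncol(x), values = as.vector(t(x)))
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(path))
  }
  js
}

#' @rdname write_cov_csv
#' @param json JSON string or path produced by `cov_to_json()`.
#' @export
cov_from_json <- function(json) {
  obj <- jsonlite::fromJSON(json)
  m <- matrix(obj$values, obj$p, obj$p, byrow = TRUE)
  dimnames(m) <- list(obj$variables, obj$variables)
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a child RNG seed from a master seed
#'
#' Pure function of the master seed and a stream index; keeps all derived
#' seeds below 2^31 so they are valid R integer seeds.  Used by the study
#' drivers so every sub-stream is reproducible from one master seed.
#'
#' @param master master seed (integer).
#' @param stream stream index (integer, >= 0).
#' @return An integer seed.
#' @export
derive_seed <- function(master, stream) {
  as.integer((as.numeric(master) %% 2147483647) * 48271 %% 2147483647 +
               as.numeric(stream) * 104729) %% 2147483647L
}
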