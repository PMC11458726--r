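## Maximum-likelihood fitting of the two small covariance structure models
## used by the simulation studies: a one-factor model for p indicators, and
## the MIMIC variant with a manifest predictor X of the latent variable.
##
## Internal parametrization (always):
##   one-factor:  loadings lambda (p), log residual variances; var(theta) = 1.
##   MIMIC:       loadings lambda (p_y), log residual variances,
##                gamma = cov(X, theta), log var(X); var(theta) = 1, so the
##                structural coefficient is b = gamma / var(X) and the
##                disturbance is psi = 1 - b^2 var(X) = 1 - gamma^2 / var(X).
## Marker-loading results are obtained by rescaling the unit-variance
## solution (lambda* = lambda / lambda1, var(theta)* = lambda1^2,
## b* = b lambda1); both conventions imply the identical covariance matrix,
## so the discrepancy value is shared.

#' Specify a small covariance structure model
#'
#' @param n_indicators number of indicators of the single factor (>= 3 for
#'   identifiability).
#' @param has_predictor include a manifest predictor X of the latent
#'   variable (the MIMIC layout, X in the first column)?
#' @param identification `"unit_factor_variance"` fixes var(theta) = 1 so
#'   population loadings of 0.70 and a structural coefficient of 0.50 are
#'   directly interpretable; `"marker_loading"` fixes the first loading to 1
#'   and frees the factor variance.  The two conventions imply the same
#'   covariance matrix and the same discrepancy value.
#' @return A `factor_model_spec` object.
#' @export
factor_model_spec <- function(n_indicators = 4L, has_predictor = FALSE,
                              identification = c("unit_factor_variance",
                                                 "marker_loading")) {
  if (n_indicators < 3)
    stop("a one-factor model needs at least 3 indicators", call. = FALSE)
  structure(list(n_indicators = as.integer(n_indicators),
                 has_predictor = isTRUE(has_predictor),
                 identification = match.arg(identification)),
            class = "factor_model_spec")
}

#' Model-implied covariance matrix
#'
#' For the one-factor model, `Sigma = Lambda Lambda' var(theta) + diag(res)`.
#' For the MIMIC layout (X first), `var(X) = phi_x`,
#' `cov(X, Yj) = lambda_j b phi_x` and `var(theta) = b^2 phi_x + psi`.
#'
#' @param params list with `loadings`, `residual_variances`, and either
#'   `factor_variance` (one-factor) or `structural_coeff`,
#'   `predictor_variance` and `disturbance` (MIMIC).
#' @param spec a [factor_model_spec()].
#' @return The implied covariance matrix; an error if the residual variances
#'   are not positive, a warning (with the matrix still returned) if the
#'   result is not positive definite.
#' @examples
#' sp <- factor_model_spec(4)
#' implied_cov(list(loadings = rep(0.7, 4),
#'                  residual_variances = rep(0.51, 4),
#'                  factor_variance = 1), sp)  # the 0.49 compound-symmetry matrix
#' @export
implied_cov <- function(params, spec) {
  lam <- params$loadings
  res <- params$residual_variances
  if (length(lam) != spec$n_indicators || length(res) != spec$n_indicators)
    stop("loadings and residual_variances must have length n_indicators",
         call. = FALSE)
  if (any(res <= 0))
    stop("residual variances must be positive", call. = FALSE)
  if (spec$has_predictor) {
    b <- params$structural_coeff
    phix <- params$predictor_variance
    psi <- params$disturbance %||% (1 - b^2 * phix)
    vtheta <- b^2 * phix + psi
    syy <- tcrossprod(lam) * vtheta + diag(res, length(lam))
    sxy <- lam * b * phix
    sig <- rbind(c(phix, sxy), cbind(sxy, syy))
    nm <- c("X", paste0("Y", seq_along(lam)))
  } else {
    vtheta <- params$factor_variance %||% 1
    sig <- tcrossprod(lam) * vtheta + diag(res, length(lam))
    nm <- paste0("Y", seq_along(lam))
  }
  dimnames(sig) <- list(nm, nm)
  if (!is_pd(sig))
    warning("implied covariance matrix is not positive definite")
  sig
}

#' Maximum-likelihood discrepancy function
#'
#' The normal-theory fit function
#' `F = log|Sigma| + tr(S Sigma^-1) - log|S| - p`, non-negative and zero
#' exactly when `S = Sigma`.
#'
#' @param sample observed covariance matrix `S`.
#' @param implied model-implied covariance matrix `Sigma`.
#' @return The discrepancy value.
#' @export
fml_discrepancy <- function(sample, implied) {
  if (!all(dim(sample) == dim(implied)))
    stop("sample and implied matrices must have the same dimension",
         call. = FALSE)
  p <- nrow(sample)
  rs <- tryCatch(chol(sample), error = function(e)
    stop("sample covariance matrix is singular or not PD (rcond = ",
         format(rcond(sample), digits = 3), ")", call. = FALSE))
  ri <- tryCatch(chol(implied), error = function(e)
    stop("implied covariance matrix is singular or not PD (rcond = ",
         format(rcond(implied), digits = 3), ")", call. = FALSE))
  isig <- chol2inv(ri)
  2 * sum(log(diag(ri))) + sum(isig * sample) - 2 * sum(log(diag(rs))) - p
}

## objective + analytic gradient in the internal parametrization -------------

fml_obj_factor <- function(par, S, p) {
  lam <- par[1:p]
  th <- exp(par[(p + 1):(2 * p)])
  sig <- tcrossprod(lam) + diag(th, p)
  r <- tryCatch(chol(sig), error = function(e) NULL)
  if (is.null(r)) return(1e10)
  isig <- chol2inv(r)
  2 * sum(log(diag(r))) + sum(isig * S)
}

fml_gr_factor <- function(par, S, p) {
  lam <- par[1:p]
  th <- exp(par[(p + 1):(2 * p)])
  sig <- tcrossprod(lam) + diag(th, p)
  r <- tryCatch(chol(sig), error = function(e) NULL)
  if (is.null(r)) return(rep(0, 2 * p))
  isig <- chol2inv(r)
  g <- isig - isig %*% S %*% isig          # dF/dSigma
  c(2 * as.vector(g %*% lam), diag(g) * th)
}

fml_obj_mimic <- function(par, S, p) {
  py <- p
  lam <- par[1:py]
  th <- exp(par[(py + 1):(2 * py)])
  gam <- par[2 * py + 1]
  phix <- exp(par[2 * py + 2])
  sig <- rbind(c(phix, lam * gam),
               cbind(lam * gam, tcrossprod(lam) + diag(th, py)))
  r <- tryCatch(chol(sig), error = function(e) NULL)
  if (is.null(r)) return(1e10)
  isig <- chol2inv(r)
  2 * sum(log(diag(r))) + sum(isig * S)
}

fml_gr_mimic <- function(par, S, p) {
  py <- p
  lam <- par[1:py]
  th <- exp(par[(py + 1):(2 * py)])
  gam <- par[2 * py + 1]
  phix <- exp(par[2 * py + 2])
  sig <- rbind(c(phix, lam * gam),
               cbind(lam * gam, tcrossprod(lam) + diag(th, py)))
  r <- tryCatch(chol(sig), error = function(e) NULL)
  if (is.null(r)) return(rep(0, 2 * py + 2))
  isig <- chol2inv(r)
  g <- isig - isig %*% S %*% isig
  gxx <- g[1, 1]
  gxy <- g[1, -1]
  gyy <- g[-1, -1]
  c(2 * as.vector(gyy %*% lam) + 2 * gam * gxy,
    diag(gyy) * th,
    2 * sum(lam * gxy),
    gxx * phix)
}

#' Fit a small covariance structure model by maximum likelihood
#'
#' Minimizes [fml_discrepancy()] over the model parameters with BFGS and
#' analytic gradients, from the deterministic start (all loadings 0.5, all
#' residual variances 0.5) with one random restart if the first attempt does
#' not converge.  Residual and predictor variances are optimized on the log
#' scale.  Sign indeterminacy is resolved by flipping so the sum of loadings
#' is positive (jointly flipping the X--theta covariance in the MIMIC case,
#' which leaves the implied matrix unchanged).
#'
#' @param sample observed covariance matrix (positive definite); for the
#'   MIMIC layout the predictor X must be the first row/column.
#' @param spec a [factor_model_spec()]; the reported parameters follow its
#'   identification convention.
#' @param reltol relative convergence tolerance on the discrepancy.
#' @return A `factor_fit` object: `params` (loadings, residual variances,
#'   factor variance or disturbance, and for MIMIC the structural
#'   coefficient and predictor variance), `discrepancy`, `converged`,
#'   `score_weights` (Thurstone regression weights, see
#'   [regression_score_weights()]), and `spec`.
#' @examples
#' om <- build_case_omega("part3")
#' fit <- fit_ml(om, factor_model_spec(4))
#' fit$params$loadings            # 0.70 each: perfect-fit recovery
#' @export
fit_ml <- function(sample, spec, reltol = 1e-12) {
  check_cov(sample, arg = "sample")
  p <- nrow(sample)
  py <- spec$n_indicators
  if (p != py + as.integer(spec$has_predictor))
    stop("sample dimension does not match the model layout", call. = FALSE)

  start <- c(rep(0.5, py), rep(log(0.5), py))
  if (spec$has_predictor)
    start <- c(start, 0.25, log(max(sample[1, 1], 0.1)))
  fn <- if (spec$has_predictor) fml_obj_mimic else fml_obj_factor
  gr <- if (spec$has_predictor) fml_gr_mimic else fml_gr_factor

  run_opt <- function(st) {
    stats::optim(st, function(par) fn(par, sample, py),
                 function(par) gr(par, sample, py), method = "BFGS",
                 control = list(maxit = 500L, reltol = reltol))
  }
  opt <- run_opt(start)
  converged <- opt$convergence == 0L
  if (!converged) {   # one random restart
    opt2 <- run_opt(start + stats::runif(length(start), -0.25, 0.25))
    if (opt2$convergence == 0L || opt2$value < opt$value) {
      opt <- opt2
      converged <- opt2$convergence == 0L
    }
  }

  par <- opt$par
  lam <- par[1:py]
  res <- exp(par[(py + 1):(2 * py)])
  if (spec$has_predictor) {
    gam <- par[2 * py + 1]
    phix <- exp(par[2 * py + 2])
  }
  # sign alignment: sum of loadings > 0
  if (sum(lam) < 0) {
    lam <- -lam
    if (spec$has_predictor) gam <- -gam
  }

  if (spec$has_predictor) {
    b <- gam / phix
    psi <- 1 - gam^2 / phix
    params <- list(loadings = lam, residual_variances = res,
                   factor_variance = 1, disturbance = psi,
                   structural_coeff = b, predictor_variance = phix)
    if (spec$identification == "marker_loading") {
      c1 <- lam[1]
      params$loadings <- lam / c1
      params$factor_variance <- c1^2
      params$disturbance <- psi * c1^2
      params$structural_coeff <- b * c1
    }
    imp <- rbind(c(phix, lam * gam),
                 cbind(lam * gam, tcrossprod(lam) + diag(res, py)))
    nm <- c("X", paste0("Y", 1:py))
  } else {
    params <- list(loadings = lam, residual_variances = res,
                   factor_variance = 1)
    if (spec$identification == "marker_loading") {
      c1 <- lam[1]
      params$loadings <- lam / c1
      params$factor_variance <- c1^2
    }
    imp <- tcrossprod(lam) + diag(res, py)
    nm <- paste0("Y", 1:py)
  }
  dimnames(imp) <- list(nm, nm)
  fit <- structure(
    list(params = params,
         discrepancy = max(fml_discrepancy(sample, imp), 0),
         converged = converged,
         implied = imp,
         spec = spec,
         # canonical (unit-variance) solution kept for score computation
         unit_loadings = lam,
         unit_structural = if (spec$has_predictor) b else NULL),
    class = "factor_fit")
  fit$score_weights <- regression_score_weights(fit)
  fit
}

#' @export
print.factor_fit <- function(x, ...) {
  cat("One-factor", if (x$spec$has_predictor) "MIMIC", "ML fit (",
      x$spec$identification, ")\n", sep = " ")
  cat("  loadings          :", format(round(x$params$loadings, 4)), "\n")
  cat("  residual variances:", format(round(x$params$residual_variances, 4)), "\n")
  if (x$spec$has_predictor)
    cat("  structural coeff b:", format(round(x$params$structural_coeff, 4)), "\n")
  cat("  F_ML =", format(x$discrepancy, digits = 6),
      " converged:", x$converged, "\n")
  invisible(x)
}

#' Thurstone regression factor-score weights
#'
#' Computes the regression (Thurstone) weights `w = Lambda' Sigma^-1` from a
#' fitted model, so the factor score for a data row `x` is `w %*% x`
#' (indicator columns only in the MIMIC layout).  The conventional
#' `var(theta)` premultiplier is omitted: it is a common scale factor across
#' indicators and drops out once scores are standardized.
#'
#' @param fit a [fit_ml()] result.
#' @param cov_used covariance matrix to invert; defaults to the model-implied
#'   indicator covariance matrix.
#' @return A numeric weight vector of length `n_indicators`.
#' @export
regression_score_weights <- function(fit, cov_used = NULL) {
  lam <- fit$unit_loadings
  py <- length(lam)
  sig <- cov_used %||% {
    imp <- fit$implied
    if (fit$spec$has_predictor) imp[-1, -1, drop = FALSE] else imp
  }
  if (nrow(sig) != py)
    stop("cov_used must cover the indicator block (", py, " variables)",
         call. = FALSE)
  r <- tryCatch(chol(sig), error = function(e)
    stop("covariance matrix for score weights is singular", call. = FALSE))
  as.vector(chol2inv(r) %*% lam)
}
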