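#' Simple linear regression with a two-sided slope test
#'
#' The fitting primitive of the detection algorithm: ordinary least squares
#' of `y` on `x` via the normal equations, with a t test of H0: slope = 0 on
#' n - 2 degrees of freedom. Pairs with a non-finite value in either vector
#' are dropped before fitting.
#'
#' Degenerate fits are given a defined answer rather than `NaN`: when the
#' residual sum of squares is (numerically) zero the p-value is 0 for a
#' non-zero slope and 1 for a zero slope; a zero slope (Sxy = 0) always gets
#' p = 1.
#'
#' @param x numeric covariate vector.
#' @param y numeric response vector, same length.
#' @return An `ols_fit` list: `beta0` (intercept), `beta1` (slope),
#'   `se_beta1`, `pvalue`, `n`, `df`.
#' @examples
#' fit_ols(c(0, 1, 2, 3), c(1, 2, 2, 3))  # slope 0.6, intercept 1.1
#' @export
fit_ols <- function(x, y) {
  if (length(x) != length(y))
    spike_error("'x' and 'y' must have the same length", "spike_input_error")
  keep <- is.finite(x) & is.finite(y)
  x <- as.numeric(x[keep])
  y <- as.numeric(y[keep])
  n <- length(x)
  if (n < 3L)
    spike_error(sprintf("need at least 3 complete observations, got %d", n),
                "spike_insufficient_error")
  xbar <- mean(x)
  ybar <- mean(y)
  dx <- x - xbar
  dy <- y - ybar
  sxx <- sum(dx * dx)
  if (sxx == 0)
    spike_error("covariate is constant: slope is not identifiable",
                "spike_degenerate_error")
  sxy <- sum(dx * dy)
  syy <- sum(dy * dy)
  beta1 <- sxy / sxx
  beta0 <- ybar - beta1 * xbar
  rss <- max(syy - beta1 * sxy, 0)
  df <- n - 2L
  if (beta1 == 0) {
    se <- if (rss > 0) sqrt(rss / df / sxx) else 0
    pvalue <- 1
  } else if (syy == 0 || rss <= 1e-12 * syy) {
    # numerically exact line: the t statistic diverges
    se <- 0
    pvalue <- 0
  } else {
    se <- sqrt(rss / df / sxx)
    tval <- beta1 / se
    pvalue <- 2 * stats::pt(-abs(tval), df)
  }
  structure(list(beta0 = beta0, beta1 = beta1, se_beta1 = se,
                 pvalue = pvalue, n = n, df = df),
            class = "ols_fit")
}

#' @export
print.ols_fit <- function(x, ...) {
  cat(sprintf("ols_fit: beta0=%.6g, beta1=%.6g (se %.6g), p=%.4g, n=%d\n",
              x$beta0, x$beta1, x$se_beta1, x$pvalue, x$n))
  invisible(x)
}

#' Predict from a fitted simple regression
#'
#' @param fit an `ols_fit` from [fit_ols()].
#' @param x0 covariate value(s) at which to predict.
#' @return `beta0 + beta1 * x0`.
#' @export
predict_at <- function(fit, x0) {
  if (!inherits(fit, "ols_fit"))
    spike_error("'fit' must be an ols_fit", "spike_input_error")
  fit$beta0 + fit$beta1 * x0
}
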