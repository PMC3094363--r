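#' @title Asymptotic height-diameter model
#' @description Chapman-Richards height model used to supply heights to
#'   standard (DBH-and-height) equations so that envelopes are indexed by
#'   DBH alone.
#' @name height_model
NULL

#' Height-model parameters
#'
#' Parameters of the asymptotic height-DBH curve
#' `h = b0 * (1 - exp(b1 * d))^b2` with `h` in m and `d` (DBH) in cm.
#' `b0` is the asymptotic maximum height (m), `b1 < 0` the steepness and
#' `b2 > 0` the curvature. The asymptote avoids the unrealistic heights many
#' other forms predict for large trees.
#'
#' @param species species code.
#' @param b0 asymptotic maximum height, m (> 0).
#' @param b1 steepness, per cm (< 0).
#' @param b2 curvature, dimensionless (> 0).
#' @param n optional fit sample size (metadata).
#' @param mse optional fit mean squared error (metadata).
#' @return object of class `height_params`.
#' @export
height_params <- function(species, b0, b1, b2, n = NA_integer_, mse = NA_real_) {
  stopifnot(is_num1(b0), is_num1(b1), is_num1(b2))
  if (b0 <= 0) stopf("b0 (asymptotic height) must be positive")
  if (b1 >= 0) stopf("b1 (steepness) must be negative")
  if (b2 <= 0) stopf("b2 (curvature) must be positive")
  structure(list(species = species, b0 = b0, b1 = b1, b2 = b2,
                 n = n, mse = mse),
            class = "height_params")
}

#' @export
print.height_params <- function(x, ...) {
  cat(sprintf("<height_params> %s: h = %.4g * (1 - exp(%.4g d))^%.4g\n",
              x$species, x$b0, x$b1, x$b2))
  invisible(x)
}

#' Predict height from DBH
#'
#' @param params a [height_params()] object.
#' @param dbh DBH in cm, `>= 0` (vectorised).
#' @return heights in m, in `[0, b0)`, strictly increasing in `dbh`.
#' @export
#' @examples
#' psme <- height_params("PSME", b0 = 63.054, b1 = -0.016, b2 = 1.0711)
#' predict_height(psme, 50)  # about 33.3 m
predict_height <- function(params, dbh) {
  stopifnot(inherits(params, "height_params"))
  if (any(dbh < 0)) stopf("dbh must be non-negative")
  params$b0 * (1 - exp(params$b1 * dbh))^params$b2
}

#' Fit the height-DBH model to class means
#'
#' Weighted nonlinear least squares (Levenberg-Marquardt) of
#' `h = b0 (1 - exp(b1 d))^b2` on (DBH class, mean height) pairs, weighted by
#' `1/d` so small classes, which are far more numerous in an inventory, are
#' not swamped by the tall tail. The starting point is fixed at
#' `(b0 = 1.05 * max(h), b1 = -0.02, b2 = 1)` so fits are reproducible.
#'
#' @param dbh DBH classes, cm.
#' @param height mean measured height per class, m (positive).
#' @param weights fitting weights; default `1/dbh`.
#' @return a [height_params()] object with attributes `mse` (weighted
#'   residual mean square) and `convergence` (optimizer message).
#' @export
fit_height_params <- function(dbh, height, weights = 1 / dbh) {
  if (length(dbh) != length(height)) stopf("dbh and height lengths differ")
  keep <- is.finite(dbh) & is.finite(height)
  dbh <- dbh[keep]; height <- height[keep]; weights <- weights[keep]
  if (length(unique(dbh)) < 4L)
    stopf("need at least 4 distinct DBH classes to fit 3 parameters")
  if (any(height <= 0)) stopf("heights must be positive")
  if (diff(range(height)) == 0) stopf("degenerate input: all heights equal")
  dat <- data.frame(d = dbh, h = height)
  start <- list(b0 = 1.05 * max(height), b1 = -0.02, b2 = 1.0)
  fit <- minpack.lm::nlsLM(
    h ~ b0 * (1 - exp(b1 * d))^b2,
    data = dat, start = start, weights = weights,
    lower = c(b0 = 1e-6, b1 = -Inf, b2 = 1e-6),
    upper = c(b0 = Inf, b1 = -1e-12, b2 = Inf),
    control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-15,
                                         ptol = 1e-15)
  )
  if (!fit$convInfo$isConv)
    stopf("height fit did not converge: %s", fit$convInfo$stopMessage)
  cf <- stats::coef(fit)
  out <- height_params(species = "fitted", b0 = cf[["b0"]], b1 = cf[["b1"]],
                       b2 = cf[["b2"]], n = length(dbh),
                       mse = sum(weights * stats::resid(fit)^2) /
                         stats::df.residual(fit))
  attr(out, "convergence") <- fit$convInfo$stopMessage
  out
}
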