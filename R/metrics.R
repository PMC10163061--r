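#' Goodness-of-fit metrics for growth-model evaluation
#'
#' The three metrics used throughout the package to evaluate growth and
#' response models: the squared Pearson correlation (`r_squared()`), the
#' root-mean-square error (`rmse()`), and a sum-of-squares relative error
#' (`relative_error()`) reported in percent — the ratio of the error sum of
#' squares to the sum of squared measured values, times 100.
#'
#' @param x,y Numeric vectors of equal length (at least 2) with nonzero
#'   variance.
#' @param measured,calculated Numeric vectors of equal, nonzero length:
#'   observed values and the model's predictions for them.
#'
#' @return A single numeric value: `r_squared()` is dimensionless in
#'   \[0, 1\], `rmse()` is in the units of `measured`, and
#'   `relative_error()` is a percentage.
#'
#' @examples
#' r_squared(c(1, 2, 3), c(1, 2, 2))      # 0.75
#' rmse(c(1, 2), c(2, 2))                 # sqrt(0.5)
#' relative_error(c(1, 2), c(2, 2))       # 20 (percent)
#' @name fit-metrics
NULL

#' @rdname fit-metrics
#' @export
r_squared <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 2) abort("`r_squared()` needs at least 2 paired values.")
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    abort("`r_squared()` is undefined when either vector has zero variance.")
  }
  stats::cor(x, y)^2
}

#' @rdname fit-metrics
#' @export
rmse <- function(measured, calculated) {
  stopifnot(length(measured) == length(calculated))
  if (length(measured) == 0) abort("`rmse()` needs at least one value.")
  sqrt(mean((measured - calculated)^2))
}

#' @rdname fit-metrics
#' @export
relative_error <- function(measured, calculated) {
  stopifnot(length(measured) == length(calculated))
  ss_m <- sum(measured^2)
  if (ss_m == 0) abort("`relative_error()` is undefined for an all-zero measured vector.")
  100 * sum((measured - calculated)^2) / ss_m
}

#' Relative deviation between a fitted and an independently calculated parameter
#'
#' Compares two estimates of the same model coefficient — typically one fitted
#' directly to data and one obtained algebraically through the driver link —
#' as `|calculated - fitted| / |fitted|`.
#'
#' @param fitted Nonzero reference value (the directly fitted coefficient).
#' @param calculated The value to compare against it.
#' @return Dimensionless relative deviation, `>= 0`. Vectorised.
#' @examples
#' param_deviation(3.525, 3.548)  # ~0.0065
#' @export
param_deviation <- function(fitted, calculated) {
  if (any(fitted == 0)) abort("`param_deviation()` is undefined for fitted = 0.")
  abs(calculated - fitted) / abs(fitted)
}
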