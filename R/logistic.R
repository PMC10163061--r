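# Relative logistic growth curves: relative index = 1/(1 + exp(u(x))) with
# u(x) = intercept + slope * x (H, D) or + curvature * x^2 (LAI), x being a
# relative season driver on [0, 1].

#' Relative logistic growth model
#'
#' Constructs a relative logistic growth curve
#' `R(x) = 1 / (1 + exp(intercept + slope * x [+ curvature * x^2]))`
#' where `x` is a relative season driver (cumulative GDD or cumulative
#' reference evapotranspiration divided by its season total). A linear
#' exponent gives the monotone sigmoid used for plant height and dry matter
#' (negative `slope` for a growth curve); adding a positive `curvature`
#' gives the rise-then-fall curve used for leaf area index.
#'
#' @param intercept,slope Dimensionless exponent coefficients.
#' @param curvature Dimensionless quadratic exponent coefficient, or `NULL`
#'   for the linear form. Must be positive for a rise-then-fall curve;
#'   non-positive values are accepted (the model is still a valid curve) but
#'   [peak_driver()] will refuse them.
#' @param driver Which relative driver the curve is expressed in:
#'   `"cgdd"` or `"ceto"`.
#' @param index Growth index the curve describes: `"H"` (plant height, cm),
#'   `"LAI"` (leaf area index), or `"D"` (dry matter, g/plant).
#' @return An object of class `logistic_growth`.
#' @examples
#' m <- logistic_growth(2.82, -5.424, driver = "cgdd", index = "H")
#' predict(m, x = c(0.25, 0.5, 0.75))
#' @export
logistic_growth <- function(intercept, slope,
                            curvature = NULL,
                            driver = c("cgdd", "ceto"),
                            index = c("H", "LAI", "D")) {
  driver <- match.arg(driver)
  index <- match.arg(index)
  stopifnot(is.numeric(intercept), is.numeric(slope), length(intercept) == 1,
            length(slope) == 1)
  if (slope == 0) abort("`slope` must be nonzero.")
  if (!is.null(curvature)) {
    stopifnot(is.numeric(curvature), length(curvature) == 1)
  }
  structure(
    list(intercept = intercept, slope = slope, curvature = curvature,
         driver = driver, index = index),
    class = "logistic_growth"
  )
}

is_quadratic <- function(object) !is.null(object$curvature)

exponent_value <- function(object, x) {
  u <- object$intercept + object$slope * x
  if (is_quadratic(object)) u <- u + object$curvature * x^2
  u
}

#' @export
print.logistic_growth <- function(x, ...) {
  form <- if (is_quadratic(x)) "quadratic" else "linear"
  cat(sprintf(
    "<logistic_growth> index %s, driver R_%s (%s exponent)\n",
    x$index, x$driver, form
  ))
  cf <- coef(x)
  cat("  1/(1 + exp(", paste(signif(cf, 5), collapse = ", "), "))\n")
  invisible(x)
}

#' @export
coef.logistic_growth <- function(object, ...) {
  if (is_quadratic(object)) {
    c(intercept = object$intercept, slope = object$slope,
      curvature = object$curvature)
  } else {
    c(intercept = object$intercept, slope = object$slope)
  }
}

#' Evaluate a relative logistic growth curve
#'
#' @param object A [logistic_growth()] model.
#' @param x Relative driver values. The model is defined on \[0, 1\];
#'   values outside are evaluated (extrapolation) with a warning.
#' @param ... Unused.
#' @return Relative index values in (0, 1).
#' @examples
#' predict(cotton_model("H", "cgdd"), x = 0.5)
#' @export
predict.logistic_growth <- function(object, x, ...) {
  warn_extrapolation(x)
  1 / (1 + exp(exponent_value(object, x)))
}

warn_extrapolation <- function(x) {
  if (any(x < 0 | x > 1, na.rm = TRUE)) {
    warn("Relative driver outside [0, 1]: extrapolating the growth curve.")
  }
  invisible(NULL)
}

#' Growth rate of a relative logistic curve
#'
#' First derivative of the relative index with respect to the relative
#' driver: `-u'(x) R (1 - R)` with `R` the predicted value and `u` the
#' exponent polynomial.
#'
#' @inheritParams predict.logistic_growth
#' @param model A [logistic_growth()] model.
#' @return Derivative values (dimensionless).
#' @examples
#' growth_rate(cotton_model("H", "cgdd"), 0.52)
#' @export
growth_rate <- function(model, x) {
  stopifnot(inherits(model, "logistic_growth"))
  warn_extrapolation(x)
  r <- 1 / (1 + exp(exponent_value(model, x)))
  uprime <- model$slope
  if (is_quadratic(model)) uprime <- uprime + 2 * model$curvature * x
  -uprime * r * (1 - r)
}

#' Driver value at which a rise-then-fall curve peaks
#'
#' For a quadratic-exponent curve with positive curvature the relative index
#' is maximal where the exponent is minimal, at `-slope / (2 curvature)`.
#'
#' @param model A quadratic [logistic_growth()] model with
#'   `curvature > 0`.
#' @return The peak relative driver value.
#' @examples
#' peak_driver(cotton_model("LAI", "cgdd"))  # ~0.794
#' @export
peak_driver <- function(model) {
  stopifnot(inherits(model, "logistic_growth"))
  if (!is_quadratic(model)) {
    abort("A linear-exponent curve is monotone: no interior peak.")
  }
  if (model$curvature <= 0) {
    abort("`curvature` must be positive for an interior maximum.")
  }
  -model$slope / (2 * model$curvature)
}

#' Theoretical maximum of a growth index
#'
#' Field-observed seasonal maxima underestimate the asymptote of the growth
#' curve, so the observed maximum is inflated by a small factor (between
#' 1.01 and 1.05) before normalising observations.
#'
#' @param observed_max Observed seasonal maximum (> 0), in index units.
#' @param factor Inflation factor, within \[1.01, 1.05\] unless
#'   `strict = FALSE`.
#' @param strict Enforce the standard factor range (default `TRUE`).
#' @return `observed_max * factor`.
#' @examples
#' theoretical_max(100, 1.03)  # 103
#' @export
theoretical_max <- function(observed_max, factor = 1.03, strict = TRUE) {
  if (any(observed_max <= 0)) abort("`observed_max` must be positive.")
  if (strict && any(factor < 1.01 | factor > 1.05)) {
    abort("`factor` outside [1.01, 1.05]; pass strict = FALSE to override.")
  }
  observed_max * factor
}

#' Convert a relative index back to absolute units
#'
#' @param relative_value Relative index in \[0, 1\].
#' @param theoretical_max Theoretical maximum of the index (> 0).
#' @return Absolute index value, `relative_value * theoretical_max`.
#' @examples
#' denormalize(0.5, 103)  # 51.5
#' @export
denormalize <- function(relative_value, theoretical_max) {
  if (any(theoretical_max <= 0)) abort("`theoretical_max` must be positive.")
  relative_value * theoretical_max
}

#' Curve and rate plot for a logistic growth model
#'
#' @param object A [logistic_growth()] model.
#' @param n Number of grid points on \[0, 1\].
#' @param ... Unused.
#' @return A ggplot showing the relative index and its growth rate.
#' @method autoplot logistic_growth
#' @export
autoplot.logistic_growth <- function(object, n = 201, ...) {
  x <- seq(0, 1, length.out = n)
  df <- tibble::tibble(
    x = rep(x, 2),
    value = c(predict(object, x), growth_rate(object, x)),
    what = rep(c("relative index", "growth rate"), each = n)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~what, scales = "free_y") +
    ggplot2::labs(
      x = paste0("relative ", toupper(object$driver)),
      y = NULL,
      title = paste0("Relative ", object$index, " logistic model")
    )
}
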