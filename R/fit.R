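# Nonlinear least-squares estimation of the relative logistic growth
# curves, with logit-linearised ordinary least squares supplying start
# values and Levenberg-Marquardt refining them on the original scale.

#' Fit a relative logistic growth curve to observations
#'
#' Estimates the exponent coefficients of a relative logistic growth model
#' from paired observations of relative driver (`x`) and relative growth
#' index (`y`). The objective is ordinary least squares on the original
#' scale, `sum((y - 1/(1 + exp(u(x))))^2)`, minimised by
#' Levenberg-Marquardt ([minpack.lm::nlsLM()]); start values come from an
#' ordinary linear regression of the logit `log(1/y - 1)` on `x` (and `x^2`
#' for the quadratic form). Observations with `y` exactly 0 or 1 are nudged
#' into the open interval by 1e-6 for the logit initialiser only; the main
#' objective uses the raw values.
#'
#' @param data Data frame with numeric columns `x` (relative driver, in
#'   \[0, 1\]) and `y` (relative index, in (0, 1)).
#' @param form `"linear"` (plant height, dry matter) or `"quadratic"`
#'   (leaf area index).
#' @param driver,index Labels stored on the fitted model, see
#'   [logistic_growth()].
#' @return An object of class `growth_fit`: the fitted [logistic_growth()]
#'   model plus evaluation metrics ([r_squared()], [rmse()],
#'   [relative_error()]) computed on the fitted curve. Supports `tidy()`,
#'   `glance()`, `predict()`, and `autoplot()`.
#' @examples
#' mod <- cotton_model("H", "cgdd")
#' obs <- tibble::tibble(x = seq(0.05, 1, length.out = 20),
#'                       y = predict(mod, seq(0.05, 1, length.out = 20)))
#' fit_growth(obs, form = "linear")
#' @export
fit_growth <- function(data, form = c("linear", "quadratic"),
                       driver = c("cgdd", "ceto"),
                       index = NULL) {
  form <- match.arg(form)
  driver <- match.arg(driver)
  index <- index %||% if (form == "quadratic") "LAI" else "H"
  stopifnot(all(c("x", "y") %in% names(data)))
  data <- tibble::as_tibble(data)[c("x", "y")]
  min_n <- if (form == "linear") 3 else 4
  if (nrow(data) < min_n) {
    abort(paste0("Need at least ", min_n, " observations for the ", form, " form."))
  }
  if (length(unique(data$x)) < min_n) {
    abort("Too few distinct `x` values for a stable fit.")
  }

  start <- logit_start(data$x, data$y, form)
  ctrl <- minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-12, ptol = 1e-12)
  fit <- if (form == "linear") {
    minpack.lm::nlsLM(
      y ~ 1 / (1 + exp(a + b * x)),
      data = data, start = list(a = start[1], b = start[2]), control = ctrl
    )
  } else {
    minpack.lm::nlsLM(
      y ~ 1 / (1 + exp(a + b * x + c * x^2)),
      data = data, start = list(a = start[1], b = start[2], c = start[3]),
      control = ctrl
    )
  }
  cf <- coef(fit)
  model <- logistic_growth(
    unname(cf["a"]), unname(cf["b"]),
    curvature = if (form == "quadratic") unname(cf["c"]) else NULL,
    driver = driver, index = index
  )
  yhat <- predict(model, data$x)
  structure(
    list(
      model = model,
      data = data,
      n = nrow(data),
      r_squared = r_squared(data$y, yhat),
      rmse = rmse(data$y, yhat),
      re_pct = relative_error(data$y, yhat)
    ),
    class = "growth_fit"
  )
}

# OLS on the logit scale; boundary y values are nudged inward so the
# transform is defined, for start values only.
logit_start <- function(x, y, form) {
  eps <- 1e-6
  yc <- pmin(pmax(y, eps), 1 - eps)
  z <- log(1 / yc - 1)
  cf <- if (form == "linear") {
    coef(lm(z ~ x))
  } else {
    coef(lm(z ~ x + I(x^2)))
  }
  unname(cf)
}

#' @export
print.growth_fit <- function(x, ...) {
  cat("<growth_fit>\n")
  print(x$model)
  cat(sprintf("  n = %d, R^2 = %.4f, RMSE = %.4f, RE = %.3f%%\n",
              x$n, x$r_squared, x$rmse, x$re_pct))
  invisible(x)
}

#' @export
predict.growth_fit <- function(object, x, ...) {
  predict(object$model, x, ...)
}

#' @export
coef.growth_fit <- function(object, ...) coef(object$model)

#' Tidy a fitted growth curve
#'
#' @param x A [fit_growth()] result.
#' @param ... Unused.
#' @return One row per exponent coefficient with `term` and `estimate`.
#' @method tidy growth_fit
#' @export
tidy.growth_fit <- function(x, ...) {
  cf <- coef(x$model)
  tibble::tibble(term = names(cf), estimate = unname(cf))
}

#' One-row fit summary
#'
#' @param x A [fit_growth()] result.
#' @param ... Unused.
#' @return A one-row tibble with labels, sample size and fit metrics.
#' @method glance growth_fit
#' @export
glance.growth_fit <- function(x, ...) {
  tibble::tibble(
    index = x$model$index,
    driver = x$model$driver,
    form = if (is_quadratic(x$model)) "quadratic" else "linear",
    n = x$n,
    r_squared = x$r_squared,
    rmse = x$rmse,
    re_pct = x$re_pct
  )
}

#' Observations with the fitted growth curve
#'
#' @param object A [fit_growth()] result.
#' @param ... Unused.
#' @return A ggplot of the observations overlaid with the fitted curve.
#' @method autoplot growth_fit
#' @export
autoplot.growth_fit <- function(object, ...) {
  grid <- tibble::tibble(x = seq(0, 1, length.out = 201))
  grid$y <- predict(object$model, grid$x)
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_line(data = grid, colour = "steelblue") +
    ggplot2::labs(
      x = paste0("relative ", toupper(object$model$driver)),
      y = paste0("relative ", object$model$index),
      title = sprintf("Logistic fit (R² = %.3f)", object$r_squared)
    )
}

#' Fit a quadratic response curve by ordinary least squares
#'
#' Fits `y = q2 x^2 + q1 x + q0`, the form used for the yield and leaf-area
#' responses, typically to binned category means (see [bin_average()]).
#'
#' @param data Data frame with numeric columns `x` and `y` (at least 3
#'   distinct `x`).
#' @param role Passed to [quad_response()].
#' @return A [quad_response()] object with an `r_squared` attribute.
#' @examples
#' d <- tibble::tibble(x = 1:6, y = -2 * (1:6)^2 + 3 * (1:6) + 1)
#' fit_quad_response(d)
#' @export
fit_quad_response <- function(data, role = "custom") {
  stopifnot(all(c("x", "y") %in% names(data)))
  if (length(unique(data$x)) < 3) abort("Need at least 3 distinct `x` values.")
  fit <- lm(y ~ x + I(x^2), data = data)
  cf <- coef(fit)
  resp <- quad_response(unname(cf[3]), unname(cf[2]), unname(cf[1]), role = role)
  attr(resp, "r_squared") <- r_squared(data$y, predict(fit))
  resp
}
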