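# The linear relative-driver link r_ceto = m * r_cgdd + n and the exact
# algebra it induces between CGDD-based and CETo-based logistic exponents.

#' Linear link between the two relative drivers
#'
#' Within a region the relative cumulative reference evapotranspiration is
#' very nearly a linear function of the relative cumulative growing degree
#' days, `r_ceto = m * r_cgdd + n`. Under this link, logistic growth
#' parameters convert exactly between the two driver bases
#' (see [convert_params()]).
#'
#' @param m Slope (must be positive: both drivers accumulate forward).
#' @param n Intercept.
#' @param r_squared Optional fit diagnostic when the link was estimated from
#'   paired driver series.
#' @return An object of class `driver_link`.
#' @examples
#' driver_link(0.95, 0.05)
#' @export
driver_link <- function(m, n, r_squared = NA_real_) {
  stopifnot(is.numeric(m), is.numeric(n), length(m) == 1, length(n) == 1)
  if (!is.finite(m) || m <= 0) abort("Link slope `m` must be positive.")
  structure(list(m = m, n = n, r_squared = r_squared), class = "driver_link")
}

#' @export
print.driver_link <- function(x, ...) {
  cat(sprintf("<driver_link> r_ceto = %.4f * r_cgdd + %.4f", x$m, x$n))
  if (is.finite(x$r_squared)) cat(sprintf("  (R^2 = %.4f)", x$r_squared))
  cat("\n")
  invisible(x)
}

#' Fit the linear driver link from paired relative driver series
#'
#' Ordinary least squares of relative cumulative reference
#' evapotranspiration on relative cumulative growing degree days, matched
#' day by day, with the squared Pearson correlation as diagnostic.
#'
#' @param data Data frame with columns `r_cgdd` and `r_ceto` (as produced by
#'   [accumulate_drivers()]).
#' @return A [driver_link()] with its `r_squared` filled in.
#' @examples
#' drv <- accumulate_drivers(simulate_weather(climate_profile("arid-continental"), seed = 1))
#' fit_driver_link(drv)
#' @export
fit_driver_link <- function(data) {
  stopifnot(all(c("r_cgdd", "r_ceto") %in% names(data)))
  if (nrow(data) < 2) abort("Need at least 2 paired driver values.")
  if (stats::var(data$r_cgdd) == 0) abort("Degenerate r_cgdd series (zero variance).")
  fit <- lm(r_ceto ~ r_cgdd, data = data)
  cf <- coef(fit)
  driver_link(unname(cf[2]), unname(cf[1]),
              r_squared = r_squared(data$r_cgdd, data$r_ceto))
}

#' Invert a driver link
#'
#' Returns the link mapping in the opposite direction,
#' `r_cgdd = (1/m) * r_ceto - n/m`.
#'
#' @param link A [driver_link()].
#' @return The inverse [driver_link()].
#' @export
invert_link <- function(link) {
  stopifnot(inherits(link, "driver_link"))
  driver_link(1 / link$m, -link$n / link$m, r_squared = link$r_squared)
}

#' Convert logistic growth parameters between driver bases
#'
#' Given a CGDD-based model with exponent `a + b x (+ c x^2)` and the link
#' `X = m x + n` to the CETo driver, the CETo-based exponent
#' `d + e X (+ f X^2)` that represents the identical curve is obtained in
#' closed form: `e = b/m`, `d = a - b n / m` for the linear form, and
#' `f = c/m^2`, `e = (b m - 2 c n)/m^2`, `d = a - (b m n - c n^2)/m^2` for
#' the quadratic form. Converting a CETo-based model uses the inverted link
#' automatically, so the operation is its own inverse.
#'
#' @param model A [logistic_growth()] model.
#' @param link The [driver_link()] from the CGDD to the CETo relative
#'   driver for the region.
#' @return A [logistic_growth()] model expressed in the other driver, whose
#'   predictions agree with `model` at linked driver values.
#' @examples
#' m_cgdd <- cotton_model("H", "cgdd")
#' convert_params(m_cgdd, driver_link(0.9464, 0.0574))
#' @export
convert_params <- function(model, link) {
  stopifnot(inherits(model, "logistic_growth"), inherits(link, "driver_link"))
  if (model$driver == "ceto") link <- invert_link(link)
  m <- link$m
  n <- link$n
  a <- model$intercept
  b <- model$slope
  target <- if (model$driver == "cgdd") "ceto" else "cgdd"
  if (is_quadratic(model)) {
    cc <- model$curvature
    f <- cc / m^2
    e <- (b * m - 2 * cc * n) / m^2
    d <- a - (b * m * n - cc * n^2) / m^2
    logistic_growth(d, e, curvature = f, driver = target, index = model$index)
  } else {
    logistic_growth(a - b * n / m, b / m, driver = target, index = model$index)
  }
}

#' Recover a driver link from a converted parameter pair
#'
#' Inverts the conversion algebra: given the CGDD-based coefficients and the
#' CETo-based coefficients of the same curve, solve for the link `(m, n)`
#' that relates them. For the linear exponent, `m = b/e` and
#' `n = (a - d) m / b`; for the quadratic exponent, `m = sqrt(c/f)` and
#' `n = (b m - e m^2) / (2 c)`.
#'
#' @param a,b,c CGDD-based intercept, slope and (quadratic only) curvature.
#' @param d,e,f CETo-based counterparts.
#' @return A [driver_link()].
#' @examples
#' recover_link_linear(3.190, -5.969, 3.548, -6.399)  # Korla height pair
#' @name recover-link
NULL

#' @rdname recover-link
#' @export
recover_link_linear <- function(a, b, d, e) {
  if (b == 0 || e == 0) abort("Slopes must be nonzero to recover a link.")
  m <- b / e
  driver_link(m, (a - d) * m / b)
}

#' @rdname recover-link
#' @export
recover_link_quadratic <- function(a, b, c, d, e, f) {
  if (c == 0 || f == 0) abort("Curvatures must be nonzero to recover a link.")
  ratio <- c / f
  if (ratio <= 0) abort("Curvatures must share a sign to recover a real link.")
  m <- sqrt(ratio)
  driver_link(m, (b * m - e * m^2) / (2 * c))
}

#' Evaluate a cubic driver link
#'
#' Some studies describe the relation between the relative drivers with a
#' cubic polynomial `r_ceto = g x^3 + h x^2 + k x + l`. The cubic is
#' awkward under parameter conversion, so this package only evaluates it;
#' the linear link is the working form.
#'
#' @param coefs Numeric vector `c(g, h, k, l)`, highest degree first.
#' @param x Relative CGDD values.
#' @return Relative CETo values.
#' @examples
#' eval_cubic_link(c(0, 0, 1, 0), 0.3)  # identity
#' @export
eval_cubic_link <- function(coefs, x) {
  stopifnot(length(coefs) == 4, is.numeric(coefs))
  ((coefs[1] * x + coefs[2]) * x + coefs[3]) * x + coefs[4]
}
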