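# Daily and cumulative season drivers: growing degree days and FAO-56
# Penman-Monteith reference evapotranspiration.

#' Effective mean temperature for thermal-time accumulation
#'
#' The daily mean `(t_max + t_min)/2` clamped into the crop's active
#' temperature window. For cotton the window is 10–40 °C: below the base the
#' day contributes no heat, above the upper limit extra heat is not counted.
#' Only the mean is clamped, never the individual extremes.
#'
#' @param t_max,t_min Daily maximum and minimum air temperature, °C.
#'   `t_max >= t_min` is required.
#' @param t_base,t_upper Lower and upper temperature limits, °C
#'   (defaults 10 and 40).
#' @return Effective mean temperature in °C, within `[t_base, t_upper]`.
#'   Vectorised over days.
#' @examples
#' gdd_mean_temp(30, 20)  # 25
#' gdd_mean_temp(8, 4)    # clamped up to 10
#' @export
gdd_mean_temp <- function(t_max, t_min, t_base = 10, t_upper = 40) {
  check_thermal_limits(t_base, t_upper)
  if (any(t_max < t_min)) {
    abort("`t_max` must be >= `t_min` for every day.")
  }
  pmin(pmax((t_max + t_min) / 2, t_base), t_upper)
}

#' Daily growing degree days
#'
#' Heat accumulated in one day: the effective mean temperature (see
#' [gdd_mean_temp()]) minus the base temperature. Always in
#' `[0, t_upper - t_base]`.
#'
#' @inheritParams gdd_mean_temp
#' @return Daily GDD in °C·d. Vectorised.
#' @examples
#' gdd_daily(30, 20)  # 15
#' gdd_daily(8, 4)    # 0
#' @export
gdd_daily <- function(t_max, t_min, t_base = 10, t_upper = 40) {
  gdd_mean_temp(t_max, t_min, t_base, t_upper) - t_base
}

check_thermal_limits <- function(t_base, t_upper) {
  if (!(t_base < t_upper)) abort("`t_base` must be strictly below `t_upper`.")
  invisible(NULL)
}

#' FAO-56 atmospheric helper quantities
#'
#' Standard auxiliary formulas of the FAO-56 Penman-Monteith method:
#' saturation vapor pressure (Tetens form), the slope of the saturation
#' vapor pressure curve, the psychrometric constant, and atmospheric
#' pressure from elevation.
#'
#' @param t Air temperature, °C.
#' @param pressure Atmospheric pressure, kPa (101.3 at sea level).
#' @param elevation_m Elevation above sea level, m.
#' @return `svp()` and `svp_slope()` return kPa and kPa/°C;
#'   `psychrometric_gamma()` kPa/°C; `pressure_at_elevation()` kPa.
#' @examples
#' svp_slope(20)
#' psychrometric_gamma(101.3)
#' @name fao56-atmos
NULL

#' @rdname fao56-atmos
#' @export
svp <- function(t) {
  0.6108 * exp(17.27 * t / (t + 237.3))
}

#' @rdname fao56-atmos
#' @export
svp_slope <- function(t) {
  4098 * svp(t) / (t + 237.3)^2
}

#' @rdname fao56-atmos
#' @export
psychrometric_gamma <- function(pressure = 101.3) {
  if (any(pressure <= 0)) abort("`pressure` must be positive.")
  0.000665 * pressure
}

#' @rdname fao56-atmos
#' @export
pressure_at_elevation <- function(elevation_m) {
  101.3 * ((293 - 0.0065 * elevation_m) / 293)^5.26
}

#' Daily FAO-56 Penman-Monteith reference evapotranspiration
#'
#' Evapotranspiration of a well-watered reference grass surface,
#' `[0.408 Delta (Rn - G) + gamma 900/(T+273) u2 (es - ea)] /`
#' `[Delta + gamma (1 + 0.34 u2)]`, in mm/day. The value can be negative on
#' days where soil heat flux exceeds net radiation; accumulation into a
#' season driver clamps such days to zero (see [accumulate_drivers()]) but
#' this function returns the raw value.
#'
#' @param t_mean Mean daily air temperature, °C.
#' @param u2 Wind speed at 2 m, m/s.
#' @param es,ea Saturation and actual vapor pressure, kPa (`es >= ea >= 0`).
#' @param rn Net radiation, MJ/m^2/d.
#' @param g Soil heat flux, MJ/m^2/d; 0 by the FAO-56 daily convention.
#' @param pressure Atmospheric pressure, kPa.
#' @return Reference evapotranspiration, mm/d. Vectorised.
#' @examples
#' eto_daily(t_mean = 20, u2 = 2, es = 2.34, ea = 1.34, rn = 13.28)
#' @export
eto_daily <- function(t_mean, u2, es, ea, rn, g = 0, pressure = 101.3) {
  if (any(u2 < 0)) abort("`u2` must be nonnegative.")
  if (any(ea < 0) || any(es < ea)) abort("Need `es >= ea >= 0`.")
  delta <- svp_slope(t_mean)
  gamma <- psychrometric_gamma(pressure)
  if (any(delta <= 0) || any(gamma <= 0)) {
    abort("Slope and psychrometric constant must be positive.")
  }
  num <- 0.408 * delta * (rn - g) + gamma * (900 / (t_mean + 273)) * u2 * (es - ea)
  den <- delta + gamma * (1 + 0.34 * u2)
  num / den
}

#' Relative form of a cumulative series
#'
#' Divides a nondecreasing cumulative series by its season total, mapping it
#' onto \[0, 1\] with the last value exactly 1.
#'
#' @param cumulative Nondecreasing numeric vector with positive final value.
#' @return Numeric vector in \[0, 1\].
#' @examples
#' relative_series(c(15, 30, 45))  # 1/3 2/3 1
#' @export
relative_series <- function(cumulative) {
  total <- cumulative[length(cumulative)]
  if (length(cumulative) == 0) abort("Empty series.")
  if (total <= 0) abort("Season total must be positive to form a relative series.")
  cumulative / total
}

#' Compute season drivers from a daily weather table
#'
#' Takes a tibble of daily weather (one row per day, dates strictly
#' increasing) and appends the two season drivers and their relative forms:
#' daily and cumulative growing degree days (`daily_gdd`, `cgdd`), daily and
#' cumulative reference evapotranspiration (`daily_eto`, `ceto`), and the
#' relative drivers (`r_cgdd`, `r_ceto`) obtained by dividing each cumulative
#' series by its season total. The season window is the full extent of the
#' supplied table.
#'
#' Required columns: `date`, `tmax_c`, `tmin_c`, `u2_ms`, `rn_mj_m2_d`, and
#' either both `es_kpa` and `ea_kpa` or `rh_pct` (actual vapor pressure is
#' then `rh/100` times the saturation value, with saturation pressure taken
#' as the mean of its values at `tmax_c` and `tmin_c`). Optional columns:
#' `g_mj_m2_d` (default 0) and `elevation_m` (sets pressure via
#' [pressure_at_elevation()]; default 101.3 kPa).
#'
#' `daily_eto` is the raw Penman-Monteith value; negative days are clamped to
#' zero before accumulation so `ceto` is nondecreasing and `r_ceto`
#' monotone, as the relative logistic growth forms require.
#'
#' @param weather Data frame of daily weather as described above.
#' @param t_base,t_upper Thermal limits for GDD, °C.
#' @return The input as a tibble with the six driver columns appended.
#' @examples
#' w <- simulate_weather(climate_profile("arid-continental"), seed = 1)
#' drv <- accumulate_drivers(w)
#' tail(drv[, c("date", "cgdd", "ceto", "r_cgdd", "r_ceto")])
#' @export
accumulate_drivers <- function(weather, t_base = 10, t_upper = 40) {
  weather <- validate_weather(weather)
  es_ea <- weather_vapor_pressures(weather)
  pressure <- if ("elevation_m" %in% names(weather)) {
    pressure_at_elevation(weather$elevation_m)
  } else {
    101.3
  }
  g <- if ("g_mj_m2_d" %in% names(weather)) weather$g_mj_m2_d else 0

  t_mean <- (weather$tmax_c + weather$tmin_c) / 2
  daily_eto <- eto_daily(
    t_mean = t_mean, u2 = weather$u2_ms,
    es = es_ea$es, ea = es_ea$ea,
    rn = weather$rn_mj_m2_d, g = g, pressure = pressure
  )
  daily_gdd <- gdd_daily(weather$tmax_c, weather$tmin_c, t_base, t_upper)

  weather |>
    dplyr::mutate(
      daily_gdd = daily_gdd,
      cgdd = cumsum(daily_gdd),
      daily_eto = daily_eto,
      ceto = cumsum(pmax(daily_eto, 0)),
      r_cgdd = relative_series(.data$cgdd),
      r_ceto = relative_series(.data$ceto)
    )
}

validate_weather <- function(weather) {
  weather <- tibble::as_tibble(weather)
  needed <- c("date", "tmax_c", "tmin_c", "u2_ms", "rn_mj_m2_d")
  missing <- setdiff(needed, names(weather))
  if (length(missing) > 0) {
    abort(paste0("Weather table is missing columns: ", paste(missing, collapse = ", ")))
  }
  has_vp <- all(c("es_kpa", "ea_kpa") %in% names(weather))
  if (!has_vp && !("rh_pct" %in% names(weather))) {
    abort("Weather table needs either `es_kpa` + `ea_kpa` or `rh_pct`.")
  }
  if (nrow(weather) == 0) abort("Weather table is empty.")
  bad <- which(weather$tmax_c < weather$tmin_c)
  if (length(bad) > 0) {
    abort(paste0(
      "`tmax_c` below `tmin_c` on row(s): ", paste(bad, collapse = ", ")
    ))
  }
  d <- as.Date(weather$date)
  if (anyNA(d)) abort("Unparseable dates in weather table.")
  if (nrow(weather) > 1 && any(diff(as.numeric(d)) <= 0)) {
    abort("Dates must be strictly increasing.")
  }
  weather$date <- d
  weather
}

# es/ea either supplied directly or derived from relative humidity via the
# FAO-56 convention (saturation pressure averaged over the daily extremes).
weather_vapor_pressures <- function(weather) {
  if (all(c("es_kpa", "ea_kpa") %in% names(weather))) {
    list(es = weather$es_kpa, ea = weather$ea_kpa)
  } else {
    es <- (svp(weather$tmax_c) + svp(weather$tmin_c)) / 2
    list(es = es, ea = weather$rh_pct / 100 * es)
  }
}
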