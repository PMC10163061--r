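# Seasonal weather and growth-observation simulator. Emulates an
# April-October cotton season under contrasting climates so the driver,
# fitting and linkage machinery can be exercised end to end without any
# station record. Not a faithful stochastic weather generator: day-to-day
# structure is a seasonal sinusoid plus AR(1) noise.

#' Climate profile for the weather simulator
#'
#' Parameters of a stylised regional climate: an annual temperature
#' sinusoid peaking in mid-July, a diurnal range splitting the daily mean
#' into max/min, a seasonal net-radiation sinusoid, and mean relative
#' humidity and wind. Two named presets capture the regional contrast the
#' growth models span: `"arid-continental"` (large temperature range, dry
#' air, windy — an interior-basin cotton climate) and
#' `"warm-temperate-monsoon"` (milder range, humid summers).
#'
#' @param label Preset name, or any other label if the remaining arguments
#'   are given explicitly.
#' @param t_mean_annual Mean annual temperature, °C.
#' @param t_amplitude Seasonal half-amplitude of the daily-mean temperature, °C.
#' @param diurnal_range Daily max-min spread, °C.
#' @param rn_mean,rn_amplitude Mean and seasonal half-amplitude of net
#'   radiation, MJ/m^2/d.
#' @param rh_mean Mean relative humidity, %.
#' @param wind_mean Mean wind speed at 2 m, m/s.
#' @param t_noise_sd,rn_noise_sd,rh_noise_sd Day-to-day noise scales.
#' @param t_noise_ar1 Lag-1 autocorrelation of the temperature noise
#'   (synoptic persistence).
#' @param season_start,season_end Month-day strings bounding the season.
#' @return An object of class `climate_profile`.
#' @examples
#' climate_profile("arid-continental")
#' @export
climate_profile <- function(label = c("arid-continental", "warm-temperate-monsoon"),
                            t_mean_annual = NULL,
                            t_amplitude = NULL,
                            diurnal_range = NULL,
                            rn_mean = NULL,
                            rn_amplitude = NULL,
                            rh_mean = NULL,
                            wind_mean = NULL,
                            t_noise_sd = 1.5,
                            rn_noise_sd = 2,
                            rh_noise_sd = 8,
                            t_noise_ar1 = 0.6,
                            season_start = "04-15",
                            season_end = "10-15") {
  defaults <- list(
    "arid-continental" = list(t_mean_annual = 10, t_amplitude = 15,
                              diurnal_range = 14, rn_mean = 12,
                              rn_amplitude = 5, rh_mean = 45, wind_mean = 2.2),
    "warm-temperate-monsoon" = list(t_mean_annual = 13, t_amplitude = 14,
                                    diurnal_range = 10, rn_mean = 11,
                                    rn_amplitude = 5, rh_mean = 70,
                                    wind_mean = 1.8)
  )
  label <- label[1]
  base <- defaults[[label]] %||% list()
  prof <- list(
    label = label,
    t_mean_annual = t_mean_annual %||% base$t_mean_annual,
    t_amplitude = t_amplitude %||% base$t_amplitude,
    diurnal_range = diurnal_range %||% base$diurnal_range,
    rn_mean = rn_mean %||% base$rn_mean,
    rn_amplitude = rn_amplitude %||% base$rn_amplitude,
    rh_mean = rh_mean %||% base$rh_mean,
    wind_mean = wind_mean %||% base$wind_mean,
    t_noise_sd = t_noise_sd,
    rn_noise_sd = rn_noise_sd,
    rh_noise_sd = rh_noise_sd,
    t_noise_ar1 = t_noise_ar1,
    season_start = season_start,
    season_end = season_end
  )
  if (any(vapply(prof, is.null, logical(1)))) {
    abort("Unknown profile label: supply all climate parameters explicitly.")
  }
  if (prof$t_amplitude < 0 || prof$rn_amplitude < 0) abort("Amplitudes must be >= 0.")
  if (prof$rh_mean <= 0 || prof$rh_mean >= 100) abort("`rh_mean` must be in (0, 100).")
  structure(prof, class = "climate_profile")
}

#' @export
print.climate_profile <- function(x, ...) {
  cat(sprintf(
    "<climate_profile> %s: T %g±%g °C (diurnal %g), Rn %g±%g MJ/m²/d, RH %g%%, u2 %g m/s\n",
    x$label, x$t_mean_annual, x$t_amplitude, x$diurnal_range,
    x$rn_mean, x$rn_amplitude, x$rh_mean, x$wind_mean
  ))
  invisible(x)
}

ar1_noise <- function(n, sd, phi) {
  innov_sd <- sd * sqrt(1 - phi^2)
  e <- rnorm(n, sd = innov_sd)
  as.numeric(stats::filter(e, phi, method = "recursive"))
}

#' Simulate a season of daily weather
#'
#' Generates one cotton season (profile's window within `year`) of daily
#' weather in the column layout [accumulate_drivers()] expects. Daily mean
#' temperature follows the annual sinusoid plus AR(1) noise and is split
#' into max/min by the diurnal range; net radiation follows its own
#' seasonal sinusoid with white noise, floored at 0; relative humidity is
#' the profile mean plus noise, clamped into (2, 100); wind is log-normal
#' around the profile mean. Bitwise reproducible for a fixed seed.
#'
#' @param profile A [climate_profile()].
#' @param year Calendar year of the season.
#' @param seed Integer seed; the function sets and restores RNG state
#'   locally.
#' @return A tibble with columns `date`, `tmax_c`, `tmin_c`, `rh_pct`,
#'   `u2_ms`, `rn_mj_m2_d`.
#' @examples
#' w <- simulate_weather(climate_profile("arid-continental"), seed = 42)
#' head(w)
#' @export
simulate_weather <- function(profile, year = 2020, seed = 1) {
  stopifnot(inherits(profile, "climate_profile"))
  dates <- seq(
    as.Date(paste0(year, "-", profile$season_start)),
    as.Date(paste0(year, "-", profile$season_end)),
    by = "day"
  )
  if (length(dates) < 2) abort("Season window must span at least 2 days.")
  doy <- as.integer(format(dates, "%j"))
  n <- length(dates)

  withr_seed(seed, {
    # annual cycle peaks around day 197 (mid-July)
    cycle <- cos(2 * pi * (doy - 197) / 365)
    t_mean <- profile$t_mean_annual + profile$t_amplitude * cycle +
      ar1_noise(n, profile$t_noise_sd, profile$t_noise_ar1)
    half_range <- profile$diurnal_range / 2
    rn <- pmax(
      profile$rn_mean + profile$rn_amplitude * cycle +
        rnorm(n, sd = profile$rn_noise_sd),
      0
    )
    rh <- pmin(pmax(profile$rh_mean + rnorm(n, sd = profile$rh_noise_sd), 2), 99.5)
    u2 <- profile$wind_mean * exp(rnorm(n, sd = 0.3) - 0.3^2 / 2)

    tibble::tibble(
      date = dates,
      tmax_c = t_mean + half_range,
      tmin_c = t_mean - half_range,
      rh_pct = rh,
      u2_ms = u2,
      rn_mj_m2_d = rn
    )
  })
}

# evaluate `expr` under a local, restored RNG state
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Simulate noisy relative growth observations
#'
#' Draws observations `y = model(x) + noise` at the supplied relative driver
#' values, with additive Gaussian noise truncated into the open unit
#' interval — the structure the growth-curve fitting assumes.
#'
#' @param model A [logistic_growth()] model (the generating truth).
#' @param x Relative driver values; must span at least 0.8 of \[0, 1\] so a
#'   fit is identified.
#' @param noise_sd Observation noise standard deviation (>= 0) on the
#'   relative index.
#' @param seed Integer seed.
#' @return A tibble with columns `x` and `y` suitable for [fit_growth()].
#' @examples
#' obs <- simulate_growth(cotton_model("H", "cgdd"), seq(0.02, 1, 0.02),
#'                        noise_sd = 0.02, seed = 7)
#' fit_growth(obs, "linear")
#' @export
simulate_growth <- function(model, x, noise_sd = 0.02, seed = 1) {
  stopifnot(inherits(model, "logistic_growth"))
  if (noise_sd < 0) abort("`noise_sd` must be >= 0.")
  if (diff(range(x)) < 0.8) {
    abort("Driver values must span at least 0.8 of [0, 1] to identify a fit.")
  }
  y_true <- predict(model, x)
  y <- withr_seed(seed, y_true + rnorm(length(x), sd = noise_sd))
  eps <- 1e-6
  tibble::tibble(x = x, y = pmin(pmax(y, eps), 1 - eps))
}

#' Simulate paired season drivers for several regions
#'
#' For each climate profile, simulates one season of weather and computes
#' its cumulative drivers, returning a table ready for per-region driver
#' link fitting. Each region gets a seed derived deterministically from
#' `seed`.
#'
#' @param profiles A list of [climate_profile()] objects (at least 2); names
#'   default to the profile labels.
#' @param year Season year.
#' @param seed Integer base seed.
#' @return A tibble of daily driver rows with a leading `region` column
#'   (columns as from [accumulate_drivers()]).
#' @examples
#' regs <- simulate_region_set(list(climate_profile("arid-continental"),
#'                                  climate_profile("warm-temperate-monsoon")),
#'                             seed = 3)
#' dplyr::count(regs, region)
#' @export
simulate_region_set <- function(profiles, year = 2020, seed = 1) {
  if (length(profiles) < 2) abort("Need at least 2 profiles.")
  nm <- names(profiles) %||% vapply(profiles, function(p) p$label, character(1))
  purrr::map2_dfr(profiles, seq_along(profiles), function(p, i) {
    w <- simulate_weather(p, year = year, seed = seed + 1000L * i)
    accumulate_drivers(w) |>
      dplyr::mutate(region = nm[i], .before = 1)
  })
}
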