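# Delimited-text IO for weather tables, driver tables and growth
# observations, plus the thin file-to-file runs behind the command-line
# wrapper.

#' Read and write daily weather tables
#'
#' Comma-separated, one row per day, header row. Mandatory columns: `date`
#' (ISO-8601), `tmax_c`, `tmin_c`, `u2_ms`, `rn_mj_m2_d`, and either both
#' `es_kpa`/`ea_kpa` or `rh_pct`. Optional: `g_mj_m2_d`, `elevation_m`.
#' Validation errors name the offending rows.
#'
#' @param path File path.
#' @param weather Data frame of daily weather.
#' @return `read_weather_csv()` returns a validated tibble;
#'   `write_weather_csv()` returns `weather` invisibly.
#' @examples
#' w <- simulate_weather(climate_profile("arid-continental"), seed = 1)
#' f <- tempfile(fileext = ".csv")
#' write_weather_csv(w, f)
#' all.equal(as.data.frame(read_weather_csv(f)), as.data.frame(w))
#' @export
read_weather_csv <- function(path) {
  if (!file.exists(path)) abort(paste0("No such file: ", path))
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  validate_weather(raw)
}

#' @rdname read_weather_csv
#' @export
write_weather_csv <- function(weather, path) {
  readr::write_csv(tibble::as_tibble(weather), path)
  invisible(weather)
}

#' Read relative growth observations
#'
#' Comma-separated with mandatory numeric columns `x` (relative driver) and
#' `y` (relative index); optional annotation columns (`region`,
#' `index_kind`, `driver_kind`) are passed through. Alternatively, raw
#' observations can be supplied as `value` plus `observed_max` (and an
#' optional `factor` column, default 1.03): `y` is then
#' `value / theoretical_max(observed_max, factor)`.
#'
#' @param path File path.
#' @return A tibble with at least `x` and `y`.
#' @export
read_growth_csv <- function(path) {
  if (!file.exists(path)) abort(paste0("No such file: ", path))
  d <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!("y" %in% names(d)) && all(c("value", "observed_max") %in% names(d))) {
    fac <- if ("factor" %in% names(d)) d$factor else 1.03
    d$y <- d$value / theoretical_max(d$observed_max, fac)
  }
  if (!all(c("x", "y") %in% names(d))) {
    abort("Growth table needs columns `x` and `y` (or `value` + `observed_max`).")
  }
  bad <- which(d$x < 0 | d$x > 1)
  if (length(bad) > 0) {
    abort(paste0("`x` outside [0, 1] on row(s): ", paste(bad, collapse = ", ")))
  }
  tibble::as_tibble(d)
}

#' File-to-file pipeline runs
#'
#' Thin wrappers composing the package's operations for scripted use: each
#' reads delimited text, runs the corresponding module functions, and writes
#' delimited text. No computation lives here that is not available through
#' the underlying functions.
#'
#' * `run_drivers()`: weather table in, driver table (date, daily and
#'   cumulative GDD and reference evapotranspiration, relative drivers) out.
#' * `run_yield_report()`: writes the one-row [yield_summary()] table.
#' * `run_simulation()`: simulates a season of weather ([simulate_weather()])
#'   and writes it as a weather table.
#'
#' @param input,output File paths.
#' @param t_base,t_upper Thermal limits, °C.
#' @param profile,year,seed Passed to [simulate_weather()].
#' @return The written tibble, invisibly.
#' @name pipeline-runs
NULL

#' @rdname pipeline-runs
#' @export
run_drivers <- function(input, output, t_base = 10, t_upper = 40) {
  drv <- accumulate_drivers(read_weather_csv(input), t_base, t_upper)
  out <- dplyr::select(
    drv, "date", "daily_gdd", "cgdd", "daily_eto", "ceto", "r_cgdd", "r_ceto"
  )
  readr::write_csv(out, output)
  invisible(out)
}

#' @rdname pipeline-runs
#' @export
run_yield_report <- function(output) {
  out <- yield_summary()
  readr::write_csv(out, output)
  invisible(out)
}

#' @rdname pipeline-runs
#' @export
run_simulation <- function(output, profile = climate_profile("arid-continental"),
                           year = 2020, seed = 1) {
  w <- simulate_weather(profile, year = year, seed = seed)
  write_weather_csv(w, output)
  invisible(w)
}
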