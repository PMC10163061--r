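# Shared fixtures: tiny weather tables built in code and an independent
# FAO-56 evaluation used as oracle for the packaged one.

# n-day toy weather with explicit vapor pressures
toy_weather <- function(tmax, tmin, es = 2.0, ea = 1.0, u2 = 2, rn = 13,
                        start = as.Date("2020-05-01")) {
  n <- max(length(tmax), length(tmin))
  tibble::tibble(
    date = start + seq_len(n) - 1,
    tmax_c = rep_len(tmax, n),
    tmin_c = rep_len(tmin, n),
    es_kpa = rep_len(es, n),
    ea_kpa = rep_len(ea, n),
    u2_ms = rep_len(u2, n),
    rn_mj_m2_d = rep_len(rn, n)
  )
}

# Second, independently coded Penman-Monteith evaluation: radiation and
# aerodynamic terms computed separately, Tetens terms written out in full.
reference_eto <- function(t, u2, es, ea, rn, g = 0, pressure = 101.3) {
  e0 <- 0.6108 * exp((17.27 * t) / (t + 237.3))
  delta <- (4098 * e0) / ((t + 237.3) * (t + 237.3))
  gamma <- 0.000665 * pressure
  rad_term <- 0.408 * delta * (rn - g)
  aero_term <- gamma * 900 / (t + 273) * u2 * (es - ea)
  (rad_term + aero_term) / (delta + gamma + gamma * 0.34 * u2)
}

two_profiles <- function() {
  list(
    climate_profile("arid-continental"),
    climate_profile("warm-temperate-monsoon")
  )
}
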