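test_that("effective mean temperature clamps the daily mean into the active window", {
  expect_equal(gdd_mean_temp(30, 20), 25)
  expect_equal(gdd_mean_temp(8, 4), 10)    # floor at base
  expect_equal(gdd_mean_temp(48, 40), 40)  # ceiling at upper limit
  # idempotent under re-clamping
  tm <- gdd_mean_temp(c(5, 20, 50), c(0, 10, 45))
  expect_equal(gdd_mean_temp(tm, tm), tm)
  expect_error(gdd_mean_temp(10, 20), "t_max")
  expect_error(gdd_mean_temp(20, 10, t_base = 40, t_upper = 10), "t_base")
})

test_that("daily GDD is the clamped mean minus the base, bounded by the window", {
  expect_equal(gdd_daily(30, 20), 15)
  expect_equal(gdd_daily(8, 4), 0)
  expect_equal(gdd_daily(48, 40), 30)
  tmax <- runif(50, -5, 50)
  tmin <- tmax - runif(50, 0, 15)
  g <- gdd_daily(tmax, tmin)
  expect_true(all(g >= 0 & g <= 30))
})

test_that("cumulative GDD is a running sum of daily increments", {
  w <- toy_weather(rep(30, 3), rep(20, 3))
  drv <- accumulate_drivers(w)
  expect_equal(drv$cgdd, c(15, 30, 45))
  expect_equal(drv$r_cgdd, c(1, 2, 3) / 3)

  # mixed 5-day series against a brute-force running sum
  w5 <- toy_weather(c(30, 8, 48, 22, 15), c(20, 4, 40, 12, 9))
  drv5 <- accumulate_drivers(w5)
  by_hand <- cumsum(mapply(function(a, b) gdd_daily(a, b), w5$tmax_c, w5$tmin_c))
  expect_equal(drv5$cgdd, by_hand)
  expect_true(all(diff(drv5$cgdd) >= 0))
})

test_that("FAO-56 atmospheric helpers match their closed forms", {
  expect_equal(svp_slope(0), 4098 * 0.6108 / 237.3^2, tolerance = 1e-12)
  expect_equal(psychrometric_gamma(101.3), 0.000665 * 101.3)
  # slope strictly increases with temperature over 0..40
  t <- seq(0, 40, by = 0.5)
  expect_true(all(diff(svp_slope(t)) > 0))
  expect_equal(pressure_at_elevation(0), 101.3, tolerance = 1e-9)
  expect_lt(pressure_at_elevation(1000), 101.3)
})

test_that("daily reference evapotranspiration matches an independent evaluation", {
  got <- eto_daily(t_mean = 20, u2 = 2, es = 2.34, ea = 1.34, rn = 13.28)
  want <- reference_eto(t = 20, u2 = 2, es = 2.34, ea = 1.34, rn = 13.28)
  expect_equal(got, want, tolerance = 1e-6)

  # zero numerator: no radiation surplus and no vapor deficit
  expect_equal(eto_daily(25, u2 = 3, es = 1.5, ea = 1.5, rn = 5, g = 5), 0)
  # calm air: aerodynamic term vanishes
  delta <- svp_slope(18)
  gamma <- psychrometric_gamma()
  expect_equal(
    eto_daily(18, u2 = 0, es = 2, ea = 1, rn = 10),
    0.408 * delta * 10 / (delta + gamma)
  )
})

test_that("reference evapotranspiration increases with vapor deficit and radiation", {
  vpd <- seq(0, 2, by = 0.1)
  e1 <- eto_daily(22, u2 = 2, es = 2.5, ea = 2.5 - vpd, rn = 12)
  expect_true(all(diff(e1) > 0))
  rn <- seq(2, 18, by = 1)
  e2 <- eto_daily(22, u2 = 2, es = 2.5, ea = 1.5, rn = rn)
  expect_true(all(diff(e2) > 0))
})

test_that("cumulative evapotranspiration clamps negative days and stays monotone", {
  w <- toy_weather(rep(25, 3), rep(15, 3), es = 1.2, ea = 1.2)
  w$rn_mj_m2_d <- c(10, 0, 10)
  w$g_mj_m2_d <- c(0, 5, 0)  # day 2 has Rn < G and no vapor deficit
  drv <- accumulate_drivers(w)
  expect_lt(drv$daily_eto[2], 0)             # raw value stays visible
  expect_equal(drv$ceto[2], drv$ceto[1])     # but contributes nothing
  expect_true(all(diff(drv$ceto) >= 0))

  w3 <- toy_weather(rep(25, 3), rep(15, 3))
  drv3 <- accumulate_drivers(w3)
  expect_equal(drv3$ceto, drv3$daily_eto[1] * (1:3))
})

test_that("relative accumulation normalises to [0, 1] and ignores uniform scaling", {
  expect_equal(relative_series(c(15, 30, 45)), c(1, 2, 3) / 3)
  expect_equal(relative_series(42), 1)
  cum <- cumsum(runif(20))
  expect_equal(relative_series(cum * 7.3), relative_series(cum))
  r <- relative_series(cum)
  expect_equal(max(r), 1)
  expect_gte(min(r), 0)
  expect_error(relative_series(c(0, 0)), "positive")
})

test_that("weather validation reports missing columns and bad rows", {
  w <- toy_weather(rep(30, 8), rep(20, 8))
  w$tmin_c[7] <- 35
  expect_error(accumulate_drivers(w), "row\\(s\\): 7")
  expect_error(accumulate_drivers(w[0, ]), "empty")
  expect_error(accumulate_drivers(dplyr::select(w, -"u2_ms")), "u2_ms")
  w2 <- toy_weather(rep(30, 3), rep(20, 3))
  w2$date <- rep(w2$date[1], 3)
  expect_error(accumulate_drivers(w2), "strictly increasing")
})
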