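test_that("daily statistics reduce each complete day exactly", {
  s <- test_surface(4, 4)
  # constant day
  ts <- as.POSIXct("2012-07-01 00:00:00", tz = "UTC") + 3600 * (0:23)
  cube <- temp_cube(array(30, dim = c(24, 4, 4)), ts, s)
  ds <- daily_statistics(cube)
  expect_equal(ds$tmax[1, 1, 1], 30)
  expect_equal(ds$tmin[1, 1, 1], 30)
  expect_equal(ds$tmean[1, 1, 1], 30)
  # hourly sinusoid against an exhaustive 24-value scan
  v <- 30 + 5 * sin(2 * pi * (0:23 - 9) / 24)
  cube2 <- temp_cube(array(rep(v, 16), dim = c(24, 4, 4)), ts, s)
  ds2 <- daily_statistics(cube2)
  expect_equal(ds2$tmax[1, 2, 3], max(v), tolerance = 1e-12)
  expect_equal(ds2$tmin[1, 2, 3], min(v), tolerance = 1e-12)
  expect_equal(ds2$tmean[1, 2, 3], mean(v), tolerance = 1e-12)
  expect_true(all(ds2$tmin <= ds2$tmean & ds2$tmean <= ds2$tmax))
  # a 23-hour day is excluded and reported
  cube3 <- temp_cube(array(30, dim = c(47, 4, 4)),
                     ts[1] + 3600 * (0:46), s)
  expect_message(ds3 <- daily_statistics(cube3), "1 incomplete")
  expect_length(ds3$dates, 1)
})

test_that("T95 uses linear interpolation between order statistics", {
  clim <- list(variant = "Tmean",
               values = array(rep(1:100, 4), dim = c(100, 2, 2)),
               n_years = 1, days_per_year = 100)
  bl <- compute_t95(clim)
  expect_equal(bl$t95, matrix(95.05, 2, 2))
  expect_match(bl$percentile_method, "linear")
  # constant series
  climc <- list(variant = "Tmean", values = array(21.5, dim = c(30, 1, 1)))
  expect_equal(compute_t95(climc)$t95[1, 1], 21.5)
  # order invariance
  withr::with_seed(8, {
    x <- stats::rnorm(60, 25, 4)
    c1 <- list(variant = "Tmean", values = array(x, dim = c(60, 1, 1)))
    c2 <- list(variant = "Tmean", values = array(sample(x), dim = c(60, 1, 1)))
    expect_equal(compute_t95(c1)$t95, compute_t95(c2)$t95)
  })
  # too few values
  short <- list(variant = "Tmean", values = array(1:10, dim = c(10, 1, 1)))
  expect_error(compute_t95(short), "20")
})

test_that("T95 equals the sort-and-interpolate oracle on random series", {
  withr::with_seed(55, {
    for (rep in 1:25) {
      n <- sample(20:120, 1)
      x <- stats::rnorm(n, 27, 3)
      clim <- list(variant = "Tmean", values = array(x, dim = c(n, 1, 1)))
      expect_equal(compute_t95(clim)$t95[1, 1], percentile_oracle(x),
                   tolerance = 1e-12)
    }
  })
})

test_that("window means are exact and refuse incomplete windows", {
  s <- test_surface(4, 4)
  ts <- as.POSIXct("2012-07-01 00:00:00", tz = "UTC") + 3600 * (0:(5 * 24 - 1))
  daily_vals <- c(30, 32, 34, 31, 29)
  vals <- array(rep(rep(daily_vals, each = 24), 16), dim = c(120, 4, 4))
  cube <- temp_cube(vals, ts, s)
  ds <- daily_statistics(cube)
  t3 <- window_mean(ds, as.Date("2012-07-01") + 0:2)
  expect_equal(t3[1, 1], 32.0)
  # previous-consecutive-days form: mean of the 3 days before July 5
  t3b <- rolling_previous_mean(ds, 3, as.Date("2012-07-05"))
  expect_equal(t3b[2, 2], mean(c(32, 34, 31)))
  # constant series: T30-style mean is that constant
  expect_equal(rolling_previous_mean(ds, 5, as.Date("2012-07-06"))[1, 1],
               mean(daily_vals))
  # missing day named in the error
  expect_error(window_mean(ds, as.Date("2012-07-04") + 0:2), "2012-07-06")
  expect_error(rolling_previous_mean(ds, 30, as.Date("2012-07-05")),
               "2012-06-05")
})

test_that("EHF arithmetic follows the excess-heat equations exactly", {
  to_m <- function(x) matrix(x, 1, 1)
  f <- compute_ehf(to_m(35), to_m(28), to_m(30))
  expect_equal(f$ehi_sig[1, 1], 5)
  expect_equal(f$ehi_accl[1, 1], 7)
  expect_equal(f$ehf[1, 1], 35)
  expect_equal(f$severity[1, 1], "high")
  # clamp active: EHI_accl = 0.5 < 1
  f2 <- compute_ehf(to_m(30.5), to_m(30), to_m(28.5))
  expect_equal(f2$ehi_sig[1, 1], 2)
  expect_equal(f2$ehi_accl[1, 1], 0.5)
  expect_equal(f2$ehf[1, 1], 2)
  # negative significance passes through
  f3 <- compute_ehf(to_m(28), to_m(27), to_m(30))
  expect_equal(f3$ehf[1, 1], -2)
  expect_equal(f3$severity[1, 1], "none")
  expect_error(compute_ehf(to_m(1), matrix(1, 2, 2), to_m(1)), "congruent")
})

test_that("EHF equals EHI_sig when acclimatization is clamped, and is monotone in T3", {
  withr::with_seed(12, {
    t30 <- matrix(stats::rnorm(25, 28, 2), 5, 5)
    t95 <- matrix(stats::rnorm(25, 30, 1), 5, 5)
    t3a <- matrix(stats::rnorm(25, 29, 2), 5, 5)
    t3b <- t3a + matrix(stats::runif(25, 0, 3), 5, 5)  # pointwise larger
    fa <- compute_ehf(t3a, t30, t95)
    fb <- compute_ehf(t3b, t30, t95)
    # monotone: larger T3 never lowers EHF
    expect_true(all(fb$ehf >= fa$ehf))
    # clamp identity
    clamped <- fa$ehi_accl <= 1
    expect_equal(fa$ehf[clamped], fa$ehi_sig[clamped])
  })
})

test_that("severity classes split at zero and at the high threshold", {
  expect_equal(classify_severity(c(35, -2, 1, 0, 2, 2.0001)),
               c("high", "none", "positive", "none", "positive", "high"))
  expect_equal(classify_severity(5, high_threshold = 10), "positive")
  expect_error(classify_severity(1, high_threshold = -1), ">= 0")
  expect_true(is.na(classify_severity(NA_real_)))
})

test_that("episode map equals the manual composition of its stages", {
  s <- test_surface()
  # event scenario: urban-dominant pulse on days 32-34 of a 35-day run
  sc <- heat_scenario(n_days = 35, hw_start_day = 32, hw_end_day = 35,
                      hw_amplitude_rural = 2, hw_amplitude_urban = 4,
                      noise_sd = 0.2, synoptic_sd = 1, seed = 77,
                      climatology_years = 3, climatology_days = 40)
  cube <- generate_temperature_cube(s, sc)
  clim <- generate_climatology(s, sc, "Tmean")
  t3d <- sc$start_date + 31 + 0:2
  field <- ehf_episode_map(cube, clim, t3d, "Tmean")

  ds <- daily_statistics(cube)
  t3 <- window_mean(ds, t3d, "Tmean")
  t30 <- rolling_previous_mean(ds, 30, min(t3d), "Tmean")
  t95 <- compute_t95(clim)
  manual <- compute_ehf(t3, t30, t95, surface = s, variant = "Tmean")
  expect_identical(field$ehf, manual$ehf)
  expect_identical(field$severity, manual$severity)

  # an urban-dominant event yields higher EHF in the urban core than in
  # vegetated surroundings
  urb <- s$urban_fraction >= 0.9
  veg <- s$land_class == "vegetation"
  expect_gt(mean(field$ehf[urb]), mean(field$ehf[veg]))
  # water is masked through
  expect_true(all(is.na(field$ehf[s$land_class == "open_water"])))
  expect_true(all(!is.na(field$ehf[!(s$land_class == "open_water")])))
})

test_that("episode map validates variant pairing and date coverage", {
  s <- test_surface(6, 5)
  sc <- quiet_scenario(n_days = 35, climatology_years = 1,
                       climatology_days = 30)
  cube <- generate_temperature_cube(s, sc)
  clim <- generate_climatology(s, sc, "Tmin")
  t3d <- sc$start_date + 31 + 0:2
  expect_error(ehf_episode_map(cube, clim, t3d, "Tmean"), "variant")
  # T30 window not covered when the event starts too early
  clim2 <- generate_climatology(s, sc, "Tmean")
  expect_error(ehf_episode_map(cube, clim2, sc$start_date + 5 + 0:2, "Tmean"),
               "T30 stage")
})
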