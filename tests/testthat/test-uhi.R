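make_grid_surface <- function(frac, cls) {
  urban_surface(matrix(frac, 1), matrix(cls, 1))
}

test_that("period means split the day at the configured hours", {
  s <- test_surface(6, 5)
  # constant cube
  ts <- as.POSIXct("2012-07-01 00:00:00", tz = "UTC") + 3600 * (0:47)
  cube <- temp_cube(array(30, dim = c(48, 6, 5)), ts, s)
  pm <- suppressMessages(period_means(cube))
  expect_equal(pm$day$values[1, , ], matrix(30, 6, 5))
  expect_equal(pm$night$values[1, , ], matrix(30, 6, 5))
  # 36-hour cube: exactly one complete day and one complete night window
  cube36 <- temp_cube(array(25, dim = c(36, 6, 5)), ts[1:36], s)
  pm36 <- suppressMessages(period_means(cube36))
  expect_length(pm36$day$dates, 1)
  expect_length(pm36$night$dates, 1)
  expect_equal(pm36$day$dates, as.Date("2012-07-01"))
})

test_that("sinusoidal day-night contrast matches a 24-term summation oracle", {
  s <- test_surface(4, 4)
  A <- 5.5
  hod <- rep(0:23, 2)
  vals <- 30 + A * sin(2 * pi * (hod - 9) / 24)
  ts <- as.POSIXct("2012-07-01 00:00:00", tz = "UTC") + 3600 * (0:47)
  cube <- temp_cube(array(rep(vals, 16), dim = c(48, 4, 4)), ts, s)
  pm <- suppressMessages(period_means(cube))
  # direct hour-by-hour oracle
  day_o <- mean(30 + A * sin(2 * pi * (6:17 - 9) / 24))
  night_o <- mean(30 + A * sin(2 * pi * (18:29 - 9) / 24))
  expect_equal(pm$day$values[1, 1, 1] - pm$night$values[1, 1, 1],
               day_o - night_o, tolerance = 1e-12)
})

test_that("UHII fit reproduces an exact line and excludes open water", {
  s <- make_grid_surface(c(0, 0.5, 0.95, 0),
                         c("vegetation", "low_intensity_residential",
                           "industrial_commercial", "open_water"))
  # exact line T = 2*frac + 24 with an extreme water value
  g <- matrix(c(24, 25, 25.9, -50), 1)
  fit <- suppressWarnings(fit_uhii(g, s))
  expect_equal(fit$slope, 2.0, tolerance = 1e-12)
  expect_equal(fit$intercept, 24.0, tolerance = 1e-12)
  expect_equal(fit$r_value, 1.0, tolerance = 1e-12)
  expect_equal(fit$n_cells, 3L)
  # water temperature cannot influence the estimate
  g2 <- g; g2[4] <- 1e6
  fit2 <- suppressWarnings(fit_uhii(g2, s))
  expect_identical(fit[c("slope", "intercept", "r_value", "p_value")],
                   fit2[c("slope", "intercept", "r_value", "p_value")])
})

test_that("UHII fit agrees with the closed-form normal-equations oracle", {
  withr::with_seed(15, {
    for (rep in 1:10) {
      n <- 40
      frac <- sample(c(0, 0, 0.5, 0.9, 0.95), n, replace = TRUE)
      cls <- ifelse(frac == 0, "vegetation", "industrial_commercial")
      s <- make_grid_surface(frac, cls)
      g <- matrix(24 + 2 * frac + stats::rnorm(n, 0, 0.4), 1)
      fit <- fit_uhii(g, s)
      o <- ols_oracle(frac, as.vector(g))
      expect_equal(fit$slope, o$slope, tolerance = 1e-10)
      expect_equal(fit$intercept, o$intercept, tolerance = 1e-10)
    }
  })
})

test_that("degenerate designs are refused", {
  s <- make_grid_surface(c(0, 0, 0), rep("vegetation", 3))
  expect_error(fit_uhii(matrix(c(24, 25, 26), 1), s), "degenerate")
  s2 <- make_grid_surface(c(0, 0.5), c("vegetation", "low_intensity_residential"))
  expect_error(fit_uhii(matrix(c(24, 25), 1), s2), "fewer than 3")
})

test_that("shifting all temperatures moves intercepts only", {
  s <- test_surface()
  cube <- generate_temperature_cube(s, heat_scenario(
    n_days = 2, hw_start_day = 1, hw_end_day = 1, seed = 21))
  pm <- suppressMessages(period_means(cube))
  f1 <- fit_uhii(pm$night$values[1, , ], s)
  f2 <- fit_uhii(pm$night$values[1, , ] + 3.25, s)
  expect_equal(f2$slope, f1$slope, tolerance = 1e-10)
  expect_equal(f2$intercept, f1$intercept + 3.25, tolerance = 1e-10)
  expect_equal(f2$r_value, f1$r_value, tolerance = 1e-10)
  expect_equal(f2$p_value, f1$p_value, tolerance = 1e-10)
})

test_that("noise-free daily series recovers the injected slope every night", {
  s <- test_surface()
  sc <- quiet_scenario(n_days = 8, true_uhii_night = 2)
  cube <- generate_temperature_cube(s, sc)
  ser <- suppressWarnings(suppressMessages(
    daily_uhii_series(cube, period = "night")))
  expect_equal(nrow(ser), 7)  # last night incomplete
  expect_equal(ser$slope, rep(2, 7), tolerance = 1e-9)
  expect_equal(ser$r_value, rep(1, 7), tolerance = 1e-9)
  # the day-period series sees no UHI signal at all
  day <- suppressWarnings(suppressMessages(
    daily_uhii_series(cube, period = "day")))
  expect_equal(day$slope, rep(0, 8), tolerance = 1e-9)
})

test_that("cross-sections report profiles, Tu/Tr and an exactly consistent delta", {
  s <- test_surface()
  sc <- quiet_scenario(n_days = 3, true_uhii_night = 2)
  cube <- generate_temperature_cube(s, sc)
  dates <- list(all = as.Date("2012-05-28") + 0:1)
  xs <- suppressMessages(extract_cross_section(
    cube, start = c(9, 12), end = c(9, 0), date_sets = dates))
  expect_equal(nrow(xs$path), 13)
  expect_true(all(xs$path$land_class != "open_water"))
  # noise-free: night profile at fraction 0.95 minus vegetation = 1.9
  night <- xs$temps[xs$temps$period == "night", ]
  p95 <- night$temp[xs$path$urban_fraction == 0.95][1]
  pveg <- night$temp[xs$path$urban_fraction == 0][1]
  expect_equal(p95 - pveg, 1.9, tolerance = 1e-10)
  # stored delta equals Tu - Tr recomputed from the profile
  for (i in seq_len(nrow(xs$summary))) {
    row <- xs$summary[i, ]
    prof <- xs$temps[xs$temps$set == row$set & xs$temps$period == row$period, ]
    tu <- mean(prof$temp[xs$path$urban_fraction >= 0.5])
    tr <- mean(prof$temp[xs$path$urban_fraction == 0 &
                           xs$path$land_class == "vegetation"])
    expect_equal(row$delta_T, row$Tu - row$Tr)
    expect_equal(row$Tu, tu); expect_equal(row$Tr, tr)
  }
  # reversing the endpoints flips the order but not the summary
  xr <- suppressMessages(extract_cross_section(
    cube, start = c(9, 0), end = c(9, 12), date_sets = dates))
  expect_equal(xr$path$col, rev(xs$path$col))
  expect_equal(xr$summary$Tu, xs$summary$Tu)
  expect_equal(xr$summary$delta_T, xs$summary$delta_T)
})
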