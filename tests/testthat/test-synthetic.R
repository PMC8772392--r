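test_that("categorical surface follows the land-class to urban-fraction mapping", {
  s <- test_surface()
  expect_equal(s$urban_fraction[10, 13], 0.95)  # urban center cell
  expect_equal(s$land_class[10, 13], "industrial_commercial")
  # full scan: fractions are exactly the categorical set
  expect_true(all(s$urban_fraction %in% c(0, 0.50, 0.90, 0.95)))
  # per-class mapping holds everywhere
  expect_true(all(s$urban_fraction == class_urban_fraction[s$land_class]))
  # water band and vegetation carry zero fraction
  expect_true(all(s$urban_fraction[s$land_class == "open_water"] == 0))
  expect_true(all(s$urban_fraction[s$land_class == "vegetation"] == 0))
  expect_true(all(s$land_class[, 15:16] == "open_water"))
  expect_true(all(s$urban_fraction >= 0 & s$urban_fraction <= 1))
})

test_that("surface generation validates its parameters", {
  expect_error(generate_surface(10, 10, class_radii = c(3, 2, 4, 5)),
               "strictly increasing")
  expect_error(generate_surface(10, 10, class_radii = c(2, 4, 6, 30)),
               "exceed")
  expect_error(generate_surface(10, 10, class_radii = c(2, 4, 6, 8),
                                lake_cols = 10), "lake_cols")
  expect_error(urban_surface(matrix(0.5, 2, 2),
                             matrix("vegetation", 2, 2)),
               "must be 0 on open_water and vegetation")
})

test_that("cube has the injected nighttime urban-fraction signal", {
  s <- test_surface()
  sc <- quiet_scenario(n_days = 2, true_uhii_night = 2)
  cube <- generate_temperature_cube(s, sc)
  # 03:00 on day 1 is a night hour outside the heatwave
  h <- 4
  iu <- which(s$urban_fraction == 0.95, arr.ind = TRUE)[1, ]
  iv <- which(s$land_class == "vegetation", arr.ind = TRUE)[1, ]
  expect_equal(cube$values[h, iu[1], iu[2]] - cube$values[h, iv[1], iv[2]],
               2 * 0.95)
  # noon: UHI term off, urban equals vegetation
  expect_equal(cube$values[13, iu[1], iu[2]], cube$values[13, iv[1], iv[2]])
})

test_that("heatwave pulse shifts vegetation daily means by exactly its amplitude", {
  s <- test_surface()
  sc <- quiet_scenario(n_days = 5, hw_start_day = 3, hw_end_day = 4,
                       hw_amplitude_rural = 4, hw_amplitude_urban = 2.5)
  cube <- generate_temperature_cube(s, sc)
  ds <- daily_statistics(cube)
  iv <- which(s$land_class == "vegetation", arr.ind = TRUE)[1, ]
  iu <- which(s$urban_fraction == 0.95, arr.ind = TRUE)[1, ]
  expect_equal(ds$tmean[3, iv[1], iv[2]] - ds$tmean[1, iv[1], iv[2]], 4.0)
  expect_equal(ds$tmean[3, iu[1], iu[2]] - ds$tmean[1, iu[1], iu[2]], 2.5)
})

test_that("same scenario and seed regenerate bit-identical cubes; seed only moves the noise", {
  s <- test_surface()
  sc <- heat_scenario(n_days = 2, hw_start_day = 1, hw_end_day = 1, seed = 11)
  c1 <- generate_temperature_cube(s, sc)
  c2 <- generate_temperature_cube(s, sc)
  expect_identical(c1$values, c2$values)
  # different seed: stochastic realization changes ...
  sc3 <- heat_scenario(n_days = 2, hw_start_day = 1, hw_end_day = 1, seed = 12)
  c3 <- generate_temperature_cube(s, sc3)
  expect_false(identical(c1$values, c3$values))
  # ... but the deterministic component does not
  det <- function(seed) {
    scq <- quiet_scenario(n_days = 2, seed = seed)
    generate_temperature_cube(s, scq)$values
  }
  expect_identical(det(11), det(12))
})

test_that("climatology has years x days values per cell from the non-heatwave process", {
  s <- test_surface(10, 8)
  sc <- quiet_scenario(climatology_years = 10, climatology_days = 92,
                       lake_cooling_amplitude = 5)
  clim <- generate_climatology(s, sc, "Tmean")
  expect_equal(dim(clim$values), c(920, 10, 8))
  # daytime-free UHI + no noise: Tmean identical across vegetation cells
  # equidistant from the lake
  scq <- quiet_scenario(climatology_years = 1, climatology_days = 5,
                        lake_cooling_amplitude = 5)
  cl2 <- generate_climatology(s, scq, "Tmean")
  d <- urbanheat:::lake_distance(s)
  veg <- which(s$land_class == "vegetation" & abs(d - 4) < 1e-12)
  vals <- matrix(cl2$values[1, , ][veg], nrow = 1)
  expect_true(length(veg) >= 2)
  expect_equal(max(vals) - min(vals), 0)
  # reproducible under a fixed seed
  cl3 <- generate_climatology(s, scq, "Tmean")
  expect_identical(cl2$values, cl3$values)
  expect_error(generate_climatology(s, scq, "Tavg"), "variant")
})

test_that("stations sample land cells and are exact at zero observation noise", {
  s <- test_surface()
  cube <- generate_temperature_cube(s, quiet_scenario(n_days = 2))
  st <- sample_stations(cube, 8, obs_noise_sd = 0, seed = 5)
  expect_length(st, 8)
  for (x in st) {
    cls <- s$land_class[x$cell[1] + 1, x$cell[2] + 1]
    expect_true(cls != "open_water")
    expect_identical(x$obs, cube$values[, x$cell[1] + 1, x$cell[2] + 1])
  }
  # seeded determinism
  st2 <- sample_stations(cube, 8, obs_noise_sd = 0, seed = 5)
  expect_identical(lapply(st, `[[`, "cell"), lapply(st2, `[[`, "cell"))
  # more stations than land cells is refused
  expect_error(sample_stations(cube, 10000, seed = 1), "land cells")
})
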