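#' Construct a temperature cube
#'
#' @param values numeric array `(time, y, x)` of 2-m temperature (degC).
#' @param timestamps POSIXct vector of hourly local-time instants, strictly
#'   increasing with a constant 1-hour step. Local clock time is represented
#'   in UTC; no time-zone arithmetic is performed.
#' @param surface the `urban_surface` the cube lies on.
#' @return Object of class `temp_cube`.
#' @export
temp_cube <- function(values, timestamps, surface) {
  stopifnot(inherits(surface, "urban_surface"))
  if (length(dim(values)) != 3)
    stop("values must be a (time, y, x) array", call. = FALSE)
  if (dim(values)[2] != surface$n_y || dim(values)[3] != surface$n_x)
    stop("cube and surface grid dimensions differ", call. = FALSE)
  if (dim(values)[1] != length(timestamps))
    stop("time dimension does not match timestamps", call. = FALSE)
  if (length(timestamps) > 1) {
    dt <- diff(as.numeric(timestamps))
    if (any(dt != 3600))
      stop("time axis must be strictly increasing with a 1-hour step",
           call. = FALSE)
  }
  structure(list(values = values, timestamps = timestamps, surface = surface),
            class = "temp_cube")
}

#' @export
print.temp_cube <- function(x, ...) {
  cat(sprintf("temp_cube: %d hours x %d x %d cells, %s .. %s\n",
              dim(x$values)[1], dim(x$values)[2], dim(x$values)[3],
              format(min(x$timestamps)), format(max(x$timestamps))))
  invisible(x)
}

cube_hours <- function(cube) as.integer(format(cube$timestamps, "%H", tz = "UTC"))
cube_dates <- function(cube) as.Date(cube$timestamps, tz = "UTC")

# distance (in cells) from each cell to the nearest open-water cell; Inf when
# the surface has no water.
lake_distance <- function(surface) {
  water <- which(surface$land_class == "open_water", arr.ind = TRUE)
  d <- matrix(Inf, surface$n_y, surface$n_x)
  if (nrow(water) == 0) return(d)
  rows <- seq_len(surface$n_y); cols <- seq_len(surface$n_x)
  for (k in seq_len(nrow(water))) {
    dk <- sqrt(outer((rows - water[k, 1])^2, (cols - water[k, 2])^2, "+"))
    d <- pmin(d, dk)
  }
  d
}

#' Generate an hourly synthetic temperature cube
#'
#' Deterministic structure plus seeded noise:
#' `T(t, cell) = baseline + A * sin(2*pi*(hour - 9)/24) + HW(t, cell)
#'  + night(t) * true_uhii_night * urban_fraction(cell) - lake(cell)
#'  + synoptic(day(t), cell) + eps(t, cell)`.
#' The diurnal cycle peaks at 15:00 local. The heatwave pulse adds
#' `hw_amplitude_urban` on cells with urban fraction > 0 and
#' `hw_amplitude_rural` on vegetation cells during the heatwave window
#' (calendar days). The urban-heat-island term is active during the night
#' window (before 06:00 or from 18:00 local), so the nighttime cross-grid
#' expectation is linear in urban fraction with slope `true_uhii_night`.
#' Lake cooling is `lake_cooling_amplitude * exp(-d / lake_decay_length)`
#' with `d` the distance to the nearest open-water cell. The synoptic
#' anomaly is AR(1) across days (iid across cells); `eps` is iid hourly
#' noise. Randomness is scoped with the scenario seed: same scenario + seed
#' gives a bit-identical cube.
#'
#' @param surface an `urban_surface`.
#' @param scenario a `heat_scenario`.
#' @return A `temp_cube`.
#' @export
generate_temperature_cube <- function(surface, scenario) {
  validate_scenario(scenario)
  sc <- scenario
  n_t <- sc$n_days * 24L
  ny <- surface$n_y; nx <- surface$n_x; ncell <- ny * nx
  hod <- rep(0:23, sc$n_days)
  day <- rep(seq_len(sc$n_days), each = 24L)

  base_t <- sc$baseline_mean + sc$diurnal_amplitude * sin(2 * pi * (hod - 9) / 24)
  night <- as.numeric(hod < 6 | hod >= 18)
  hw_t <- as.numeric(day >= sc$hw_start_day & day <= sc$hw_end_day)

  hw_cell <- matrix(0, ny, nx)
  hw_cell[surface$urban_fraction > 0] <- sc$hw_amplitude_urban
  hw_cell[surface$land_class == "vegetation"] <- sc$hw_amplitude_rural
  lake <- sc$lake_cooling_amplitude * exp(-lake_distance(surface) / sc$lake_decay_length)
  lake[!is.finite(lake)] <- 0

  vals <- array(base_t, dim = c(n_t, ny, nx))        # recycles along time
  vals <- vals + outer(night * sc$true_uhii_night, surface$urban_fraction)
  vals <- vals + outer(hw_t, hw_cell)
  vals <- vals - outer(rep(1, n_t), lake)

  withr::with_seed(sc$seed, {
    if (sc$synoptic_sd > 0) {
      delta <- matrix(0, sc$n_days, ncell)
      delta[1, ] <- stats::rnorm(ncell, 0, sc$synoptic_sd)
      if (sc$n_days > 1) {
        innov_sd <- sc$synoptic_sd * sqrt(1 - sc$synoptic_rho^2)
        for (d in 2:sc$n_days)
          delta[d, ] <- sc$synoptic_rho * delta[d - 1, ] +
            stats::rnorm(ncell, 0, innov_sd)
      }
      vals <- vals + array(delta[day, ], dim = c(n_t, ny, nx))
    }
    if (sc$noise_sd > 0)
      vals <- vals + array(stats::rnorm(n_t * ncell, 0, sc$noise_sd),
                           dim = c(n_t, ny, nx))
  })

  ts <- as.POSIXct(paste(sc$start_date, "00:00:00"), tz = "UTC") +
    3600 * (seq_len(n_t) - 1)
  temp_cube(vals, ts, surface)
}

#' Generate a multi-year daily climatology
#'
#' Draws `climatology_years` independent baseline years from the scenario's
#' non-heatwave generative process (heatwave amplitudes forced to zero; UHI,
#' lake cooling, synoptic variability and noise retained), each
#' `climatology_days` long, and reduces each year to daily statistics. Year
#' `y` is seeded with `scenario$seed + y`, so the baseline is reproducible
#' and independent of the episode cube (seeded with `scenario$seed`).
#'
#' @param surface an `urban_surface`.
#' @param scenario a `heat_scenario`.
#' @param variant one of `"Tmax"`, `"Tmin"`, `"Tmean"`.
#' @return Object of class `climatology`: list with `variant`, `values`
#'   (array `(n_years * climatology_days, y, x)` of daily values), `n_years`,
#'   `days_per_year`.
#' @export
generate_climatology <- function(surface, scenario, variant = "Tmean") {
  validate_scenario(scenario)
  variant <- check_variant(variant)
  sc <- scenario
  per_year <- vector("list", sc$climatology_years)
  for (y in seq_len(sc$climatology_years)) {
    sc_y <- sc
    sc_y$n_days <- sc$climatology_days
    sc_y$hw_start_day <- 1L; sc_y$hw_end_day <- 1L
    sc_y$hw_amplitude_rural <- 0; sc_y$hw_amplitude_urban <- 0
    sc_y$seed <- sc$seed + y
    cube <- generate_temperature_cube(surface, sc_y)
    ds <- daily_statistics(cube)
    per_year[[y]] <- ds[[variant_field(variant)]]
  }
  n_days <- sc$climatology_years * sc$climatology_days
  vals <- array(NA_real_, dim = c(n_days, surface$n_y, surface$n_x))
  for (y in seq_len(sc$climatology_years))
    vals[(y - 1) * sc$climatology_days + seq_len(sc$climatology_days), , ] <-
      per_year[[y]]
  structure(list(variant = variant, values = vals,
                 n_years = sc$climatology_years,
                 days_per_year = sc$climatology_days),
            class = "climatology")
}

check_variant <- function(variant) {
  if (length(variant) != 1 || !(variant %in% c("Tmax", "Tmin", "Tmean")))
    stop("variant must be one of 'Tmax', 'Tmin', 'Tmean'", call. = FALSE)
  variant
}
variant_field <- function(variant) c(Tmax = "tmax", Tmin = "tmin", Tmean = "tmean")[[variant]]

#' Sample synthetic station observations from a cube
#'
#' Places stations uniformly at random (without replacement) on land cells
#' and records the cube's series at the containing cell plus iid observation
#' noise. Station locations are cell-snapped: the reported fractional
#' location is the cell center, and the true cell is kept in the metadata so
#' evaluation against the generating cube is exact when `obs_noise_sd = 0`.
#'
#' @param cube a `temp_cube`.
#' @param n_stations number of stations (must not exceed the land-cell count).
#' @param obs_noise_sd observation noise sd (degC).
#' @param seed RNG seed for placement and noise.
#' @return List of `station_series` objects (fields `station_id`, `location`
#'   = 0-based fractional `(row, col)`, `cell` = 0-based integer `(row,
#'   col)`, `time`, `obs`).
#' @export
sample_stations <- function(cube, n_stations, obs_noise_sd = 0.5, seed = 1L) {
  surface <- cube$surface
  land <- which(is_land(surface))
  if (n_stations < 1) stop("n_stations must be >= 1", call. = FALSE)
  if (n_stations > length(land))
    stop("n_stations exceeds the number of land cells (", length(land), ")",
         call. = FALSE)
  n_t <- dim(cube$values)[1]
  withr::with_seed(seed, {
    cells <- sample(land, n_stations)
    noise <- matrix(if (obs_noise_sd > 0)
      stats::rnorm(n_t * n_stations, 0, obs_noise_sd) else 0,
      n_t, n_stations)
  })
  lapply(seq_len(n_stations), function(k) {
    idx <- arrayInd(cells[k], c(surface$n_y, surface$n_x))
    row <- idx[1] - 1L; col <- idx[2] - 1L
    structure(
      list(station_id = sprintf("ST%03d", k),
           location = c(row = as.numeric(row), col = as.numeric(col)),
           cell = c(row = row, col = col),
           time = cube$timestamps,
           obs = cube$values[, idx[1], idx[2]] + noise[, k]),
      class = "station_series")
  })
}

#' @export
print.station_series <- function(x, ...) {
  cat(sprintf("station_series %s at (%.2f, %.2f): %d obs, %.1f..%.1f degC\n",
              x$station_id, x$location[1], x$location[2], length(x$obs),
              min(x$obs), max(x$obs)))
  invisible(x)
}
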