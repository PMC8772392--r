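#' Define a synthetic heatwave scenario
#'
#' Bundles the parameters of the synthetic gridded-meteorology generator.
#' Defaults emulate a midwestern coastal city in a hot summer with a four-day
#' heatwave: mean summer temperature around 28.5 degC, a 6 degC-amplitude
#' diurnal cycle peaking at 15:00 local, a heatwave pulse that warms rural
#' land by 4 degC and urban land by 2.5 degC, a 2 degC-per-unit-urban-fraction
#' nighttime urban heat island, lake-breeze cooling of up to 5 degC decaying
#' away from the lake, AR(1) day-to-day synoptic variability and additive
#' hourly observation noise.
#'
#' @param n_days simulated days (hourly resolution, starting 00:00 local).
#' @param start_date first simulated calendar day (`Date` or parseable
#'   string). With the defaults (start 2012-05-28, 45 days) the heatwave
#'   occupies July 4-7 and the 3-day exposure window July 4-6 has 30 complete
#'   prior days for the acclimatization baseline.
#' @param baseline_mean rural daily-mean temperature (degC).
#' @param diurnal_amplitude half peak-to-trough of the diurnal sinusoid
#'   (degC); the cycle peaks at 15:00 local time.
#' @param hw_start_day,hw_end_day heatwave window, 1-based day indices,
#'   inclusive.
#' @param hw_amplitude_rural,hw_amplitude_urban additive heatwave warming
#'   (degC) applied to vegetation cells and to urban (fraction > 0) cells
#'   respectively; the rural response is larger by default.
#' @param true_uhii_night injected nighttime warming per unit urban fraction
#'   (degC) — the ground-truth UHII.
#' @param lake_cooling_amplitude cooling magnitude at the lake shore (degC).
#' @param lake_decay_length e-folding distance of lake cooling (cells).
#' @param noise_sd additive hourly Gaussian noise (degC).
#' @param synoptic_sd standard deviation of the per-day synoptic temperature
#'   anomaly (degC), iid across cells, AR(1) across days.
#' @param synoptic_rho lag-1 autocorrelation of the synoptic anomaly.
#' @param climatology_years number of baseline years for the percentile
#'   climatology.
#' @param climatology_days days per baseline year (92 = one summer season).
#' @param seed RNG seed; identical scenario + seed regenerates bit-identical
#'   output.
#' @return Object of class `heat_scenario`.
#' @export
heat_scenario <- function(n_days = 45,
                          start_date = "2012-05-28",
                          baseline_mean = 28.5,
                          diurnal_amplitude = 6,
                          hw_start_day = 38,
                          hw_end_day = 41,
                          hw_amplitude_rural = 4,
                          hw_amplitude_urban = 2.5,
                          true_uhii_night = 2,
                          lake_cooling_amplitude = 5,
                          lake_decay_length = 2,
                          noise_sd = 0.3,
                          synoptic_sd = 2,
                          synoptic_rho = 0.9,
                          climatology_years = 10,
                          climatology_days = 92,
                          seed = 1L) {
  sc <- structure(
    list(n_days = as.integer(n_days), start_date = as.Date(start_date),
         baseline_mean = baseline_mean, diurnal_amplitude = diurnal_amplitude,
         hw_start_day = as.integer(hw_start_day),
         hw_end_day = as.integer(hw_end_day),
         hw_amplitude_rural = hw_amplitude_rural,
         hw_amplitude_urban = hw_amplitude_urban,
         true_uhii_night = true_uhii_night,
         lake_cooling_amplitude = lake_cooling_amplitude,
         lake_decay_length = lake_decay_length,
         noise_sd = noise_sd, synoptic_sd = synoptic_sd,
         synoptic_rho = synoptic_rho,
         climatology_years = as.integer(climatology_years),
         climatology_days = as.integer(climatology_days),
         seed = as.integer(seed)),
    class = "heat_scenario")
  validate_scenario(sc)
  sc
}

validate_scenario <- function(sc) {
  stopifnot(inherits(sc, "heat_scenario"))
  if (sc$n_days < 1) stop("n_days must be >= 1", call. = FALSE)
  if (!(sc$hw_start_day <= sc$hw_end_day && sc$hw_end_day <= sc$n_days))
    stop("heatwave window must satisfy hw_start_day <= hw_end_day <= n_days",
         call. = FALSE)
  amps <- c(sc$diurnal_amplitude, sc$hw_amplitude_rural, sc$hw_amplitude_urban,
            sc$lake_cooling_amplitude)
  if (any(amps < 0)) stop("amplitudes must be >= 0", call. = FALSE)
  if (sc$noise_sd < 0 || sc$synoptic_sd < 0)
    stop("noise standard deviations must be >= 0", call. = FALSE)
  if (sc$synoptic_rho < 0 || sc$synoptic_rho >= 1)
    stop("synoptic_rho must be in [0, 1)", call. = FALSE)
  if (sc$lake_decay_length <= 0)
    stop("lake_decay_length must be > 0", call. = FALSE)
  if (sc$climatology_years < 1)
    stop("climatology_years must be >= 1", call. = FALSE)
  invisible(sc)
}

#' @export
print.heat_scenario <- function(x, ...) {
  cat(sprintf("heat_scenario: %d days from %s (seed %d)\n",
              x$n_days, format(x$start_date), x$seed))
  cat(sprintf("  baseline %.1f degC, diurnal amplitude %.1f degC\n",
              x$baseline_mean, x$diurnal_amplitude))
  cat(sprintf("  heatwave days %d-%d: +%.1f rural / +%.1f urban degC\n",
              x$hw_start_day, x$hw_end_day,
              x$hw_amplitude_rural, x$hw_amplitude_urban))
  cat(sprintf("  nighttime UHII %.2f degC/fraction, lake cooling %.1f degC (L=%.1f)\n",
              x$true_uhii_night, x$lake_cooling_amplitude, x$lake_decay_length))
  cat(sprintf("  noise sd %.2f, synoptic sd %.2f (rho %.2f), climatology %d x %d d\n",
              x$noise_sd, x$synoptic_sd, x$synoptic_rho,
              x$climatology_years, x$climatology_days))
  invisible(x)
}
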