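# Shared fixtures: small domains and deterministic ("quiet") scenarios.

test_surface <- function(n_y = 20, n_x = 16, lake_cols = 2) {
  if (max(n_y, n_x) >= 16) {
    generate_surface(n_y, n_x, urban_center = c(9, 12),
                     class_radii = c(2, 4, 6, 8), lake_cols = lake_cols)
  } else {
    generate_surface(n_y, n_x,
                     urban_center = c(floor(n_y / 2), floor(n_x / 2)),
                     class_radii = c(1, 2, 3, min(4, max(n_y, n_x))),
                     lake_cols = min(lake_cols, 1))
  }
}

# all stochastic terms and confounders off unless overridden: no noise, no
# synoptic variability, no lake cooling, no heatwave
quiet_scenario <- function(n_days = 3, ...) {
  args <- list(n_days = n_days, hw_start_day = 1, hw_end_day = 1,
               hw_amplitude_rural = 0, hw_amplitude_urban = 0,
               lake_cooling_amplitude = 0, noise_sd = 0, synoptic_sd = 0,
               climatology_years = 2, climatology_days = 30)
  over <- list(...)
  args[names(over)] <- over
  do.call(heat_scenario, args)
}

# independently coded closed-form OLS (normal equations), the oracle for
# fit_uhii
ols_oracle <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  slope <- (n * sum(x * y) - sx * sy) / (n * sum(x^2) - sx^2)
  intercept <- (sy - slope * sx) / n
  list(slope = slope, intercept = intercept)
}

# direct-summation metrics oracle (explicit loop, no vectorized reuse)
metrics_oracle <- function(obs, mod) {
  n <- length(obs)
  s_b <- 0; s_g <- 0; s_q <- 0
  for (i in seq_len(n)) {
    d <- mod[i] - obs[i]
    s_b <- s_b + d
    s_g <- s_g + abs(d)
    s_q <- s_q + d * d
  }
  list(MB = s_b / n, GE = s_g / n, RMSE = sqrt(s_q / n))
}

# sort-and-interpolate percentile oracle: h = (n - 1) p + 1 between order
# statistics
percentile_oracle <- function(x, p = 0.95) {
  x <- sort(x)
  n <- length(x)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  if (lo >= n) return(x[n])
  x[lo] + (h - lo) * (x[lo + 1] - x[lo])
}
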