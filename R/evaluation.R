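#' Match a station to its nearest grid cell
#'
#' Nearest cell center by Euclidean distance in (0-based) grid units; exact
#' ties are broken toward the lower `(row, col)` index.
#'
#' @param station a `station_series` or a numeric `(row, col)` location.
#' @param surface the `urban_surface`.
#' @return Integer `(row, col)`, 0-based.
#' @export
match_station_to_cell <- function(station, surface) {
  loc <- if (inherits(station, "station_series")) station$location else station
  if (loc[1] < -0.5 || loc[1] > surface$n_y - 0.5 ||
      loc[2] < -0.5 || loc[2] > surface$n_x - 0.5)
    stop("station at (", loc[1], ", ", loc[2], ") is outside the grid",
         call. = FALSE)
  # half-integer coordinates round toward the lower index
  snap <- function(v, n) min(max(as.integer(ceiling(v - 0.5)), 0L), n - 1L)
  c(row = snap(loc[1], surface$n_y), col = snap(loc[2], surface$n_x))
}

#' Model-evaluation statistics for one station
#'
#' Pairs modeled and observed series on identical timestamps (unpaired
#' timestamps are dropped with a message) and computes mean bias
#' `MB = mean(mod - obs)`, mean gross error `GE = mean(|mod - obs|)` and
#' `RMSE = sqrt(mean((mod - obs)^2))`, plus pass flags against configurable
#' benchmark thresholds.
#'
#' @param obs,mod numeric temperature series (degC).
#' @param obs_time,mod_time optional timestamp vectors; when given, series
#'   are aligned on their intersection, otherwise they must have equal
#'   length and are paired positionally.
#' @param mb_threshold,ge_threshold benchmark thresholds (degC): the flags
#'   are `|MB| <= mb_threshold` and `GE <= ge_threshold`.
#' @param station_id label carried into the result.
#' @return Object of class `eval_result`: `station_id`, `n`, `MB`, `GE`,
#'   `RMSE`, `mb_ok`, `ge_ok`, `mb_threshold`, `ge_threshold`.
#' @export
compute_metrics <- function(obs, mod, obs_time = NULL, mod_time = NULL,
                            mb_threshold = 0.5, ge_threshold = 2,
                            station_id = NA_character_) {
  if (!is.null(obs_time) || !is.null(mod_time)) {
    if (is.null(obs_time) || is.null(mod_time))
      stop("supply both obs_time and mod_time or neither", call. = FALSE)
    common <- intersect(as.numeric(obs_time), as.numeric(mod_time))
    n_drop <- (length(obs_time) - length(common)) +
      (length(mod_time) - length(common))
    if (n_drop > 0)
      message("compute_metrics: dropped ", n_drop, " unpaired timestamp(s)")
    obs <- obs[match(common, as.numeric(obs_time))]
    mod <- mod[match(common, as.numeric(mod_time))]
  } else if (length(obs) != length(mod)) {
    stop("obs and mod lengths differ and no timestamps were supplied",
         call. = FALSE)
  }
  keep <- !(is.na(obs) | is.na(mod))
  obs <- obs[keep]; mod <- mod[keep]
  n <- length(obs)
  if (n == 0) stop("no paired observations remain", call. = FALSE)
  e <- mod - obs
  mb <- mean(e); ge <- mean(abs(e)); rmse <- sqrt(mean(e^2))
  structure(list(station_id = station_id, n = n, MB = mb, GE = ge,
                 RMSE = rmse, mb_ok = abs(mb) <= mb_threshold,
                 ge_ok = ge <= ge_threshold,
                 mb_threshold = mb_threshold, ge_threshold = ge_threshold),
            class = "eval_result")
}

#' @export
print.eval_result <- function(x, ...) {
  cat(sprintf("%s: n=%d MB=%.3f GE=%.3f RMSE=%.3f  [MB %s, GE %s]\n",
              if (is.na(x$station_id)) "series" else x$station_id,
              x$n, x$MB, x$GE, x$RMSE,
              if (x$mb_ok) "ok" else "exceeds",
              if (x$ge_ok) "ok" else "exceeds"))
  invisible(x)
}

#' Aggregate station metrics
#'
#' Unweighted mean of MB, GE and RMSE across stations; `n` is the total
#' paired sample count. Benchmark flags are re-applied to the aggregate
#' values using the (common) thresholds of the inputs.
#'
#' @param results non-empty list of `eval_result`.
#' @return An `eval_result` with `station_id = "ALL"`.
#' @export
aggregate_metrics <- function(results) {
  if (length(results) == 0) stop("no station results to aggregate", call. = FALSE)
  stopifnot(all(vapply(results, inherits, TRUE, "eval_result")))
  mb_thr <- unique(vapply(results, `[[`, 0, "mb_threshold"))
  ge_thr <- unique(vapply(results, `[[`, 0, "ge_threshold"))
  if (length(mb_thr) != 1 || length(ge_thr) != 1)
    stop("stations were evaluated with different benchmark thresholds",
         call. = FALSE)
  mb <- mean(vapply(results, `[[`, 0, "MB"))
  ge <- mean(vapply(results, `[[`, 0, "GE"))
  rmse <- mean(vapply(results, `[[`, 0, "RMSE"))
  structure(list(station_id = "ALL",
                 n = sum(vapply(results, `[[`, 0L, "n")),
                 MB = mb, GE = ge, RMSE = rmse,
                 mb_ok = abs(mb) <= mb_thr, ge_ok = ge <= ge_thr,
                 mb_threshold = mb_thr, ge_threshold = ge_thr),
            class = "eval_result")
}

#' Evaluate a modeled cube against station observations
#'
#' Matches each station to its grid cell, extracts the modeled series there,
#' computes per-station metrics and appends the unweighted "ALL" aggregate.
#'
#' @param stations list of `station_series`.
#' @param cube the modeled `temp_cube`.
#' @param surface the `urban_surface`; defaults to the cube's.
#' @param mb_threshold,ge_threshold benchmark thresholds (degC).
#' @return data.frame with one row per station plus an `ALL` row; columns
#'   `station_id`, `n`, `MB`, `GE`, `RMSE`, `mb_ok`, `ge_ok`.
#' @export
evaluate_stations <- function(stations, cube, surface = cube$surface,
                              mb_threshold = 0.5, ge_threshold = 2) {
  results <- lapply(stations, function(st) {
    cell <- match_station_to_cell(st, surface)
    mod <- cube$values[, cell[1] + 1L, cell[2] + 1L]
    compute_metrics(st$obs, mod, obs_time = st$time, mod_time = cube$timestamps,
                    mb_threshold = mb_threshold, ge_threshold = ge_threshold,
                    station_id = st$station_id)
  })
  all_row <- aggregate_metrics(results)
  rows <- c(results, list(all_row))
  do.call(rbind, lapply(rows, function(r)
    data.frame(station_id = r$station_id, n = r$n, MB = r$MB, GE = r$GE,
               RMSE = r$RMSE, mb_ok = r$mb_ok, ge_ok = r$ge_ok)))
}
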