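#' Day/night diurnal partition
#'
#' The day window is `[day_start, day_end)` local hours (default 06:00-18:00)
#' and the night window is its complement, spanning midnight
#' (default 18:00-06:00).
#'
#' @param day_start,day_end local hours, `0 <= day_start < day_end <= 24`.
#' @return Object of class `diurnal_mask`.
#' @export
diurnal_mask <- function(day_start = 6, day_end = 18) {
  if (!(day_start >= 0 && day_start < day_end && day_end <= 24))
    stop("need 0 <= day_start < day_end <= 24", call. = FALSE)
  structure(list(day_start = as.integer(day_start),
                 day_end = as.integer(day_end)),
            class = "diurnal_mask")
}

#' Per-date day and night mean grids
#'
#' Day mean of date d averages hours `[day_start, day_end)` of d; the night
#' mean averages `[day_end, 24)` of d plus `[0, day_start)` of d + 1 and is
#' assigned to the date on which the night begins. Incomplete leading or
#' trailing windows are dropped with a message.
#'
#' @param cube a `temp_cube`.
#' @param mask a `diurnal_mask`.
#' @return Object of class `period_means`: list with elements `day` and
#'   `night`, each a list of `dates` (Date) and `values` (array
#'   `(date, y, x)`), plus `n_dropped`.
#' @export
period_means <- function(cube, mask = diurnal_mask()) {
  stopifnot(inherits(mask, "diurnal_mask"))
  hours <- cube_hours(cube)
  dates <- cube_dates(cube)
  ud <- sort(unique(dates))
  ny <- dim(cube$values)[2]; nx <- dim(cube$values)[3]
  n_day_hours <- mask$day_end - mask$day_start
  n_night_hours <- 24L - n_day_hours

  collect <- function(sel_fun, n_required) {
    keep_dates <- as.Date(character())
    grids <- list()
    for (d in ud) {
      sel <- sel_fun(as.Date(d, origin = "1970-01-01"))
      if (length(sel) != n_required) next
      keep_dates <- c(keep_dates, as.Date(d, origin = "1970-01-01"))
      grids[[length(grids) + 1]] <-
        colMeans(cube$values[sel, , , drop = FALSE], dims = 1)
    }
    if (length(grids) == 0) return(NULL)
    vals <- array(NA_real_, dim = c(length(grids), ny, nx))
    for (i in seq_along(grids)) vals[i, , ] <- grids[[i]]
    list(dates = keep_dates, values = vals)
  }

  day <- collect(function(d) which(dates == d & hours >= mask$day_start &
                                     hours < mask$day_end), n_day_hours)
  night <- collect(function(d) which((dates == d & hours >= mask$day_end) |
                                       (dates == d + 1 & hours < mask$day_start)),
                   n_night_hours)
  if (is.null(day) && is.null(night))
    stop("no complete day or night window in the cube", call. = FALSE)
  n_possible <- 2L * length(ud)
  n_kept <- length(day$dates) + length(night$dates)
  if (n_possible > n_kept)
    message("period_means: dropped ", n_possible - n_kept,
            " incomplete window(s)")
  structure(list(day = day, night = night, n_dropped = n_possible - n_kept),
            class = "period_means")
}

#' Fit the UHII regression on one mean-temperature grid
#'
#' Ordinary least squares of per-cell temperature on urban fraction,
#' `T = URB_FRC x UHII + T(vegetation)`, over all land cells (vegetation and
#' urban); open-water cells are excluded, and vegetation cells are the only
#' zero-fraction data entering the fit. The slope is the urban heat island
#' intensity (degC per unit urban fraction) and the intercept the baseline
#' vegetation temperature.
#'
#' @param mean_grid numeric matrix `(y, x)` of temperatures (degC).
#' @param surface the `urban_surface` the grid lies on.
#' @param conf_level confidence level for the slope interval.
#' @return Object of class `uhii_fit`: `slope`, `intercept`, `slope_se`,
#'   `ci_lower`, `ci_upper`, `r_value` (Pearson correlation), `p_value`
#'   (two-sided t test of slope = 0), `n_cells`.
#' @export
fit_uhii <- function(mean_grid, surface, conf_level = 0.95) {
  if (!identical(dim(mean_grid), c(surface$n_y, surface$n_x)))
    stop("mean_grid and surface dimensions differ", call. = FALSE)
  use <- is_land(surface) & !is.na(mean_grid)
  x <- surface$urban_fraction[use]
  y <- mean_grid[use]
  n <- length(y)
  if (n < 3) stop("fewer than 3 usable land cells (", n, ")", call. = FALSE)
  if (length(unique(x)) < 2)
    stop("degenerate design: all urban fractions identical", call. = FALSE)
  fm <- stats::lm(y ~ x)
  co <- summary(fm)$coefficients
  tcrit <- stats::qt(1 - (1 - conf_level) / 2, df = n - 2)
  structure(list(slope = unname(co["x", "Estimate"]),
                 intercept = unname(co["(Intercept)", "Estimate"]),
                 slope_se = unname(co["x", "Std. Error"]),
                 ci_lower = unname(co["x", "Estimate"] - tcrit * co["x", "Std. Error"]),
                 ci_upper = unname(co["x", "Estimate"] + tcrit * co["x", "Std. Error"]),
                 r_value = stats::cor(x, y),
                 p_value = unname(co["x", "Pr(>|t|)"]),
                 n_cells = n),
            class = "uhii_fit")
}

#' @export
print.uhii_fit <- function(x, ...) {
  cat(sprintf("UHII %.3f degC/fraction (SE %.3f, 95%% CI %.3f..%.3f)\n",
              x$slope, x$slope_se, x$ci_lower, x$ci_upper))
  cat(sprintf("  T(vegetation) %.2f degC, r = %.3f, p = %.3g, n = %d cells\n",
              x$intercept, x$r_value, x$p_value, x$n_cells))
  invisible(x)
}

#' Daily UHII series
#'
#' One UHII regression per complete date on the chosen period's mean grid
#' (per-date means, not pooled hourly values). A date whose fit fails is kept
#' in the table with NA estimates and the failure message in `note`.
#'
#' @param cube a `temp_cube`.
#' @param surface the `urban_surface`; defaults to the cube's.
#' @param mask a `diurnal_mask`.
#' @param period `"day"` or `"night"`.
#' @param conf_level confidence level for the slope interval.
#' @return data.frame with columns `date`, `period`, `slope`, `intercept`,
#'   `slope_se`, `ci_lower`, `ci_upper`, `r_value`, `p_value`, `n_cells`,
#'   `note`.
#' @export
daily_uhii_series <- function(cube, surface = cube$surface,
                              mask = diurnal_mask(), period = "night",
                              conf_level = 0.95) {
  if (!(period %in% c("day", "night")))
    stop("period must be 'day' or 'night'", call. = FALSE)
  pm <- period_means(cube, mask)[[period]]
  if (is.null(pm)) stop("no complete ", period, " window", call. = FALSE)
  rows <- lapply(seq_along(pm$dates), function(i) {
    fit <- tryCatch(fit_uhii(pm$values[i, , ], surface, conf_level),
                    error = function(e) e)
    if (inherits(fit, "error")) {
      warning("UHII fit failed for ", format(pm$dates[i]), ": ",
              conditionMessage(fit), call. = FALSE)
      data.frame(date = pm$dates[i], period = period, slope = NA_real_,
                 intercept = NA_real_, slope_se = NA_real_,
                 ci_lower = NA_real_, ci_upper = NA_real_,
                 r_value = NA_real_, p_value = NA_real_,
                 n_cells = NA_integer_, note = conditionMessage(fit))
    } else {
      data.frame(date = pm$dates[i], period = period, slope = fit$slope,
                 intercept = fit$intercept, slope_se = fit$slope_se,
                 ci_lower = fit$ci_lower, ci_upper = fit$ci_upper,
                 r_value = fit$r_value, p_value = fit$p_value,
                 n_cells = fit$n_cells, note = "")
    }
  })
  do.call(rbind, rows)
}

# Bresenham line between two 0-based (row, col) cells; 8-connected, includes
# both endpoints.
bresenham_line <- function(start, end) {
  r0 <- as.integer(start[1]); c0 <- as.integer(start[2])
  r1 <- as.integer(end[1]); c1 <- as.integer(end[2])
  dr <- abs(r1 - r0); dc <- abs(c1 - c0)
  sr <- if (r0 < r1) 1L else -1L
  sc <- if (c0 < c1) 1L else -1L
  err <- dc - dr
  rows <- integer(0); cols <- integer(0)
  repeat {
    rows <- c(rows, r0); cols <- c(cols, c0)
    if (r0 == r1 && c0 == c1) break
    e2 <- 2L * err
    if (e2 > -dr) { err <- err - dr; c0 <- c0 + sc }
    if (e2 < dc) { err <- err + dc; r0 <- r0 + sr }
  }
  cbind(row = rows, col = cols)
}

#' Urban-to-rural cross-section
#'
#' Extracts the discrete (Bresenham, 8-connected) line of cells from an urban
#' start to a rural end and averages the per-date day/night mean grids over
#' each named date set, giving one temperature profile per date set x period.
#' The urban mean Tu averages positions with urban fraction >= `tu_min_frac`;
#' the rural mean Tr averages zero-fraction vegetation positions;
#' `delta_T = Tu - Tr`.
#'
#' @param cube a `temp_cube`.
#' @param surface the `urban_surface`; defaults to the cube's.
#' @param start,end 0-based `(row, col)` endpoints; both must be on land.
#' @param mask a `diurnal_mask`.
#' @param date_sets named list of Date vectors (e.g. heatwave vs non-heatwave
#'   days).
#' @param tu_min_frac urban-fraction threshold defining "urban" positions.
#' @return Object of class `cross_section`: `path` data.frame (`position`,
#'   `row`, `col`, `urban_fraction`, `land_class`), `temps` data.frame
#'   (`set`, `period`, `position`, `temp`), `summary` data.frame (`set`,
#'   `period`, `Tu`, `Tr`, `delta_T`).
#' @export
extract_cross_section <- function(cube, surface = cube$surface, start, end,
                                  mask = diurnal_mask(), date_sets,
                                  tu_min_frac = 0.5) {
  for (p in list(start, end))
    if (p[1] < 0 || p[1] > surface$n_y - 1 || p[2] < 0 || p[2] > surface$n_x - 1)
      stop("cross-section endpoint outside the grid", call. = FALSE)
  line <- bresenham_line(start, end)
  cls <- surface$land_class[cbind(line[, 1] + 1L, line[, 2] + 1L)]
  if (any(cls[c(1, nrow(line))] == "open_water"))
    stop("cross-section endpoints must be on land", call. = FALSE)
  if (length(unique(cls)) < 2)
    warning("cross-section lies within a single land class", call. = FALSE)
  frac <- surface$urban_fraction[cbind(line[, 1] + 1L, line[, 2] + 1L)]
  path <- data.frame(position = seq_len(nrow(line)) - 1L,
                     row = line[, 1], col = line[, 2],
                     urban_fraction = frac, land_class = cls)

  pm <- period_means(cube, mask)
  is_urban <- frac >= tu_min_frac
  is_rural <- frac == 0 & cls == "vegetation"
  temps <- list(); summ <- list()
  for (set_name in names(date_sets)) {
    for (period in c("day", "night")) {
      pd <- pm[[period]]
      if (is.null(pd)) next
      sel <- which(pd$dates %in% as.Date(date_sets[[set_name]]))
      if (length(sel) == 0)
        stop("date set '", set_name, "' has no complete ", period, " window",
             call. = FALSE)
      grid <- apply(pd$values[sel, , , drop = FALSE], c(2, 3), mean)
      prof <- grid[cbind(line[, 1] + 1L, line[, 2] + 1L)]
      tu <- if (any(is_urban)) mean(prof[is_urban]) else NA_real_
      tr <- if (any(is_rural)) mean(prof[is_rural]) else NA_real_
      if (is.na(tu) || is.na(tr))
        warning("Tu or Tr undefined on cross-section for ", set_name, "/",
                period, call. = FALSE)
      temps[[length(temps) + 1]] <-
        data.frame(set = set_name, period = period, position = path$position,
                   temp = prof)
      summ[[length(summ) + 1]] <-
        data.frame(set = set_name, period = period, Tu = tu, Tr = tr,
                   delta_T = tu - tr)
    }
  }
  structure(list(path = path, temps = do.call(rbind, temps),
                 summary = do.call(rbind, summ)),
            class = "cross_section")
}
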