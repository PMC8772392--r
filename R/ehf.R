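#' Daily Tmax/Tmin/Tmean statistics from an hourly cube
#'
#' Reduces each complete local calendar day (24 hourly values) to its
#' maximum, minimum and arithmetic mean per cell. Incomplete leading or
#' trailing days are excluded with a message.
#'
#' @param cube a `temp_cube`.
#' @return Object of class `daily_statistics`: list with `dates` (Date) and
#'   `tmax`, `tmin`, `tmean` arrays `(day, y, x)`.
#' @export
daily_statistics <- function(cube) {
  dates <- cube_dates(cube)
  ud <- unique(dates)
  counts <- table(dates)
  complete <- ud[counts[as.character(ud)] == 24L]
  dropped <- length(ud) - length(complete)
  if (dropped > 0)
    message("daily_statistics: excluded ", dropped, " incomplete day(s)")
  if (length(complete) == 0)
    stop("no complete local day in the cube", call. = FALSE)
  ny <- dim(cube$values)[2]; nx <- dim(cube$values)[3]
  nd <- length(complete)
  tmax <- tmin <- tmean <- array(NA_real_, dim = c(nd, ny, nx))
  for (i in seq_len(nd)) {
    sel <- which(dates == complete[i])
    block <- cube$values[sel, , , drop = FALSE]
    m <- matrix(block, length(sel), ny * nx)
    mx <- m[1, ]; mn <- m[1, ]
    for (r in seq_len(nrow(m))[-1]) {
      mx <- pmax(mx, m[r, ]); mn <- pmin(mn, m[r, ])
    }
    tmax[i, , ] <- mx
    tmin[i, , ] <- mn
    tmean[i, , ] <- colMeans(m)
  }
  structure(list(dates = complete, tmax = tmax, tmin = tmin, tmean = tmean),
            class = "daily_statistics")
}

#' 95th-percentile climatology baseline (T95)
#'
#' Per-cell 95th percentile of the multi-year daily series, using linear
#' interpolation between closest order statistics (the `h = (n - 1) p + 1`
#' rule; for 100 values 1..100 this gives 95.05). The interpolation rule is
#' recorded in the result because different percentile conventions shift T95
#' by tenths of a degree.
#'
#' @param climatology a `climatology` (see [generate_climatology()]) or any
#'   list with `values` array `(day, y, x)` and a `variant` field.
#' @param probs percentile level (default 0.95).
#' @return Object of class `climatology_baseline`: `variant`, `t95` matrix
#'   `(y, x)`, `n_years`, `n_days`, `percentile_method`.
#' @export
compute_t95 <- function(climatology, probs = 0.95) {
  vals <- climatology$values
  n_days <- dim(vals)[1]
  if (n_days < 20)
    stop("at least 20 daily values per cell are required for the percentile; got ",
         n_days, call. = FALSE)
  t95 <- apply(vals, c(2, 3), stats::quantile, probs = probs, type = 7,
               names = FALSE, na.rm = FALSE)
  structure(list(variant = climatology$variant, t95 = t95,
                 n_years = climatology$n_years %||% NA_integer_,
                 n_days = n_days,
                 percentile_method = "linear interpolation between order statistics (type 7)"),
            class = "climatology_baseline")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Mean over a fixed window of daily grids
#'
#' Arithmetic mean per cell over an explicit, complete set of daily dates.
#' `rolling_previous_mean()` is the "previous consecutive N days" form: the
#' `window` days strictly before `as_of`. `window_mean()` takes an explicit
#' date list (the 3-day exposure window of an event is pinned to explicit
#' dates, e.g. July 4-6). Any missing day is an error naming the absent
#' dates; partial means are never returned.
#'
#' @param daily a `daily_statistics`.
#' @param variant one of `"Tmax"`, `"Tmin"`, `"Tmean"`.
#' @param dates explicit Date vector of window days.
#' @param window window length in days (3 or 30 in practice).
#' @param as_of anchor date; the window is `as_of - window, ..., as_of - 1`.
#' @return Matrix `(y, x)` of per-cell means (degC).
#' @export
window_mean <- function(daily, dates, variant = "Tmean") {
  variant <- check_variant(variant)
  dates <- as.Date(dates)
  miss <- dates[!(dates %in% daily$dates)]
  if (length(miss) > 0)
    stop("window incomplete; missing day(s): ",
         paste(format(miss), collapse = ", "), call. = FALSE)
  idx <- match(dates, daily$dates)
  vals <- daily[[variant_field(variant)]][idx, , , drop = FALSE]
  apply(vals, c(2, 3), mean)
}

#' @rdname window_mean
#' @export
rolling_previous_mean <- function(daily, window, as_of, variant = "Tmean") {
  if (!(window >= 1)) stop("window must be >= 1", call. = FALSE)
  as_of <- as.Date(as_of)
  window_mean(daily, seq(as_of - window, by = "day", length.out = window),
              variant = variant)
}

#' Excess heat indices and Excess Heat Factor
#'
#' Combines a 3-day mean grid, a 30-day acclimatization grid and a
#' percentile baseline into the excess heat significance index
#' `EHI_sig = T3 - T95`, the acclimatization index `EHI_accl = T3 - T30`,
#' and the Excess Heat Factor `EHF = EHI_sig * max(1, EHI_accl)` (degC^2),
#' with severity classified by [classify_severity()]. Open-water cells are
#' masked (NA) when a surface is supplied.
#'
#' @param t3,t30 per-cell mean grids `(y, x)` over the 3-day event window and
#'   the previous 30 days (degC).
#' @param t95 a `climatology_baseline` or a bare `(y, x)` matrix (degC).
#' @param surface optional `urban_surface` used to mask open water.
#' @param variant label stored in the result.
#' @param high_threshold severity threshold (degC^2), default 2.
#' @return Object of class `ehf_field`: `variant`, `t3`, `t30`, `t95`,
#'   `ehi_sig`, `ehi_accl`, `ehf`, `severity` (character matrix in
#'   `none/positive/high`, NA on masked cells), `high_threshold`.
#' @export
compute_ehf <- function(t3, t30, t95, surface = NULL, variant = "Tmean",
                        high_threshold = 2) {
  t95m <- if (inherits(t95, "climatology_baseline")) t95$t95 else t95
  if (!identical(dim(t3), dim(t30)) || !identical(dim(t3), dim(t95m)))
    stop("t3, t30 and t95 grids are not congruent", call. = FALSE)
  ehi_sig <- t3 - t95m
  ehi_accl <- t3 - t30
  ehf <- ehi_sig * pmax(1, ehi_accl)
  if (!is.null(surface)) {
    water <- surface$land_class == "open_water"
    ehi_sig[water] <- NA_real_; ehi_accl[water] <- NA_real_; ehf[water] <- NA_real_
  }
  structure(list(variant = variant, t3 = t3, t30 = t30, t95 = t95m,
                 ehi_sig = ehi_sig, ehi_accl = ehi_accl, ehf = ehf,
                 severity = classify_severity(ehf, high_threshold),
                 high_threshold = high_threshold),
            class = "ehf_field")
}

#' Classify EHF severity
#'
#' `none` when EHF <= 0 (no excess heat), `positive` when 0 < EHF <=
#' `high_threshold`, `high` when EHF > `high_threshold`. The default
#' threshold of 2 degC^2 marks a high-severity heatwave; positive EHF alone
#' is already associated with elevated health burden. NA passes through.
#'
#' @param ehf numeric matrix/vector of EHF values (degC^2), or an
#'   `ehf_field`.
#' @param high_threshold non-negative severity threshold (degC^2).
#' @return Character matrix/vector with values `none`, `positive`, `high`.
#' @export
classify_severity <- function(ehf, high_threshold = 2) {
  if (inherits(ehf, "ehf_field")) ehf <- ehf$ehf
  if (high_threshold < 0) stop("high_threshold must be >= 0", call. = FALSE)
  out <- ifelse(is.na(ehf), NA_character_,
                ifelse(ehf <= 0, "none",
                       ifelse(ehf > high_threshold, "high", "positive")))
  if (is.matrix(ehf)) out <- matrix(out, nrow(ehf), ncol(ehf))
  out
}

#' Full EHF map for a heatwave episode
#'
#' Chains the stage operations for one temperature variant: daily statistics
#' from the hourly cube, the 3-day event mean over `t3_dates`, the 30-day
#' acclimatization mean over the days preceding the event, the percentile
#' baseline from the climatology, the excess heat indices and severity.
#'
#' @param cube a `temp_cube` spanning the episode and at least the 30 days
#'   before `min(t3_dates)`.
#' @param climatology a `climatology` for the same variant.
#' @param t3_dates explicit Date vector of the event window (3 days for the
#'   canonical definition).
#' @param variant one of `"Tmax"`, `"Tmin"`, `"Tmean"`; must match the
#'   climatology's variant.
#' @param high_threshold severity threshold (degC^2).
#' @param t30_window acclimatization window length (days) ending the day
#'   before `min(t3_dates)`.
#' @return An `ehf_field`.
#' @export
ehf_episode_map <- function(cube, climatology, t3_dates, variant = "Tmean",
                            high_threshold = 2, t30_window = 30) {
  variant <- check_variant(variant)
  if (!identical(climatology$variant, variant))
    stop("climatology variant (", climatology$variant,
         ") does not match requested variant (", variant, ")", call. = FALSE)
  ds <- tryCatch(daily_statistics(cube),
                 error = function(e) stop("daily_statistics stage: ",
                                          conditionMessage(e), call. = FALSE))
  t3 <- tryCatch(window_mean(ds, t3_dates, variant),
                 error = function(e) stop("T3 stage: ", conditionMessage(e),
                                          call. = FALSE))
  t30 <- tryCatch(rolling_previous_mean(ds, t30_window, min(as.Date(t3_dates)),
                                        variant),
                  error = function(e) stop("T30 stage: ", conditionMessage(e),
                                           call. = FALSE))
  t95 <- tryCatch(compute_t95(climatology),
                  error = function(e) stop("T95 stage: ", conditionMessage(e),
                                           call. = FALSE))
  compute_ehf(t3, t30, t95, surface = cube$surface, variant = variant,
              high_threshold = high_threshold)
}

#' @export
print.ehf_field <- function(x, ...) {
  cat(sprintf("ehf_field (%s): EHF %.2f..%.2f degC^2\n", x$variant,
              min(x$ehf, na.rm = TRUE), max(x$ehf, na.rm = TRUE)))
  tab <- table(factor(x$severity, levels = c("none", "positive", "high")))
  cat(sprintf("  severity: none %d, positive %d, high %d (threshold %.1f degC^2)\n",
              tab[["none"]], tab[["positive"]], tab[["high"]], x$high_threshold))
  invisible(x)
}
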