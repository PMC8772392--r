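#' Default pipeline configuration
#'
#' Flat key-value configuration driving the whole pipeline. Every key has a
#' documented default; [read_config()] / [write_config()] persist it as a
#' flat YAML file, and every [run_stage()] call writes the fully resolved
#' configuration beside its outputs so any run is reproducible from its
#' artifacts.
#'
#' Keys (defaults in parentheses): grid layout `n_y` (36), `n_x` (30),
#' `urban_center_row` (14), `urban_center_col` (24), `radius_industrial`
#' (4), `radius_high` (7), `radius_low` (10), `radius_rural` (14),
#' `lake_cols` (2), `cell_size_km` (1); scenario fields as in
#' [heat_scenario()]; diurnal window `day_start` (6), `day_end` (18);
#' station sampling `n_stations` (15), `obs_noise_sd` (0.5); evaluation
#' benchmarks `mb_threshold` (0.5 degC), `ge_threshold` (2 degC); exposure
#' `t3_dates` ("2012-07-04,2012-07-05,2012-07-06"), `t30_window` (30),
#' `ehf_high_threshold` (2 degC2), `variant` ("Tmean" or "all");
#' cross-section endpoints `cross_start_row/col`, `cross_end_row/col`;
#' `seed` (1) and `out_dir`.
#'
#' @param ... overrides for any key (unknown keys are an error).
#' @return Named list of configuration values.
#' @export
default_config <- function(...) {
  cfg <- list(
    # surface
    n_y = 36L, n_x = 30L, urban_center_row = 14L, urban_center_col = 24L,
    radius_industrial = 4, radius_high = 7, radius_low = 10, radius_rural = 14,
    lake_cols = 2L, cell_size_km = 1,
    # scenario
    n_days = 45L, start_date = "2012-05-28", baseline_mean = 28.5,
    diurnal_amplitude = 6, hw_start_day = 38L, hw_end_day = 41L,
    hw_amplitude_rural = 4, hw_amplitude_urban = 2.5, true_uhii_night = 2,
    lake_cooling_amplitude = 5, lake_decay_length = 2, noise_sd = 0.3,
    synoptic_sd = 2, synoptic_rho = 0.9, climatology_years = 10L,
    climatology_days = 92L,
    # diurnal partition
    day_start = 6L, day_end = 18L,
    # stations + evaluation
    n_stations = 15L, obs_noise_sd = 0.5,
    mb_threshold = 0.5, ge_threshold = 2,
    # exposure
    t3_dates = "2012-07-04,2012-07-05,2012-07-06", t30_window = 30L,
    ehf_high_threshold = 2, variant = "Tmean",
    # cross-section (urban core to western rural edge)
    cross_start_row = 14L, cross_start_col = 24L,
    cross_end_row = 14L, cross_end_col = 0L,
    # run control
    seed = 1L, out_dir = "results/pipeline"
  )
  resolve_config(cfg, list(...))
}

#' Merge overrides into a configuration, validating keys
#'
#' @param cfg base configuration (a full key set).
#' @param overrides named list of overriding values.
#' @return The merged configuration.
#' @export
resolve_config <- function(cfg, overrides = list()) {
  if (length(overrides) > 0) {
    unknown <- setdiff(names(overrides), names(cfg))
    if (length(unknown) > 0)
      stop("invalid config key(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    cfg[names(overrides)] <- overrides
  }
  cfg
}

#' @rdname default_config
#' @param path YAML file path.
#' @param cfg configuration list to write.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' @rdname default_config
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  resolve_config(default_config(), yaml::read_yaml(path))
}

surface_from_config <- function(cfg) {
  generate_surface(cfg$n_y, cfg$n_x,
                   urban_center = c(cfg$urban_center_row, cfg$urban_center_col),
                   class_radii = c(cfg$radius_industrial, cfg$radius_high,
                                   cfg$radius_low, cfg$radius_rural),
                   lake_cols = cfg$lake_cols, cell_size = cfg$cell_size_km)
}

scenario_from_config <- function(cfg) {
  heat_scenario(n_days = cfg$n_days, start_date = cfg$start_date,
                baseline_mean = cfg$baseline_mean,
                diurnal_amplitude = cfg$diurnal_amplitude,
                hw_start_day = cfg$hw_start_day, hw_end_day = cfg$hw_end_day,
                hw_amplitude_rural = cfg$hw_amplitude_rural,
                hw_amplitude_urban = cfg$hw_amplitude_urban,
                true_uhii_night = cfg$true_uhii_night,
                lake_cooling_amplitude = cfg$lake_cooling_amplitude,
                lake_decay_length = cfg$lake_decay_length,
                noise_sd = cfg$noise_sd, synoptic_sd = cfg$synoptic_sd,
                synoptic_rho = cfg$synoptic_rho,
                climatology_years = cfg$climatology_years,
                climatology_days = cfg$climatology_days, seed = cfg$seed)
}

config_variants <- function(cfg) {
  if (identical(cfg$variant, "all")) c("Tmax", "Tmin", "Tmean")
  else check_variant(cfg$variant)
}

config_t3_dates <- function(cfg) {
  as.Date(trimws(strsplit(cfg$t3_dates, ",", fixed = TRUE)[[1]]))
}

pipeline_paths <- function(out_dir) {
  list(cube = file.path(out_dir, "cube.txt"),
       clim = function(v) file.path(out_dir, sprintf("climatology_%s.txt", v)),
       stations = file.path(out_dir, "stations.csv"),
       metrics = file.path(out_dir, "metrics.csv"),
       uhii = file.path(out_dir, "uhii_daily.csv"),
       cross = file.path(out_dir, "cross_section.csv"),
       cross_summary = file.path(out_dir, "cross_section_summary.csv"),
       ehf = function(v) file.path(out_dir, sprintf("ehf_%s.txt", v)),
       ehf_summary = file.path(out_dir, "ehf_summary.csv"),
       config = file.path(out_dir, "config_used.yml"),
       report = file.path(out_dir, "report.txt"))
}

require_file <- function(path, produced_by) {
  if (!file.exists(path))
    stop("dependency error: missing ", path,
         " (run the '", produced_by, "' stage first)", call. = FALSE)
  path
}

write_csv_bin <- function(df, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Run one pipeline stage
#'
#' Stages: `simulate` writes the synthetic cube + surface, the per-variant
#' climatologies and the station sample; `evaluate` writes the station
#' metrics table; `uhii` writes the daily day/night UHII series and the
#' urban-to-rural cross-section tables; `ehf` writes the gridded EHF
#' field(s) and a severity summary; `report` writes a plain-text digest of
#' all prior outputs. Every stage re-reads its inputs from `out_dir` (so
#' stages are independent processes) and writes the resolved configuration
#' beside its outputs. Identical configuration + seed gives byte-identical
#' output files.
#'
#' @param stage one of `"simulate"`, `"evaluate"`, `"uhii"`, `"ehf"`,
#'   `"report"`.
#' @param config configuration list (see [default_config()]).
#' @param out_dir output directory; defaults to `config$out_dir`.
#' @param verbose emit progress messages.
#' @return Invisibly, a character vector of the files written.
#' @export
run_stage <- function(stage, config = default_config(),
                      out_dir = config$out_dir, verbose = FALSE) {
  stages <- c("simulate", "evaluate", "uhii", "ehf", "report")
  if (!(stage %in% stages))
    stop("unknown stage '", stage, "'; valid: ",
         paste(stages, collapse = ", "), call. = FALSE)
  say <- function(...) if (verbose) message("[", stage, "] ", ...)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- pipeline_paths(out_dir)
  written <- character(0)

  if (stage == "simulate") {
    surface <- surface_from_config(config)
    scenario <- scenario_from_config(config)
    say("generating ", scenario$n_days, "-day cube on ",
        surface$n_y, "x", surface$n_x, " grid")
    cube <- generate_temperature_cube(surface, scenario)
    write_cube(cube, surface, p$cube)
    written <- c(written, p$cube)
    for (v in config_variants(config)) {
      say("generating ", v, " climatology (", scenario$climatology_years,
          " years)")
      clim <- generate_climatology(surface, scenario, v)
      write_climatology(clim, p$clim(v))
      written <- c(written, p$clim(v))
    }
    say("sampling ", config$n_stations, " stations")
    stations <- sample_stations(cube, config$n_stations,
                                obs_noise_sd = config$obs_noise_sd,
                                seed = config$seed + 9999L)
    write_station_csv(stations, p$stations)
    written <- c(written, p$stations)
  } else if (stage == "evaluate") {
    cube <- read_cube(require_file(p$cube, "simulate"))$cube
    stations <- read_station_csv(require_file(p$stations, "simulate"))
    tab <- evaluate_stations(stations, cube,
                             mb_threshold = config$mb_threshold,
                             ge_threshold = config$ge_threshold)
    tab$MB <- fmt_num(tab$MB); tab$GE <- fmt_num(tab$GE)
    tab$RMSE <- fmt_num(tab$RMSE)
    write_csv_bin(tab, p$metrics)
    written <- c(written, p$metrics)
  } else if (stage == "uhii") {
    cube <- read_cube(require_file(p$cube, "simulate"))$cube
    mask <- diurnal_mask(config$day_start, config$day_end)
    say("fitting daily UHII series")
    ser <- rbind(daily_uhii_series(cube, mask = mask, period = "day"),
                 daily_uhii_series(cube, mask = mask, period = "night"))
    ser$date <- format(ser$date)
    for (cl in c("slope", "intercept", "slope_se", "ci_lower", "ci_upper",
                 "r_value", "p_value"))
      ser[[cl]] <- fmt_num(ser[[cl]])
    write_csv_bin(ser, p$uhii)
    written <- c(written, p$uhii)

    dates <- sort(unique(cube_dates(cube)))
    hw_days <- dates[config$hw_start_day:min(config$hw_end_day, length(dates))]
    non_hw <- setdiff(dates, hw_days)
    xs <- extract_cross_section(
      cube, start = c(config$cross_start_row, config$cross_start_col),
      end = c(config$cross_end_row, config$cross_end_col), mask = mask,
      date_sets = list(HW = hw_days,
                       nonHW = as.Date(non_hw, origin = "1970-01-01")))
    tt <- merge(xs$temps, xs$path, by = "position", sort = FALSE)
    tt <- tt[order(tt$set, tt$period, tt$position),
             c("set", "period", "position", "row", "col", "urban_fraction",
               "land_class", "temp")]
    tt$temp <- fmt_num(tt$temp)
    write_csv_bin(tt, p$cross)
    su <- xs$summary
    for (cl in c("Tu", "Tr", "delta_T")) su[[cl]] <- fmt_num(su[[cl]])
    write_csv_bin(su, p$cross_summary)
    written <- c(written, p$cross, p$cross_summary)
  } else if (stage == "ehf") {
    cube <- read_cube(require_file(p$cube, "simulate"))$cube
    summaries <- list()
    for (v in config_variants(config)) {
      clim <- read_climatology(require_file(p$clim(v), "simulate"))
      say("EHF map for ", v)
      field <- ehf_episode_map(cube, clim, config_t3_dates(config),
                               variant = v,
                               high_threshold = config$ehf_high_threshold,
                               t30_window = config$t30_window)
      write_ehf_field(field, p$ehf(v))
      written <- c(written, p$ehf(v))
      land <- is_land(cube$surface)
      tab <- table(factor(field$severity[land],
                          levels = c("none", "positive", "high")))
      summaries[[v]] <- data.frame(
        variant = v, n_land_cells = sum(land),
        n_none = tab[["none"]], n_positive = tab[["positive"]],
        n_high = tab[["high"]],
        ehf_land_max = fmt_num(max(field$ehf[land], na.rm = TRUE)),
        ehf_land_median = fmt_num(stats::median(field$ehf[land], na.rm = TRUE)))
    }
    write_csv_bin(do.call(rbind, summaries), p$ehf_summary)
    written <- c(written, p$ehf_summary)
  } else if (stage == "report") {
    lines <- c("urbanheat pipeline report", "=========================")
    if (file.exists(p$metrics)) {
      m <- utils::read.csv(p$metrics)
      all_row <- m[m$station_id == "ALL", ]
      lines <- c(lines, "",
                 sprintf("Station evaluation (%d stations, %d paired hours):",
                         nrow(m) - 1, all_row$n),
                 sprintf("  mean MB %.3f degC, GE %.3f degC, RMSE %.3f degC",
                         all_row$MB, all_row$GE, all_row$RMSE),
                 sprintf("  benchmarks: %d/%d stations pass |MB|, %d/%d pass GE",
                         sum(m$mb_ok[m$station_id != "ALL"]), nrow(m) - 1,
                         sum(m$ge_ok[m$station_id != "ALL"]), nrow(m) - 1))
    }
    if (file.exists(p$uhii)) {
      u <- utils::read.csv(p$uhii)
      un <- u[u$period == "night" & !is.na(u$slope), ]
      lines <- c(lines, "",
                 sprintf("Nighttime UHII over %d nights: %.2f to %.2f degC/fraction (median %.2f)",
                         nrow(un), min(un$slope), max(un$slope),
                         stats::median(un$slope)),
                 sprintf("  nights with r > 0.7 and p < 0.01: %d/%d",
                         sum(un$r_value > 0.7 & un$p_value < 0.01), nrow(un)))
    }
    if (file.exists(p$cross_summary)) {
      cs <- utils::read.csv(p$cross_summary)
      for (i in seq_len(nrow(cs)))
        lines <- c(lines, sprintf(
          "Cross-section %s/%s: Tu %.2f, Tr %.2f, delta_T %.2f degC",
          cs$set[i], cs$period[i], cs$Tu[i], cs$Tr[i], cs$delta_T[i]))
    }
    if (file.exists(p$ehf_summary)) {
      es <- utils::read.csv(p$ehf_summary)
      lines <- c(lines, "")
      for (i in seq_len(nrow(es)))
        lines <- c(lines, sprintf(
          "EHF (%s): max %.1f degC2 on land, %d/%d land cells high severity",
          es$variant[i], es$ehf_land_max[i], es$n_high[i], es$n_land_cells[i]))
    }
    con <- file(p$report, open = "wb")
    writeLines(lines, con, sep = "\n")
    close(con)
    written <- c(written, p$report)
  }

  write_config(config, p$config)
  written <- c(written, p$config)
  say("wrote ", length(written), " file(s)")
  invisible(written)
}
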