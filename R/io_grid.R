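#' Gridded text format
#'
#' Single self-describing plain-text file for gridded fields, mirroring the
#' CF layout conventions: named dimensions in fixed `(time, y, x)` order for
#' cubes and `(y, x)` for static fields, a mandatory `units` attribute per
#' variable, a documented integer code table for land classes, and a
#' time-encoding string. Values are written with `%.17g`, so doubles
#' round-trip bit-exactly; missing values are written as `NA`.
#'
#' Layout:
#' \preformatted{
#' gridtext 1
#' meta n_y=<rows> n_x=<cols> cell_size_km=<km>
#' meta time_units=hours since <YYYY-MM-DD HH:MM> local
#' meta land_class_codes=0:open_water,1:vegetation,...
#' var <name> dims=time,y,x units=<units> n_t=<steps>
#' <one line of n_y*n_x values per time step, row-major (row 0 first)>
#' var <name> dims=y,x units=<units>
#' <n_y lines of n_x values>
#' }
#'
#' @name gridtext
#' @keywords internal
NULL

fmt_num <- function(x) {
  out <- sprintf("%.17g", x)
  out[is.na(x)] <- "NA"
  out
}

# one matrix (y, x) -> n_y lines of n_x numbers
fmt_matrix <- function(m) {
  apply(m, 1, function(r) paste(fmt_num(r), collapse = " "))
}

parse_meta_line <- function(line) {
  body <- sub("^meta ", "", line)
  eq <- regexpr("=", body, fixed = TRUE)
  key <- substr(body, 1, eq - 1)
  stats::setNames(list(substr(body, eq + 1, nchar(body))), key)
}

#' Write a temperature cube and its surface to a gridded text file
#'
#' Stores `temperature` (degC, dims time,y,x), `urban_fraction`
#' (dimensionless, dims y,x) and `land_class` (integer codes, dims y,x) in
#' one self-describing file; see [gridtext].
#'
#' @param cube a `temp_cube`.
#' @param surface the `urban_surface`; defaults to the cube's. Must share the
#'   cube's grid dimensions.
#' @param path output file path.
#' @return Invisibly, a handle: list with `path`, `dims`, `variable_names`,
#'   `time_encoding`.
#' @export
write_cube <- function(cube, surface = cube$surface, path) {
  stopifnot(inherits(cube, "temp_cube"), inherits(surface, "urban_surface"))
  if (dim(cube$values)[2] != surface$n_y || dim(cube$values)[3] != surface$n_x)
    stop("cube and surface grid dimensions differ", call. = FALSE)
  n_t <- dim(cube$values)[1]
  t0 <- format(cube$timestamps[1], "%Y-%m-%d %H:%M", tz = "UTC")
  codes <- paste(sprintf("%d:%s", land_class_codes, names(land_class_codes)),
                 collapse = ",")
  lines <- c(
    "gridtext 1",
    sprintf("meta n_y=%d n_x=%d cell_size_km=%s", surface$n_y, surface$n_x,
            fmt_num(surface$cell_size)),
    sprintf("meta time_units=hours since %s local", t0),
    sprintf("meta land_class_codes=%s", codes),
    sprintf("var temperature dims=time,y,x units=degC n_t=%d", n_t),
    vapply(seq_len(n_t), function(t)
      paste(fmt_num(as.vector(t(cube$values[t, , ]))), collapse = " "), ""),
    "var urban_fraction dims=y,x units=1",
    fmt_matrix(surface$urban_fraction),
    "var land_class dims=y,x units=code",
    fmt_matrix(matrix(land_class_codes[surface$land_class],
                      surface$n_y, surface$n_x))
  )
  con <- file(path, open = "wb")  # binary mode: LF-only, byte-stable output
  on.exit(close(con))
  writeLines(lines, con, sep = "\n")
  invisible(list(path = path,
                 dims = c(time = n_t, y = surface$n_y, x = surface$n_x),
                 variable_names = c("temperature", "urban_fraction", "land_class"),
                 time_encoding = sprintf("hours since %s local", t0)))
}

read_gridtext <- function(path) {
  if (!file.exists(path))
    stop("gridded file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  if (length(lines) == 0 || lines[1] != "gridtext 1")
    stop("schema error: not a gridtext v1 file: ", path, call. = FALSE)
  meta <- list()
  i <- 2
  while (i <= length(lines) && startsWith(lines[i], "meta ")) {
    # first meta line holds several key=val tokens; the rest one each
    if (grepl("^meta n_y=", lines[i])) {
      toks <- strsplit(sub("^meta ", "", lines[i]), " ", fixed = TRUE)[[1]]
      for (tk in toks) {
        kv <- strsplit(tk, "=", fixed = TRUE)[[1]]
        meta[[kv[1]]] <- kv[2]
      }
    } else meta <- c(meta, parse_meta_line(lines[i]))
    i <- i + 1
  }
  for (k in c("n_y", "n_x"))
    if (is.null(meta[[k]]))
      stop("schema error: missing meta field '", k, "'", call. = FALSE)
  n_y <- as.integer(meta$n_y); n_x <- as.integer(meta$n_x)
  vars <- list()
  while (i <= length(lines)) {
    if (!startsWith(lines[i], "var "))
      stop("schema error: expected a 'var' header at line ", i, call. = FALSE)
    toks <- strsplit(sub("^var ", "", lines[i]), " ", fixed = TRUE)[[1]]
    vname <- toks[1]
    attrs <- list()
    for (tk in toks[-1]) {
      kv <- strsplit(tk, "=", fixed = TRUE)[[1]]
      attrs[[kv[1]]] <- kv[2]
    }
    if (is.null(attrs$units))
      stop("validation error: variable '", vname, "' has no units attribute",
           call. = FALSE)
    if (is.null(attrs$dims))
      stop("schema error: variable '", vname, "' has no dims attribute",
           call. = FALSE)
    i <- i + 1
    if (attrs$dims == "time,y,x") {
      n_t <- as.integer(attrs$n_t)
      if (is.na(n_t)) stop("schema error: cube variable without n_t", call. = FALSE)
      vals <- array(NA_real_, dim = c(n_t, n_y, n_x))
      for (t in seq_len(n_t)) {
        row <- scan(text = lines[i], what = double(), quiet = TRUE,
                    na.strings = "NA")
        if (length(row) != n_y * n_x)
          stop("schema error: time step ", t, " of '", vname, "' has ",
               length(row), " values, expected ", n_y * n_x, call. = FALSE)
        vals[t, , ] <- matrix(row, n_y, n_x, byrow = TRUE)
        i <- i + 1
      }
    } else if (attrs$dims == "y,x") {
      vals <- matrix(NA_real_, n_y, n_x)
      for (r in seq_len(n_y)) {
        row <- scan(text = lines[i], what = double(), quiet = TRUE,
                    na.strings = "NA")
        if (length(row) != n_x)
          stop("schema error: row ", r, " of '", vname, "' has ",
               length(row), " values, expected ", n_x, call. = FALSE)
        vals[r, ] <- row
        i <- i + 1
      }
    } else {
      stop("schema error: variable '", vname, "' has dims '", attrs$dims,
           "'; only 'time,y,x' and 'y,x' are valid", call. = FALSE)
    }
    vars[[vname]] <- list(values = vals, attrs = attrs)
  }
  list(meta = meta, vars = vars)
}

#' Read a temperature cube and its surface from a gridded text file
#'
#' Inverse of [write_cube()]; re-validates all invariants (dimension order,
#' units attributes, urban fraction in \[0, 1\], zero fraction on water and
#' vegetation, regular hourly time axis). Missing temperature values load as
#' an explicit NA mask and their count is reported.
#'
#' @param path file written by [write_cube()].
#' @return List with elements `cube` (a `temp_cube`) and `surface` (an
#'   `urban_surface`).
#' @export
read_cube <- function(path) {
  g <- read_gridtext(path)
  need <- c("temperature", "urban_fraction", "land_class")
  miss <- setdiff(need, names(g$vars))
  if (length(miss) > 0)
    stop("schema error: missing variable(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (g$vars$temperature$attrs$dims != "time,y,x")
    stop("schema error: temperature must have dims time,y,x", call. = FALSE)
  tu <- g$meta$time_units
  m <- regmatches(tu, regexec("^hours since (\\d{4}-\\d{2}-\\d{2} \\d{2}:\\d{2}) local$", tu))[[1]]
  if (length(m) != 2)
    stop("validation error: unparseable time_units: ", tu, call. = FALSE)
  t0 <- as.POSIXct(m[2], tz = "UTC", format = "%Y-%m-%d %H:%M")

  code_map <- strsplit(strsplit(g$meta$land_class_codes, ",", fixed = TRUE)[[1]],
                       ":", fixed = TRUE)
  code_names <- vapply(code_map, `[`, "", 2)
  names(code_names) <- vapply(code_map, `[`, "", 1)
  lc_codes <- g$vars$land_class$values
  if (any(!(as.vector(lc_codes) %in% as.integer(names(code_names)))))
    stop("validation error: land_class contains codes outside the code table",
         call. = FALSE)
  land_class <- matrix(code_names[as.character(as.vector(lc_codes))],
                       nrow(lc_codes), ncol(lc_codes))

  frac <- g$vars$urban_fraction$values
  if (any(frac < 0 | frac > 1, na.rm = TRUE))
    stop("validation error: urban_fraction outside [0, 1]", call. = FALSE)
  surface <- urban_surface(frac, land_class,
                           cell_size = as.numeric(g$meta$cell_size_km %||% 1))

  vals <- g$vars$temperature$values
  n_missing <- sum(is.na(vals))
  if (n_missing > 0)
    message("read_cube: ", n_missing, " masked (NA) temperature value(s)")
  ts <- t0 + 3600 * (seq_len(dim(vals)[1]) - 1)
  list(cube = temp_cube(vals, ts, surface), surface = surface)
}

#' Write / read a daily climatology to a gridded text file
#'
#' Same container as [write_cube()] with a `daily_<variant>` cube variable
#' encoded as `days since` the (nominal) first baseline day, plus `n_years`
#' and `days_per_year` metadata.
#'
#' @param climatology a `climatology`.
#' @param path file path.
#' @return `write_climatology()` invisibly returns the path;
#'   `read_climatology()` returns a `climatology`.
#' @export
write_climatology <- function(climatology, path) {
  vals <- climatology$values
  n_d <- dim(vals)[1]; n_y <- dim(vals)[2]; n_x <- dim(vals)[3]
  lines <- c(
    "gridtext 1",
    sprintf("meta n_y=%d n_x=%d cell_size_km=1", n_y, n_x),
    sprintf("meta time_units=days since baseline local"),
    sprintf("meta land_class_codes=%s",
            paste(sprintf("%d:%s", land_class_codes, names(land_class_codes)),
                  collapse = ",")),
    sprintf("meta variant=%s", climatology$variant),
    sprintf("meta n_years=%d", climatology$n_years),
    sprintf("meta days_per_year=%d", climatology$days_per_year),
    sprintf("var daily_%s dims=time,y,x units=degC n_t=%d",
            tolower(climatology$variant), n_d),
    vapply(seq_len(n_d), function(t)
      paste(fmt_num(as.vector(t(vals[t, , ]))), collapse = " "), "")
  )
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n")
  invisible(path)
}

#' @rdname write_climatology
#' @export
read_climatology <- function(path) {
  g <- read_gridtext(path)
  variant <- g$meta$variant
  vn <- paste0("daily_", tolower(variant))
  if (is.null(g$vars[[vn]]))
    stop("schema error: missing variable '", vn, "'", call. = FALSE)
  structure(list(variant = variant, values = g$vars[[vn]]$values,
                 n_years = as.integer(g$meta$n_years),
                 days_per_year = as.integer(g$meta$days_per_year)),
            class = "climatology")
}

#' Write an EHF field to a gridded text file
#'
#' Static variables `ehi_sig`, `ehi_accl` (degC), `ehf` (degC2) and
#' `severity` (coded 0 = none, 1 = positive, 2 = high, NA on masked cells).
#'
#' @param field an `ehf_field`.
#' @param path file path.
#' @return Invisibly, the path.
#' @export
write_ehf_field <- function(field, path) {
  sev_codes <- c(none = 0, positive = 1, high = 2)
  sev <- matrix(sev_codes[field$severity], nrow(field$ehf), ncol(field$ehf))
  lines <- c(
    "gridtext 1",
    sprintf("meta n_y=%d n_x=%d cell_size_km=1", nrow(field$ehf), ncol(field$ehf)),
    sprintf("meta variant=%s", field$variant),
    sprintf("meta high_threshold=%s", fmt_num(field$high_threshold)),
    "meta severity_codes=0:none,1:positive,2:high",
    "var ehi_sig dims=y,x units=degC", fmt_matrix(field$ehi_sig),
    "var ehi_accl dims=y,x units=degC", fmt_matrix(field$ehi_accl),
    "var ehf dims=y,x units=degC2", fmt_matrix(field$ehf),
    "var severity dims=y,x units=code", fmt_matrix(sev)
  )
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n")
  invisible(path)
}
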