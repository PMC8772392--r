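#' Write / read station series as CSV
#'
#' Fixed dialect: comma-separated, header required, UTF-8, '.' decimal.
#' Columns: `station_id`, `time` (ISO-8601 local, `YYYY-MM-DDTHH:MM:SS`),
#' `temperature_C`, `row`, `col` (0-based fractional grid coordinates).
#' On read, rows are sorted by time within station; duplicate
#' `(station, time)` rows and unparseable times are rejected with the
#' offending record named.
#'
#' @param stations list of `station_series`.
#' @param path CSV file path.
#' @return `write_station_csv()` invisibly returns the path;
#'   `read_station_csv()` returns a list of `station_series`.
#' @export
write_station_csv <- function(stations, path) {
  rows <- do.call(rbind, lapply(stations, function(st)
    data.frame(station_id = st$station_id,
               time = format(st$time, "%Y-%m-%dT%H:%M:%S", tz = "UTC"),
               temperature_C = fmt_num(st$obs),
               row = fmt_num(st$location[1]),
               col = fmt_num(st$location[2]))))
  con <- file(path, open = "wb")
  on.exit(close(con))
  utils::write.csv(rows, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_station_csv
#' @export
read_station_csv <- function(path) {
  if (!file.exists(path))
    stop("station CSV not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(station_id = "character",
                                       time = "character"))
  need <- c("station_id", "time", "temperature_C", "row", "col")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0)
    stop("station CSV missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  ts <- as.POSIXct(df$time, tz = "UTC", format = "%Y-%m-%dT%H:%M:%S")
  bad <- which(is.na(ts) & !is.na(df$time))
  if (length(bad) > 0)
    stop("unparseable time at data row ", bad[1], ": '", df$time[bad[1]], "'",
         call. = FALSE)
  key <- paste(df$station_id, df$time)
  if (anyDuplicated(key)) {
    d <- key[duplicated(key)][1]
    stop("duplicate (station, time) row: ", d, call. = FALSE)
  }
  lapply(split(seq_len(nrow(df)), df$station_id), function(idx) {
    idx <- idx[order(ts[idx])]
    loc <- c(row = df$row[idx[1]], col = df$col[idx[1]])
    structure(list(station_id = df$station_id[idx[1]],
                   location = loc,
                   cell = c(row = as.integer(round(loc[1])),
                            col = as.integer(round(loc[2]))),
                   time = ts[idx],
                   obs = df$temperature_C[idx]),
              class = "station_series")
  })
}
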