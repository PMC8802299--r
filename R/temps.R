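#' Hourly ambient temperature series
#'
#' Container for a contiguous hourly air-temperature record, the substrate of
#' all chill and heat accumulation models in this package. Timestamps must be
#' strictly increasing on an exact one-hour grid and every hour must carry a
#' finite temperature; [fill_temperature_gaps()] can close short gaps by
#' linear interpolation before construction.
#'
#' All timestamps are treated as timezone-naive local time and stored as
#' POSIXct in UTC; calendar-day operations ([mean_daily_temperature()],
#' [windowed_chill_sum()]) derive the day from the UTC clock face.
#'
#' @param timestamps `POSIXct` vector (or something coercible via
#'   [as.POSIXct()] with `tz = "UTC"`), one instant per hour.
#' @param temp_c numeric vector of air temperatures in degrees Celsius, same
#'   length as `timestamps`.
#' @return A `data.frame` of class `hourly_temps` with columns `timestamp`
#'   and `temp_c`.
#' @examples
#' ts <- seq(as.POSIXct("2017-11-01 00:00", tz = "UTC"), by = "hour",
#'           length.out = 48)
#' ht <- hourly_temps(ts, rep(c(5, 10), 24))
#' @export
hourly_temps <- function(timestamps, temp_c) {
  if (length(timestamps) == 0L)
    stop("empty temperature series: no hourly data supplied", call. = FALSE)
  if (!inherits(timestamps, "POSIXct"))
    timestamps <- as.POSIXct(timestamps, tz = "UTC")
  attr(timestamps, "tzone") <- "UTC"
  temp_c <- as.numeric(temp_c)
  if (length(temp_c) != length(timestamps))
    stop("timestamps and temp_c must have equal length", call. = FALSE)
  if (anyNA(timestamps))
    stop("unparseable timestamp in temperature series", call. = FALSE)
  steps <- diff(as.numeric(timestamps))
  if (length(steps) && any(steps != 3600))
    stop("timestamps must be strictly increasing with a constant 1-hour step; ",
         "use fill_temperature_gaps() to close short gaps", call. = FALSE)
  if (any(!is.finite(temp_c)))
    stop("non-finite temperature value in series", call. = FALSE)
  structure(data.frame(timestamp = timestamps, temp_c = temp_c),
            class = c("hourly_temps", "data.frame"))
}

#' @export
print.hourly_temps <- function(x, ...) {
  cat(sprintf("<hourly_temps> %d hours, %s .. %s, %.1f to %.1f degC\n",
              nrow(x), format(x$timestamp[1]), format(x$timestamp[nrow(x)]),
              min(x$temp_c), max(x$temp_c)))
  invisible(x)
}

#' Close short gaps in an hourly temperature record
#'
#' Missing hours (absent rows or `NA` temperatures) of at most
#' `max_gap_hours` consecutive hours are filled by linear interpolation
#' between the flanking observed temperatures. Longer gaps are an error
#' unless `allow_long_gaps` is set, in which case they too are
#' interpolated and a warning is emitted.
#'
#' @param df data.frame with columns `timestamp` (POSIXct or parseable) and
#'   `temp_c`; rows need not be sorted.
#' @param max_gap_hours largest run of missing hours filled silently
#'   (default 6).
#' @param allow_long_gaps interpolate across longer gaps instead of failing.
#' @return An [hourly_temps] series on the full hourly grid spanning the
#'   observed record.
#' @export
fill_temperature_gaps <- function(df, max_gap_hours = 6, allow_long_gaps = FALSE) {
  stopifnot(is.data.frame(df), all(c("timestamp", "temp_c") %in% names(df)))
  ts <- df$timestamp
  if (!inherits(ts, "POSIXct")) ts <- as.POSIXct(ts, tz = "UTC")
  attr(ts, "tzone") <- "UTC"
  ord <- order(ts)
  ts <- ts[ord]
  temp <- as.numeric(df$temp_c)[ord]
  if (anyDuplicated(as.numeric(ts)))
    stop("duplicate timestamp in temperature record: ",
         format(ts[duplicated(as.numeric(ts))][1]), call. = FALSE)
  keep <- is.finite(temp)
  if (!any(keep)) stop("no finite temperatures in record", call. = FALSE)
  grid <- seq(ts[min(which(keep))], ts[max(which(keep))], by = 3600)
  obs_num <- as.numeric(ts[keep])
  filled <- stats::approx(obs_num, temp[keep], xout = as.numeric(grid),
                          method = "linear", rule = 1)$y
  # locate runs of interpolated hours and enforce the gap policy
  is_obs <- as.numeric(grid) %in% obs_num
  if (!all(is_obs)) {
    r <- rle(!is_obs)
    long <- r$lengths[r$values] > max_gap_hours
    if (any(long)) {
      msg <- sprintf("temperature record has %d gap(s) longer than %d hours",
                     sum(long), max_gap_hours)
      if (!allow_long_gaps) stop(msg, call. = FALSE)
      warning(msg, "; interpolated anyway", call. = FALSE)
    }
  }
  hourly_temps(grid, filled)
}

#' Read an hourly temperature CSV
#'
#' Expects a header `timestamp,temp_c` with ISO-8601 timestamps, one row per
#' hour. Rows are sorted, duplicate hours are an error, and gaps are closed
#' under the policy of [fill_temperature_gaps()].
#'
#' @param path CSV file path.
#' @inheritParams fill_temperature_gaps
#' @return An [hourly_temps] series.
#' @export
read_temperature_csv <- function(path, max_gap_hours = 6, allow_long_gaps = FALSE) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("timestamp", "temp_c") %in% names(df)))
    stop("temperature CSV must have header 'timestamp,temp_c': ", path,
         call. = FALSE)
  ts <- parse_iso_instants(df$timestamp)
  if (anyNA(ts)) {
    bad <- which(is.na(ts))[1]
    stop(sprintf("unparseable timestamp at line %d of %s: '%s'",
                 bad + 1L, path, df$timestamp[bad]), call. = FALSE)
  }
  df$timestamp <- ts
  fill_temperature_gaps(df, max_gap_hours = max_gap_hours,
                        allow_long_gaps = allow_long_gaps)
}

#' Write an hourly temperature series as CSV
#'
#' Inverse of [read_temperature_csv()]: ISO-8601 timestamps, header
#' `timestamp,temp_c`.
#'
#' @param series an [hourly_temps] series.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_temperature_csv <- function(series, path) {
  stopifnot(inherits(series, "hourly_temps"))
  out <- data.frame(
    timestamp = format(series$timestamp, "%Y-%m-%dT%H:%M:%S", tz = "UTC"),
    temp_c = series$temp_c)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# lenient ISO-8601 parsing; unparseable entries become NA instead of errors
parse_iso_instants <- function(x) {
  fmts <- c("%Y-%m-%dT%H:%M:%S", "%Y-%m-%d %H:%M:%S",
            "%Y-%m-%dT%H:%M", "%Y-%m-%d %H:%M")
  out <- as.POSIXct(rep(NA_real_, length(x)), origin = "1970-01-01",
                    tz = "UTC")
  for (fmt in fmts) {
    idx <- which(is.na(out))
    if (!length(idx)) break
    out[idx] <- as.POSIXct(strptime(x[idx], fmt, tz = "UTC"))
  }
  out
}

# last hour of a calendar day (the 23:00 instant), the (start, end] anchor
# used everywhere dates bound an accumulation interval
day_end <- function(date) {
  as.POSIXct(paste(format(as.Date(date)), "23:00:00"), tz = "UTC")
}

day_start <- function(date) {
  as.POSIXct(paste(format(as.Date(date)), "00:00:00"), tz = "UTC")
}

#' Mean daily temperature
#'
#' Arithmetic mean of the hourly temperatures of one calendar day. By
#' default at least `min_hours` of the 24 hours must be present so sparse
#' days are never silently averaged.
#'
#' @param series an [hourly_temps] series.
#' @param date calendar day (`Date` or parseable string).
#' @param min_hours minimum hours required (default 20).
#' @return Mean temperature in degrees Celsius.
#' @export
mean_daily_temperature <- function(series, date, min_hours = 20) {
  stopifnot(inherits(series, "hourly_temps"))
  date <- as.Date(date)
  sel <- as.Date(series$timestamp, tz = "UTC") == date
  n <- sum(sel)
  if (n == 0L)
    stop("day ", format(date), " absent from temperature series", call. = FALSE)
  if (n < min_hours)
    stop(sprintf("only %d of 24 hours present on %s (minimum %d)",
                 n, format(date), min_hours), call. = FALSE)
  mean(series$temp_c[sel])
}
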