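# Clock-time and timestamp helpers. Timestamps are naive local clock time
# carried as POSIXct in UTC so that every day has exactly 288 intervals
# (no DST transitions); files use ISO-8601 "YYYY-MM-DDTHH:MM:SS".

TS_FORMAT <- "%Y-%m-%dT%H:%M:%S"

#' Parse a clock time string to minutes after midnight
#'
#' @param x character like `"08:00"` or `"22:30"`.
#' @return integer minutes in `[0, 1440)`.
#' @keywords internal
parse_clock <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  m <- regmatches(x, regexec("^([0-9]{1,2}):([0-9]{2})$", x))[[1]]
  if (length(m) != 3L)
    stop("invalid clock time '", x, "': expected HH:MM", call. = FALSE)
  mins <- as.integer(m[2]) * 60L + as.integer(m[3])
  if (mins < 0L || mins >= 1440L || as.integer(m[3]) >= 60L)
    stop("invalid clock time '", x, "'", call. = FALSE)
  mins
}

format_ts <- function(t) format(t, TS_FORMAT, tz = "UTC")

# coerce a column read from CSV (fread may pre-parse ISO-8601) to POSIXct UTC
coerce_ts <- function(x) {
  if (inherits(x, "POSIXct"))
    return(as.POSIXct(as.numeric(x), origin = "1970-01-01", tz = "UTC"))
  if (inherits(x, c("Date", "IDate")))
    return(as.POSIXct(as.character(x), tz = "UTC"))
  parse_ts(as.character(x))
}

parse_ts <- function(x) {
  t <- as.POSIXct(x, format = TS_FORMAT, tz = "UTC")
  bad <- which(is.na(t) & !is.na(x))
  if (length(bad))
    stop("unparseable timestamp at row ", bad[1], ": '", x[bad[1]],
         "' (expected ", TS_FORMAT, ")", call. = FALSE)
  t
}

# minutes after local midnight for each timestamp
minute_of_day <- function(t) {
  as.integer(as.numeric(t) %/% 60L %% 1440L)
}

is_grid_aligned <- function(t) {
  as.numeric(t) %% INTERVAL_SEC == 0
}

# TRUE when a minute-of-day lies in the half-open waking window
# [waking_start, waking_end)
in_waking_window <- function(mins, waking_start, waking_end) {
  mins >= waking_start & mins < waking_end
}
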