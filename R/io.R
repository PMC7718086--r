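# Readers and writers for the interval / step / metadata CSV dialects.
# The interval dialect is a declared emulation of thermostat-program
# exports (one 0/1 column per remote sensor), not a parser for real
# vendor archives.

#' Read an interval-level sensor CSV
#'
#' Expects columns `house_id`, `timestamp` (ISO-8601 interval start, aligned
#' to the 5-minute grid) and `sensor_<k>` 0/1 flags. The activation count —
#' the number of distinct sensors that fired in the interval — is derived
#' from the flags. Unknown columns are dropped with a warning; duplicated
#' `(house_id, timestamp)` rows and misaligned timestamps are errors naming
#' the offending row.
#'
#' @param path CSV file path.
#' @return A `data.table` sorted by `(house_id, timestamp)` with the sensor
#'   flag columns plus `activation_count` and a `steps` column (`NA` until
#'   [join_steps()] is applied).
#' @export
read_interval_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  dt <- data.table::fread(path, colClasses = list(character = "house_id"))
  need <- c("house_id", "timestamp")
  miss <- setdiff(need, names(dt))
  if (length(miss))
    stop("interval CSV is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  sensor_cols <- grep("^sensor_", names(dt), value = TRUE)
  if (!length(sensor_cols))
    stop("interval CSV has no sensor_<k> columns", call. = FALSE)
  extra <- setdiff(names(dt), c(need, sensor_cols))
  if (length(extra)) {
    warning("ignoring unknown column(s): ", paste(extra, collapse = ", "),
            call. = FALSE)
    dt[, (extra) := NULL]
  }
  dt[, timestamp := coerce_ts(timestamp)]
  bad <- which(!is_grid_aligned(dt$timestamp))
  if (length(bad))
    stop("timestamp not aligned to the 5-min grid at row ", bad[1], ": ",
         format_ts(dt$timestamp[bad[1]]), call. = FALSE)
  for (cl in sensor_cols) {
    v <- dt[[cl]]
    if (!all(v %in% c(0L, 1L)))
      stop("sensor column '", cl, "' contains values other than 0/1",
           call. = FALSE)
  }
  dup <- duplicated(dt, by = c("house_id", "timestamp"))
  if (any(dup)) {
    i <- which(dup)[1]
    stop("duplicated interval for house ", dt$house_id[i], " at ",
         format_ts(dt$timestamp[i]), call. = FALSE)
  }
  dt[, activation_count := rowSums(.SD), .SDcols = sensor_cols]
  dt[, activation_count := as.integer(activation_count)]
  if (!"steps" %in% names(dt)) dt[, steps := NA_integer_]
  data.table::setkeyv(dt, c("house_id", "timestamp"))
  dt[]
}

#' Read a step-count CSV
#'
#' Expects columns `house_id`, `timestamp` (5-minute aligned) and `steps`
#' (non-negative integers).
#'
#' @param path CSV file path.
#' @return A `data.table` sorted by `(house_id, timestamp)`.
#' @export
read_steps_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  dt <- data.table::fread(path, colClasses = list(character = "house_id"))
  miss <- setdiff(c("house_id", "timestamp", "steps"), names(dt))
  if (length(miss))
    stop("steps CSV is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  dt[, timestamp := coerce_ts(timestamp)]
  bad <- which(!is_grid_aligned(dt$timestamp))
  if (length(bad))
    stop("timestamp not aligned to the 5-min grid at row ", bad[1],
         call. = FALSE)
  if (any(is.na(dt$steps)) || any(dt$steps < 0))
    stop("steps must be non-negative integers", call. = FALSE)
  dt[, steps := as.integer(steps)]
  data.table::setkeyv(dt, c("house_id", "timestamp"))
  dt[]
}

#' Read a ground-truth label CSV
#'
#' Companion to [emit_truth_csv()]: columns `house_id`, `timestamp`,
#' `label`.
#'
#' @param path CSV file path.
#' @return A `data.table` sorted by `(house_id, timestamp)`.
#' @export
read_truth_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  dt <- data.table::fread(path, colClasses = list(character = "house_id"))
  dt[, timestamp := coerce_ts(timestamp)]
  bad <- setdiff(unique(dt$label), BEHAVIOR_LABELS)
  if (length(bad))
    stop("unknown ground-truth label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  data.table::setkeyv(dt, c("house_id", "timestamp"))
  dt[]
}

#' Read and filter a household metadata CSV
#'
#' Expects columns `house_id`, `style`, `floor_area`, `num_floors`,
#' `num_occupants`. Rows with any missing or blank field are dropped (the
#' count of dropped rows is messaged and attached as attribute
#' `n_dropped`); surviving rows are never altered. The occupancy class is
#' derived: exactly one occupant is INDIVIDUAL, more than one HOUSEHOLD —
#' mutually exclusive and exhaustive.
#'
#' @param path CSV file path.
#' @return A `data.table` with the metadata columns plus `occupancy_class`.
#' @export
read_metadata_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  cols <- c("house_id", "style", "floor_area", "num_floors", "num_occupants")
  dt <- data.table::fread(path, colClasses = list(character = c("house_id",
                                                                "style")))
  miss <- setdiff(cols, names(dt))
  if (length(miss))
    stop("metadata CSV is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  incomplete <- Reduce(`|`, lapply(cols, function(cl) {
    v <- dt[[cl]]
    is.na(v) | (is.character(v) & trimws(v) == "")
  }))
  n_dropped <- sum(incomplete)
  if (n_dropped)
    message("dropped ", n_dropped, " metadata row(s) with incomplete fields")
  dt <- dt[!incomplete]
  if (nrow(dt) == 0L)
    stop("no complete metadata rows survive filtering; cannot stratify",
         call. = FALSE)
  if (any(dt$num_occupants < 1L))
    stop("invalid num_occupants (< 1) for house ",
         dt$house_id[which(dt$num_occupants < 1L)[1]], call. = FALSE)
  if (any(dt$num_floors < 1L))
    stop("invalid num_floors (< 1) for house ",
         dt$house_id[which(dt$num_floors < 1L)[1]], call. = FALSE)
  if (anyDuplicated(dt$house_id))
    stop("duplicated house_id in metadata", call. = FALSE)
  dt[, occupancy_class := ifelse(num_occupants == 1L, "INDIVIDUAL",
                                 "HOUSEHOLD")]
  data.table::setattr(dt, "n_dropped", n_dropped)
  dt[]
}

#' Left-join step counts onto interval records
#'
#' Joins on `(house_id, timestamp)`. Intervals without a matching step row
#' keep `steps = NA`; step rows with no matching interval are dropped with a
#' warning giving their count.
#'
#' @param intervals interval table from [read_interval_csv()] or
#'   [generate_household()].
#' @param steps step table from [read_steps_csv()].
#' @return The interval table with its `steps` column filled where matched.
#' @export
join_steps <- function(intervals, steps) {
  intervals <- data.table::as.data.table(intervals)
  steps <- data.table::as.data.table(steps)
  out <- data.table::copy(intervals)
  if (!"steps" %in% names(out)) out[, steps := NA_integer_]
  if (nrow(steps)) {
    key <- c("house_id", "timestamp")
    matched <- steps[intervals, on = key, nomatch = NULL]
    n_orphan <- nrow(steps) - nrow(unique(matched, by = key))
    if (n_orphan > 0)
      warning(n_orphan, " step row(s) have no matching interval",
              call. = FALSE)
    out[steps, on = key, steps := i.steps]
  }
  data.table::setkeyv(out, c("house_id", "timestamp"))
  out[]
}

#' Materialize missing intervals within observed days
#'
#' Gaps in a house's stream (missing 5-minute rows within a calendar day it
#' otherwise reports) are filled with records whose `activation_count` is
#' `NA`; the classifier later labels those EXCLUDED/MISSING rather than
#' imputing them.
#'
#' @param intervals interval table.
#' @return The padded table, sorted by `(house_id, timestamp)`.
#' @export
pad_missing_intervals <- function(intervals) {
  dt <- data.table::as.data.table(intervals)
  grid <- dt[, {
    days <- unique(as.Date(timestamp, tz = "UTC"))
    full <- as.POSIXct(rep(days, each = INTERVALS_PER_DAY), tz = "UTC") +
      INTERVAL_SEC * (seq_len(INTERVALS_PER_DAY) - 1L)
    list(timestamp = full)
  }, by = house_id]
  out <- dt[grid, on = c("house_id", "timestamp")]
  data.table::setkeyv(out, c("house_id", "timestamp"))
  out[]
}
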