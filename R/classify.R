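#' Classify a single 5-minute interval
#'
#' The rule table at the heart of the pipeline. Within the waking window
#' (default 08:00–22:00): an activation count at or above the
#' physical-activity cutoff is PHYSICAL_ACTIVITY; a nonzero count below the
#' cutoff is SEDENTARY (stagnant in-house behavior); a zero count is AWAY —
#' no daytime movement very likely means the occupant is out of the house.
#' Within the sleep window (the complement): zero activation is SLEEP, any
#' movement is DISTURBED_SLEEP. A missing activation count yields
#' EXCLUDED/MISSING. The label depends only on the activation count, the
#' clock time and the configuration.
#'
#' @param record a list or one-row data.frame with at least
#'   `activation_count` and `timestamp` (POSIXct or ISO-8601 string).
#' @param config a [classifier_config()].
#' @return The record as a one-row `data.table` with `label` and
#'   `exclusion_reason` columns added.
#' @examples
#' cfg <- classifier_config()
#' classify_interval(list(activation_count = 3,
#'                        timestamp = "2024-01-01T14:00:00"), cfg)$label
#' @export
classify_interval <- function(record, config) {
  stopifnot(inherits(config, "classifier_config"))
  dt <- data.table::as.data.table(record[c("activation_count", "timestamp")])
  if (!inherits(dt$timestamp, "POSIXct"))
    dt[, timestamp := coerce_ts(timestamp)]
  cnt <- as.integer(dt$activation_count)
  if (is.na(cnt)) {
    dt[, `:=`(label = "EXCLUDED", exclusion_reason = "MISSING")]
  } else {
    dt[, `:=`(label = rule_label(cnt, minute_of_day(timestamp), config),
              exclusion_reason = NA_character_)]
  }
  dt[]
}

# vectorized rule table: (activation_count, minute-of-day, config) -> label
rule_label <- function(count, minute, config) {
  pa_min <- effective_pa_min(config)
  waking <- in_waking_window(minute, config$waking_start, config$waking_end)
  data.table::fifelse(
    waking,
    data.table::fifelse(count >= pa_min, "PHYSICAL_ACTIVITY",
                        data.table::fifelse(count >= 1L, "SEDENTARY",
                                            "AWAY")),
    data.table::fifelse(count == 0L, "SLEEP", "DISTURBED_SLEEP"))
}

ensure_label_cols <- function(dt) {
  if (!"label" %in% names(dt)) dt[, label := NA_character_]
  if (!"exclusion_reason" %in% names(dt))
    dt[, exclusion_reason := NA_character_]
  invisible(dt)
}

#' Exclude step-count outliers
#'
#' Intervals whose step count strictly exceeds the configured threshold
#' (default 100 steps per 5 minutes, e.g. a treadmill workout) are atypical
#' of in-house ambulation and are excluded from analysis. The boundary value
#' itself is retained ("more than" the threshold), intervals without step
#' data are untouched, and the filter is idempotent.
#'
#' @param records interval table (labeled or not).
#' @param config a [classifier_config()].
#' @return The table with outlier intervals relabeled
#'   `EXCLUDED`/`STEP_OUTLIER`.
#' @export
filter_step_outliers <- function(records, config) {
  stopifnot(inherits(config, "classifier_config"))
  dt <- data.table::copy(data.table::as.data.table(records))
  ensure_label_cols(dt)
  if ("steps" %in% names(dt)) {
    hit <- !is.na(dt$steps) & dt$steps > config$outlier_step_threshold &
      (is.na(dt$label) | dt$label != "EXCLUDED")
    dt[hit, `:=`(label = "EXCLUDED", exclusion_reason = "STEP_OUTLIER")]
  }
  dt[]
}

#' Exclude isolated single-sensor noise
#'
#' Real deployments record one-off single-sensor activations caused by
#' moving curtains or passing animals rather than occupant movement. The
#' operational rule here: an interval with exactly one active sensor, whose
#' immediate temporal neighbors (within the same house, 5 minutes before and
#' after) both recorded zero activation, and whose step count — when present
#' — is zero, is relabeled `EXCLUDED`/`NOISE`. Neighbor counts are the
#' original (pre-filter) activation counts, so the pass is deterministic and
#' idempotent; a missing neighbor at the edge of a stream counts as zero.
#' With `noise_filter_enabled = FALSE` the input is returned unchanged.
#'
#' @param records interval table, time-sorted within each house.
#' @param config a [classifier_config()].
#' @return The table with noise intervals relabeled `EXCLUDED`/`NOISE`.
#' @export
filter_noise <- function(records, config) {
  stopifnot(inherits(config, "classifier_config"))
  dt <- data.table::copy(data.table::as.data.table(records))
  ensure_label_cols(dt)
  if (!config$noise_filter_enabled) return(dt[])
  data.table::setorderv(dt, c("house_id", "timestamp"))
  dt[, `:=`(
    prev_cnt = {
      p <- data.table::shift(activation_count, 1L)
      adj <- c(FALSE, diff(as.numeric(timestamp)) == INTERVAL_SEC)
      data.table::fifelse(adj, p, 0L)
    },
    next_cnt = {
      nx <- data.table::shift(activation_count, -1L)
      adj <- c(diff(as.numeric(timestamp)) == INTERVAL_SEC, FALSE)
      data.table::fifelse(adj, nx, 0L)
    }), by = house_id]
  step0 <- if ("steps" %in% names(dt)) is.na(dt$steps) | dt$steps == 0L
           else TRUE
  hit <- !is.na(dt$activation_count) & dt$activation_count == 1L &
    !is.na(dt$prev_cnt) & dt$prev_cnt == 0L &
    !is.na(dt$next_cnt) & dt$next_cnt == 0L & step0 &
    (is.na(dt$label) | dt$label != "EXCLUDED")
  dt[hit, `:=`(label = "EXCLUDED", exclusion_reason = "NOISE")]
  dt[, c("prev_cnt", "next_cnt") := NULL]
  dt[]
}

#' Classify every interval of a sensor stream
#'
#' The full labeling pass: missing intervals become EXCLUDED/MISSING, the
#' noise and step-outlier filters are applied per configuration, every
#' remaining interval gets exactly one of the five behavior labels via
#' [classify_interval()]'s rule table, and zero-activation daytime runs
#' shorter than `away_min_intervals` are folded back into SEDENTARY.
#'
#' @param records interval table with `house_id`, `timestamp`,
#'   `activation_count` and optionally `steps`.
#' @param config a [classifier_config()].
#' @return A `data.table` sorted by `(house_id, timestamp)` with `label`
#'   and `exclusion_reason` columns; every row carries exactly one label,
#'   and `exclusion_reason` is non-`NA` exactly on EXCLUDED rows.
#' @export
classify_intervals <- function(records, config) {
  stopifnot(inherits(config, "classifier_config"))
  dt <- data.table::copy(data.table::as.data.table(records))
  if (!all(c("house_id", "timestamp", "activation_count") %in% names(dt)))
    stop("records need house_id, timestamp and activation_count columns",
         call. = FALSE)
  if (!inherits(dt$timestamp, "POSIXct"))
    dt[, timestamp := coerce_ts(timestamp)]
  ensure_label_cols(dt)
  data.table::setorderv(dt, c("house_id", "timestamp"))

  dt[is.na(activation_count),
     `:=`(label = "EXCLUDED", exclusion_reason = "MISSING")]
  dt <- filter_noise(dt, config)
  dt <- filter_step_outliers(dt, config)

  open <- is.na(dt$label) | dt$label != "EXCLUDED"
  dt[open, label := rule_label(activation_count, minute_of_day(timestamp),
                               config)]
  dt[open, exclusion_reason := NA_character_]

  if (config$away_min_intervals > 1L) {
    dt[, run := data.table::rleid(house_id, label)]
    dt[, run_len := .N, by = run]
    dt[label == "AWAY" & run_len < config$away_min_intervals,
       label := "SEDENTARY"]
    dt[, c("run", "run_len") := NULL]
  }
  data.table::setkeyv(dt, c("house_id", "timestamp"))
  dt[]
}

#' Count sleep interruptions in one house-day
#'
#' An interruption is any movement within the sleeping hours; consecutive
#' disturbed intervals form a single interruption. Counts the maximal runs
#' of temporally adjacent `DISTURBED_SLEEP` intervals among the supplied
#' labeled intervals.
#'
#' @param labeled_day labeled intervals of one house-day (time-sorted or
#'   not; they are sorted internally).
#' @return Integer number of interruptions.
#' @examples
#' # S,S,D,D,S,D,S -> two interruptions
#' @export
count_interruptions <- function(labeled_day) {
  dt <- data.table::as.data.table(labeled_day)
  data.table::setorderv(dt, "timestamp")
  idx <- which(dt$label == "DISTURBED_SLEEP")
  if (!length(idx)) return(0L)
  t <- as.numeric(dt$timestamp[idx])
  1L + sum(diff(t) != INTERVAL_SEC)
}
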