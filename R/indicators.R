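#' Compute per-day behavior indicators
#'
#' Aggregates labeled intervals into one row per house-day: nighttime sleep,
#' disturbed sleep, sedentary time and away period in hours, in-house
#' physical activity in minutes, excluded time in hours, and the number of
#' sleep interruptions. Each indicator is simply (number of intervals with
#' that label) x 5 minutes, so the six duration components always partition
#' the 24-hour day exactly.
#'
#' @param labeled labeled interval table from [classify_intervals()]; every
#'   house-day must contain its full 288 intervals (pad gaps first with
#'   [pad_missing_intervals()], which routes them to EXCLUDED/MISSING).
#' @return A `data.table` with columns `house_id`, `date`, `sleep_h`,
#'   `disturbed_sleep_h`, `sedentary_h`, `away_h`, `pa_min`, `excluded_h`,
#'   `n_interruptions`.
#' @export
compute_daily_indicators <- function(labeled) {
  dt <- data.table::as.data.table(labeled)
  stopifnot(all(c("house_id", "timestamp", "label") %in% names(dt)))
  dt <- data.table::copy(dt)
  dt[, date := as.Date(timestamp, tz = "UTC")]
  sizes <- dt[, .N, by = .(house_id, date)]
  bad <- sizes[N != INTERVALS_PER_DAY]
  if (nrow(bad))
    stop("house ", bad$house_id[1], " day ", bad$date[1], " has ",
         bad$N[1], " intervals, expected ", INTERVALS_PER_DAY,
         " (pad gaps with pad_missing_intervals)", call. = FALSE)
  h <- function(n) n * 5 / 60
  out <- dt[, .(
    sleep_h = h(sum(label == "SLEEP")),
    disturbed_sleep_h = h(sum(label == "DISTURBED_SLEEP")),
    sedentary_h = h(sum(label == "SEDENTARY")),
    away_h = h(sum(label == "AWAY")),
    pa_min = sum(label == "PHYSICAL_ACTIVITY") * 5,
    excluded_h = h(sum(label == "EXCLUDED")),
    n_interruptions = count_interruptions(.SD)
  ), by = .(house_id, date)]
  data.table::setkeyv(out, c("house_id", "date"))
  out[]
}

#' Stratified indicator summary with PASS reference deltas
#'
#' Averages the per-day indicators within the INDIVIDUAL (single-occupant)
#' and HOUSEHOLD (multi-occupant) strata, plus ALL, and reports the
#' difference of each mean from the fixed national PASS reference values
#' ([PASS_REFERENCE]: sleep 7.2 h, physical activity 24.1 min/day, sedentary
#' 9.6 h). The references are reporting-only constants; they enter no
#' computation.
#'
#' The averaging scheme is explicit: `"house_day"` (default) pools all
#' house-days; `"house"` averages within each house first, then across
#' houses. Houses absent from the metadata are excluded with a warning.
#'
#' @param daily per-day indicator table from [compute_daily_indicators()].
#' @param metadata household metadata from [read_metadata_csv()] (or any
#'   table with `house_id` and `occupancy_class`).
#' @param weighting `"house_day"` or `"house"`.
#' @return A `data.table` of class `indicator_summary`: one row per stratum
#'   with indicator means, `n_houses`, `n_days`, and
#'   `delta_sleep_h`/`delta_pa_min`/`delta_sedentary_h` against the PASS
#'   references.
#' @export
summarize_indicators <- function(daily, metadata,
                                 weighting = c("house_day", "house")) {
  weighting <- match.arg(weighting)
  daily <- data.table::as.data.table(daily)
  metadata <- data.table::copy(data.table::as.data.table(metadata))
  if (!"occupancy_class" %in% names(metadata)) {
    stopifnot("num_occupants" %in% names(metadata))
    metadata[, occupancy_class := ifelse(num_occupants == 1L, "INDIVIDUAL",
                                         "HOUSEHOLD")]
  }
  unknown <- setdiff(unique(daily$house_id), metadata$house_id)
  if (length(unknown)) {
    warning(length(unknown), " house(s) missing from metadata excluded ",
            "from summary", call. = FALSE)
    daily <- daily[!house_id %in% unknown]
  }
  if (nrow(daily) == 0L)
    stop("no house-days left to summarize", call. = FALSE)
  dd <- metadata[, .(house_id, occupancy_class)][daily, on = "house_id"]

  ind_cols <- c("sleep_h", "disturbed_sleep_h", "sedentary_h", "away_h",
                "pa_min", "excluded_h", "n_interruptions")
  strat_mean <- function(x) {
    base <- if (weighting == "house")
      x[, lapply(.SD, mean), .SDcols = ind_cols, by = house_id]
    else x
    m <- base[, lapply(.SD, mean), .SDcols = ind_cols]
    m[, `:=`(n_houses = data.table::uniqueN(x$house_id), n_days = nrow(x))]
    m
  }
  parts <- list(
    INDIVIDUAL = dd[occupancy_class == "INDIVIDUAL"],
    HOUSEHOLD = dd[occupancy_class == "HOUSEHOLD"],
    ALL = dd)
  rows <- lapply(names(parts), function(s) {
    x <- parts[[s]]
    if (nrow(x) == 0L) return(NULL)
    cbind(data.table::data.table(stratum = s), strat_mean(x))
  })
  out <- data.table::rbindlist(rows)
  out[, `:=`(delta_sleep_h = sleep_h - PASS_REFERENCE[["sleep_h"]],
             delta_pa_min = pa_min - PASS_REFERENCE[["pa_min"]],
             delta_sedentary_h = sedentary_h -
               PASS_REFERENCE[["sedentary_h"]])]
  data.table::setattr(out, "weighting", weighting)
  data.table::setattr(out, "class",
                      c("indicator_summary", class(out)))
  out[]
}

#' Render an indicator summary as a plain-text comparison table
#'
#' One row per indicator, one column per stratum, with the PASS reference
#' values alongside — the layout of a published indicator-comparison table.
#'
#' @param summary an `indicator_summary` from [summarize_indicators()].
#' @return Character vector of report lines.
#' @export
format_indicator_report <- function(summary) {
  s <- data.table::as.data.table(summary)
  get <- function(level, col) {
    v <- s[[col]][s$stratum == level]
    if (length(v)) sprintf("%.2f", v) else "NA"
  }
  rows <- list(
    c("Nighttime sleep, hours", "sleep_h", sprintf("%.1f",
      PASS_REFERENCE[["sleep_h"]])),
    c("Disturbed sleep, hours", "disturbed_sleep_h", "N/A"),
    c("Physical activity in the house, minutes per day", "pa_min",
      sprintf("%.1f", PASS_REFERENCE[["pa_min"]])),
    c("Sedentary time, hours", "sedentary_h", sprintf("%.1f",
      PASS_REFERENCE[["sedentary_h"]])),
    c("Away period, hours", "away_h", "N/A"),
    c("Sleep interruptions, count per night", "n_interruptions", "N/A"))
  hdr <- sprintf("%-48s %12s %12s %8s", "Name of indicator", "Individual",
                 "Household", "PASS")
  body <- vapply(rows, function(r) {
    sprintf("%-48s %12s %12s %8s", r[1], get("INDIVIDUAL", r[2]),
            get("HOUSEHOLD", r[2]), r[3])
  }, character(1))
  c(hdr, strrep("-", nchar(hdr)), body)
}

#' @export
print.indicator_summary <- function(x, ...) {
  cat(format_indicator_report(x), sep = "\n")
  cat("\n(averaging: ", attr(x, "weighting"), "; strata n_houses: ",
      paste(x$stratum, x$n_houses, sep = "=", collapse = ", "), ")\n",
      sep = "")
  invisible(x)
}
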