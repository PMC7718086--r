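#' Construct a daily occupant schedule
#'
#' The schedule is the ground-truth daily routine the simulator replays: a
#' sleep window that wraps midnight, away bouts and physical-activity bouts
#' inside the waking window, and a stride length that converts walked meters
#' to steps. Whatever waking time is not covered by a bout is sedentary, so
#' the four states tile the 24-hour day; overlapping bouts or bouts escaping
#' the waking window are rejected with a diagnostic naming the offender.
#'
#' All clock times must be aligned to the 5-minute interval grid.
#'
#' @param sleep_start,sleep_end clock times `"HH:MM"`; the sleep window is
#'   `[sleep_start, 24:00) + [00:00, sleep_end)` and must wrap midnight
#'   (default 22:00–08:00, the complement of the standard waking window).
#' @param away_bouts list of `c(start, end)` clock-time pairs: out-of-house
#'   periods within the waking window.
#' @param activity_bouts list of `list(start, end, rate)`: in-house
#'   physical-activity periods; `rate` is the number of room-to-room moves
#'   the occupant makes per 5-minute interval (>= 1, so at least two distinct
#'   rooms — hence two sensors — are touched per interval).
#' @param stride_m meters per step; the default 1.56 makes 100 steps
#'   equivalent to 156 m, the walking-distance equivalence used by the
#'   outlier threshold.
#' @return An object of class `occupant_schedule`.
#' @examples
#' sched <- occupant_schedule(
#'   away_bouts = list(c("12:00", "13:00")),
#'   activity_bouts = list(list("09:00", "10:00", 3)))
#' @export
occupant_schedule <- function(sleep_start = "22:00", sleep_end = "08:00",
                              away_bouts = list(), activity_bouts = list(),
                              stride_m = 1.56) {
  ss <- parse_clock(sleep_start)
  se <- parse_clock(sleep_end)
  if (ss %% 5L || se %% 5L)
    stop("sleep window must be aligned to the 5-min grid", call. = FALSE)
  if (ss <= se)
    stop("sleep window must wrap midnight (sleep_start after sleep_end ",
         "on the clock); got ", sleep_start, "-", sleep_end, call. = FALSE)
  stopifnot(is.numeric(stride_m), stride_m > 0)

  parse_bout <- function(b, kind) {
    s <- parse_clock(b[[1]]); e <- parse_clock(b[[2]])
    if (s %% 5L || e %% 5L)
      stop(kind, " bout ", b[[1]], "-", b[[2]],
           " is not aligned to the 5-min grid", call. = FALSE)
    if (e <= s)
      stop(kind, " bout ", b[[1]], "-", b[[2]], " is empty or reversed",
           call. = FALSE)
    if (s < se || e > ss)
      stop(kind, " bout ", b[[1]], "-", b[[2]],
           " lies outside the waking window ", sleep_end, "-", sleep_start,
           call. = FALSE)
    c(start = s, end = e)
  }
  away <- do.call(rbind, lapply(away_bouts, parse_bout, kind = "away"))
  act <- do.call(rbind, lapply(activity_bouts, function(b) {
    rate <- as.numeric(b[[3]])
    if (is.na(rate) || rate < 1)
      stop("activity bout rate must be >= 1 room move per interval",
           call. = FALSE)
    c(parse_bout(b, "activity"), rate = rate)
  }))

  # overlap check over the union of bouts (sedentary time fills the rest)
  bounds <- rbind(if (!is.null(away)) away[, 1:2, drop = FALSE],
                  if (!is.null(act)) act[, 1:2, drop = FALSE])
  if (!is.null(bounds) && nrow(bounds) > 1L) {
    o <- order(bounds[, 1])
    b <- bounds[o, , drop = FALSE]
    bad <- which(b[-nrow(b), 2] > b[-1, 1])
    if (length(bad))
      stop("overlapping bouts: interval ending ",
           sprintf("%02d:%02d", b[bad[1], 2] %/% 60, b[bad[1], 2] %% 60),
           " overlaps bout starting ",
           sprintf("%02d:%02d", b[bad[1] + 1, 1] %/% 60,
                   b[bad[1] + 1, 1] %% 60), call. = FALSE)
  }

  structure(list(sleep_start = ss, sleep_end = se,
                 away_bouts = away, activity_bouts = act,
                 stride_m = as.numeric(stride_m)),
            class = "occupant_schedule")
}

#' @export
print.occupant_schedule <- function(x, ...) {
  hm <- function(m) sprintf("%02d:%02d", m %/% 60, m %% 60)
  cat("<occupant_schedule> sleep ", hm(x$sleep_start), "-", hm(x$sleep_end),
      ", ", if (is.null(x$away_bouts)) 0L else nrow(x$away_bouts),
      " away bout(s), ",
      if (is.null(x$activity_bouts)) 0L else nrow(x$activity_bouts),
      " activity bout(s), stride ", x$stride_m, " m\n", sep = "")
  invisible(x)
}

# per-interval ground-truth state for one day: character vector of length 288
schedule_states <- function(schedule) {
  mins <- seq(0L, 1435L, by = 5L)
  state <- rep("SEDENTARY", INTERVALS_PER_DAY)
  asleep <- mins >= schedule$sleep_start | mins < schedule$sleep_end
  state[asleep] <- "SLEEP"
  rate <- rep(NA_real_, INTERVALS_PER_DAY)
  ab <- schedule$away_bouts
  if (!is.null(ab))
    for (i in seq_len(nrow(ab)))
      state[mins >= ab[i, "start"] & mins < ab[i, "end"]] <- "AWAY"
  acb <- schedule$activity_bouts
  if (!is.null(acb))
    for (i in seq_len(nrow(acb))) {
      sel <- mins >= acb[i, "start"] & mins < acb[i, "end"]
      state[sel] <- "PHYSICAL_ACTIVITY"
      rate[sel] <- acb[i, "rate"]
    }
  list(minute = mins, state = state, rate = rate)
}
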