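#' Simulate one household's sensor, step and ground-truth streams
#'
#' Agent-based generator standing in for proprietary thermostat-program
#' exports. One occupant replays the [occupant_schedule()] on the
#' [floorplan()] day after day; each 5-minute interval is emitted with the
#' per-sensor activation flags, an indoor step count, and the ground-truth
#' behavior state that generated it.
#'
#' Generating rules, per ground-truth state:
#' \describe{
#'   \item{SLEEP}{no sensors fire and steps are 0; with probability
#'     `sleep_interruption_rate` the interval is instead a DISTURBED_SLEEP
#'     movement event — the bedroom sensor fires and a few steps are taken.}
#'   \item{AWAY}{no sensors fire; steps are 0 (step counts are indoor-only).}
#'   \item{SEDENTARY}{the occupied room's sensor fires and steps are a small
#'     Poisson count; rarely (`workout_rate`) the interval is a stationary
#'     workout with one sensor but many steps.}
#'   \item{PHYSICAL_ACTIVITY}{the occupant makes `rate` room-to-room moves
#'     along the floorplan graph, so at least two distinct rooms — hence two
#'     distinct sensors — are touched; steps are Poisson with mean
#'     `moves * room_distance / stride_m`.}
#' }
#' After the state pass, spurious single-sensor activations are injected
#' into zero-activation intervals at `noise_rate`, never in consecutive
#' intervals; ground-truth labels are not altered by noise.
#'
#' The generator is fully deterministic given `config$seed`.
#'
#' @param floorplan a [floorplan()].
#' @param schedule an [occupant_schedule()].
#' @param config a [sim_config()].
#' @param house_id identifier stamped on every emitted row.
#' @return A list with three `data.table`s: `intervals` (`house_id`,
#'   `timestamp`, one 0/1 column per sensor), `steps` (`house_id`,
#'   `timestamp`, `steps`) and `truth` (`house_id`, `timestamp`, `label`).
#' @examples
#' fp <- make_floorplan(6)
#' sched <- occupant_schedule(activity_bouts = list(list("09:00", "10:30", 3)))
#' sim <- generate_household(fp, sched, sim_config(seed = 42, n_days = 2))
#' nrow(sim$intervals)  # 2 days x 288 intervals
#' @export
generate_household <- function(floorplan, schedule, config,
                               house_id = "house_01") {
  stopifnot(inherits(floorplan, "floorplan"),
            inherits(schedule, "occupant_schedule"),
            inherits(config, "sim_config"))
  set.seed(config$seed)

  sensors <- all_sensors(floorplan)
  k <- length(sensors)
  day <- schedule_states(schedule)
  n <- config$n_days * INTERVALS_PER_DAY
  state <- rep(day$state, config$n_days)
  rate <- rep(day$rate, config$n_days)
  t0 <- as.POSIXct(paste0(config$start_date, "T00:00:00"),
                   format = TS_FORMAT, tz = "UTC")
  ts <- t0 + INTERVAL_SEC * (seq_len(n) - 1L)

  flags <- matrix(0L, nrow = n, ncol = k, dimnames = list(NULL, sensors))
  steps <- integer(n)
  truth <- state
  # mean steps for one room-to-room traversal
  trans_mean <- floorplan$room_distance / schedule$stride_m
  room_sensor <- function(room) {
    s <- floorplan$sensors[[room]]
    if (length(s) == 1L) s else sample(s, 1L)
  }

  current_room <- floorplan$rooms[1]
  for (i in seq_len(n)) {
    st <- state[i]
    if (st == "SLEEP") {
      if (runif(1) < config$sleep_interruption_rate) {
        truth[i] <- "DISTURBED_SLEEP"
        flags[i, room_sensor(floorplan$rooms[1])] <- 1L
        steps[i] <- rpois(1, trans_mean)
      }
    } else if (st == "SEDENTARY") {
      flags[i, room_sensor(current_room)] <- 1L
      steps[i] <- if (runif(1) < config$workout_rate)
        rpois(1, config$workout_step_mean)
      else rpois(1, config$sedentary_step_mean)
    } else if (st == "PHYSICAL_ACTIVITY") {
      moves <- max(1L, as.integer(round(rate[i])))
      visited <- current_room
      for (j in seq_len(moves)) {
        nb <- floorplan$neighbors[[current_room]]
        current_room <- if (length(nb) == 1L) nb else sample(nb, 1L)
        visited <- c(visited, current_room)
      }
      for (r in unique(visited)) flags[i, room_sensor(r)] <- 1L
      steps[i] <- rpois(1, moves * trans_mean)
    }
    # AWAY: nothing fires, no indoor steps
  }

  # spurious single-sensor activations, never in consecutive intervals
  if (config$noise_rate > 0) {
    prev_noise <- FALSE
    zero <- rowSums(flags) == 0L
    draws <- runif(n)
    for (i in seq_len(n)) {
      if (zero[i] && !prev_noise && draws[i] < config$noise_rate) {
        flags[i, sample.int(k, 1L)] <- 1L
        prev_noise <- TRUE
      } else prev_noise <- FALSE
    }
  }

  intervals <- data.table::data.table(house_id = house_id, timestamp = ts)
  intervals[, (sensors) := data.table::as.data.table(flags)]
  list(intervals = intervals,
       steps = data.table::data.table(house_id = house_id, timestamp = ts,
                                      steps = steps),
       truth = data.table::data.table(house_id = house_id, timestamp = ts,
                                      label = truth))
}

write_stream_csv <- function(tab, path) {
  out <- data.table::copy(data.table::as.data.table(tab))
  if ("timestamp" %in% names(out) && inherits(out$timestamp, "POSIXct"))
    out[, timestamp := format_ts(timestamp)]
  ok <- tryCatch({
    data.table::fwrite(out, path)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok))
    stop("cannot write '", path, "': ", conditionMessage(ok), call. = FALSE)
  invisible(path)
}

#' Write simulator tables to the CSV dialects
#'
#' `emit_dyd_csv()` writes the interval table (one 0/1 column per sensor),
#' `emit_steps_csv()` the step table, and `emit_truth_csv()` the
#' ground-truth label table. All files are UTF-8, comma-separated, with a
#' header row and ISO-8601 interval-start timestamps; they round-trip
#' losslessly through the package's readers.
#'
#' @param tab the corresponding table from [generate_household()].
#' @param path output file path.
#' @return The path, invisibly.
#' @export
emit_dyd_csv <- function(tab, path) write_stream_csv(tab, path)

#' @rdname emit_dyd_csv
#' @export
emit_steps_csv <- function(tab, path) write_stream_csv(tab, path)

#' @rdname emit_dyd_csv
#' @export
emit_truth_csv <- function(tab, path) write_stream_csv(tab, path)

#' Simulate a pilot-style multi-house cohort
#'
#' Generates `n_houses` single-occupant households with varied floorplans
#' (5–12 rooms) and daily routines (morning/evening activity bouts, a midday
#' away bout on some days' schedules), each wearing a step tracker —
#' mirroring the shape of a validation pilot in which sensor activations are
#' compared against wearable step counts. Per-house seeds are derived from
#' `seed`, so the whole cohort is reproducible.
#'
#' @param n_houses number of households (default 8).
#' @param n_days days per household (default 7).
#' @param seed master RNG seed.
#' @param noise_rate,sleep_interruption_rate,workout_rate passed to
#'   [sim_config()].
#' @param n_occupants integer vector (recycled) of household sizes recorded
#'   in the metadata. Sizes above 1 only affect stratification metadata:
#'   the simulator itself is single-occupant (occupant disambiguation is out
#'   of scope).
#' @return A list of `data.table`s: `intervals`, `steps`, `truth` (stacked
#'   across houses) and `metadata` (house style, floor area, floors,
#'   occupants).
#' @export
simulate_pilot <- function(n_houses = 8L, n_days = 7L, seed = 1L,
                           noise_rate = 0.02, sleep_interruption_rate = 0.2,
                           workout_rate = 0.005, n_occupants = 1L) {
  n_houses <- as.integer(n_houses)
  stopifnot(n_houses >= 1L)
  set.seed(seed)
  house_seeds <- sample.int(.Machine$integer.max %/% 2L, n_houses)
  n_rooms <- sample(5:12, n_houses, replace = TRUE)
  act_rate <- sample(2:4, n_houses, replace = TRUE)
  has_away <- runif(n_houses) < 0.75
  n_occupants <- rep_len(as.integer(n_occupants), n_houses)
  styles <- sample(c("apartment", "townhouse", "detached", "other"),
                   n_houses, replace = TRUE)

  sims <- vector("list", n_houses)
  for (h in seq_len(n_houses)) {
    fp <- make_floorplan(n_rooms[h])
    away <- if (has_away[h]) list(c("12:00", "13:30")) else list()
    sched <- occupant_schedule(
      away_bouts = away,
      activity_bouts = list(list("09:00", "09:45", act_rate[h]),
                            list("17:30", "18:15", act_rate[h])))
    cfg <- sim_config(seed = house_seeds[h], n_days = n_days,
                      noise_rate = noise_rate,
                      sleep_interruption_rate = sleep_interruption_rate,
                      workout_rate = workout_rate)
    sims[[h]] <- generate_household(fp, sched, cfg,
                                    house_id = sprintf("house_%02d", h))
  }
  metadata <- data.table::data.table(
    house_id = sprintf("house_%02d", seq_len(n_houses)),
    style = styles,
    floor_area = n_rooms * 180L,
    num_floors = ifelse(n_rooms > 8L, 2L, 1L),
    num_occupants = n_occupants)
  intervals <- data.table::rbindlist(lapply(sims, `[[`, "intervals"),
                                     fill = TRUE)
  # houses carry different sensor sets; absent sensors never fired
  sensor_cols <- grep("^sensor_", names(intervals), value = TRUE)
  for (cl in sensor_cols)
    data.table::set(intervals, which(is.na(intervals[[cl]])), cl, 0L)
  list(intervals = intervals,
       steps = data.table::rbindlist(lapply(sims, `[[`, "steps")),
       truth = data.table::rbindlist(lapply(sims, `[[`, "truth")),
       metadata = metadata)
}
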