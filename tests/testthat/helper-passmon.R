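# Shared fixture builders. All fixtures are constructed in code; nothing is
# read from disk except files the tests themselves write to tempdir().

library(data.table)

# interval records straight from counts: one house, consecutive 5-min grid
make_records <- function(counts, start = "2024-01-01T00:00:00",
                         house_id = "h1", steps = NULL) {
  t0 <- as.POSIXct(start, format = "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  data.table(house_id = house_id,
             timestamp = t0 + 300 * (seq_along(counts) - 1L),
             activation_count = as.integer(counts),
             steps = if (is.null(steps)) NA_integer_ else as.integer(steps))
}

# a labeled house-day built from named label counts (must sum to 288)
make_labeled_day <- function(label_counts, house_id = "h1",
                             date = "2024-01-01") {
  stopifnot(sum(label_counts) == 288L)
  labels <- rep(names(label_counts), label_counts)
  t0 <- as.POSIXct(paste0(date, " 00:00:00"), tz = "UTC")
  data.table(house_id = house_id, timestamp = t0 + 300 * (0:287),
             activation_count = NA_integer_, steps = NA_integer_,
             label = labels, exclusion_reason = NA_character_)
}

# derive activation_count from the sensor flag columns of a simulator table
add_counts <- function(intervals) {
  dt <- data.table::copy(as.data.table(intervals))
  sensor_cols <- grep("^sensor_", names(dt), value = TRUE)
  dt[, activation_count := as.integer(rowSums(.SD)), .SDcols = sensor_cols]
  dt
}

# a small deterministic household simulation used across tests
quiet_sim <- function(seed = 11L, n_days = 2L, noise_rate = 0,
                      sleep_interruption_rate = 0, workout_rate = 0,
                      activity_bouts = list(list("09:00", "10:00", 3)),
                      away_bouts = list(c("12:00", "13:30"))) {
  fp <- make_floorplan(6)
  sched <- occupant_schedule(away_bouts = away_bouts,
                             activity_bouts = activity_bouts)
  cfg <- sim_config(seed = seed, n_days = n_days, noise_rate = noise_rate,
                    sleep_interruption_rate = sleep_interruption_rate,
                    workout_rate = workout_rate)
  generate_household(fp, sched, cfg)
}

# independent Spearman oracle: ranks computed by explicit counting (no call
# to rank()), then the Pearson formula written out
oracle_spearman <- function(x, y) {
  brute_rank <- function(v) {
    vapply(seq_along(v), function(i) {
      less <- sum(v < v[i])
      eq <- sum(v == v[i])
      less + (eq + 1) / 2
    }, numeric(1))
  }
  rx <- brute_rank(x); ry <- brute_rank(y)
  num <- sum((rx - mean(rx)) * (ry - mean(ry)))
  den <- sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  num / den
}
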