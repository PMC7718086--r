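#' Simulator configuration
#'
#' Controls the stochastic layer of the household simulator. The state
#' sequence itself (sleep, bouts, sedentary fill) is deterministic from the
#' [occupant_schedule()]; this config controls the noise and step processes
#' layered on top. Identical seeds reproduce identical outputs bit for bit.
#'
#' @param seed RNG seed (integer).
#' @param n_days number of simulated days (>= 1).
#' @param noise_rate probability, per zero-activation interval, of a spurious
#'   single-sensor activation (curtains moving, a bird at a window).
#'   Spurious activations are never injected in consecutive intervals.
#' @param sleep_interruption_rate probability, per sleep interval, of a
#'   movement event (getting up at night); such intervals are ground-truth
#'   disturbed sleep. The default 0.2 yields roughly 2 h of disturbed sleep
#'   in a 10 h sleep window, the magnitude seen in thermostat-scale data.
#' @param sedentary_step_mean Poisson mean of steps in a sedentary interval
#'   (fidgeting, walking to the kitchen and back within one room's reach).
#' @param workout_rate probability that a sedentary interval is a stationary
#'   workout (e.g. a treadmill: one sensor, many steps) — the phenomenon the
#'   100-step outlier filter removes.
#' @param workout_step_mean Poisson mean of steps in a workout interval
#'   (default 150, comfortably above the 100-step outlier threshold).
#' @param start_date first simulated calendar date (`"YYYY-MM-DD"`).
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, n_days = 7L, noise_rate = 0.02,
                       sleep_interruption_rate = 0.2,
                       sedentary_step_mean = 1,
                       workout_rate = 0.005, workout_step_mean = 150,
                       start_date = "2024-01-01") {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  n_days <- as.integer(n_days)
  if (is.na(n_days) || n_days < 1L) stop("n_days must be >= 1", call. = FALSE)
  for (p in c(noise_rate, sleep_interruption_rate, workout_rate))
    if (!is.numeric(p) || p < 0 || p > 1)
      stop("rates must be probabilities in [0, 1]", call. = FALSE)
  stopifnot(sedentary_step_mean >= 0, workout_step_mean >= 0)
  if (is.na(as.Date(start_date)))
    stop("start_date must be an ISO date", call. = FALSE)
  structure(list(seed = as.integer(seed), n_days = n_days,
                 noise_rate = noise_rate,
                 sleep_interruption_rate = sleep_interruption_rate,
                 sedentary_step_mean = sedentary_step_mean,
                 workout_rate = workout_rate,
                 workout_step_mean = workout_step_mean,
                 start_date = as.character(start_date)),
            class = "sim_config")
}

#' Classifier configuration
#'
#' All thresholds and time windows of the rule-based interval classifier.
#' The defaults encode the published rules: a waking window of
#' 08:00–22:00 (its complement is the sleep window), physical activity when
#' at least `pa_min_sensors` distinct sensors fire in a 5-minute interval,
#' sedentary when fewer (but at least one) fire, away on zero daytime
#' activation, and a 100-step outlier threshold.
#'
#' The source rules state the physical-activity cutoff both as ">= 2
#' sensors" and, in a three-way variant, as ">= 3 sensors". Both are first
#' class here: `pa_min_sensors` defaults to 2, and `three_way_mode = TRUE`
#' reinterprets the cutoff as 3 so that 1–2 active sensors are sedentary.
#'
#' @param waking_start,waking_end clock times `"HH:MM"` bounding the
#'   half-open waking window; the sleep window is its complement.
#' @param pa_min_sensors minimum distinct active sensors for a waking
#'   interval to count as physical activity (default 2).
#' @param outlier_step_threshold steps per 5-minute interval above which
#'   (strictly) an interval is excluded as an outlier (default 100,
#'   equivalent to 156 m at a 1.56 m stride).
#' @param noise_filter_enabled drop isolated single-sensor blips (default
#'   `TRUE`).
#' @param three_way_mode when `TRUE`, use the three-way variant: >= 3
#'   sensors is physical activity, 1–2 is sedentary.
#' @param away_min_intervals minimum run length (in intervals) of zero
#'   daytime activation to call the occupant away; shorter zero-runs are
#'   labeled sedentary. Default 1: a single 5-minute interval may be away.
#' @return An object of class `classifier_config`.
#' @examples
#' cfg <- classifier_config()
#' cfg3 <- classifier_config(three_way_mode = TRUE)
#' @export
classifier_config <- function(waking_start = "08:00", waking_end = "22:00",
                              pa_min_sensors = 2L,
                              outlier_step_threshold = 100,
                              noise_filter_enabled = TRUE,
                              three_way_mode = FALSE,
                              away_min_intervals = 1L) {
  ws <- parse_clock(waking_start)
  we <- parse_clock(waking_end)
  if (ws >= we)
    stop("waking_start must precede waking_end within one day", call. = FALSE)
  pa_min_sensors <- as.integer(pa_min_sensors)
  if (is.na(pa_min_sensors) || pa_min_sensors < 1L)
    stop("pa_min_sensors must be >= 1", call. = FALSE)
  if (!is.numeric(outlier_step_threshold) || outlier_step_threshold <= 0)
    stop("outlier_step_threshold must be > 0", call. = FALSE)
  away_min_intervals <- as.integer(away_min_intervals)
  if (is.na(away_min_intervals) || away_min_intervals < 1L)
    stop("away_min_intervals must be >= 1", call. = FALSE)
  structure(list(waking_start = ws, waking_end = we,
                 waking_start_str = waking_start,
                 waking_end_str = waking_end,
                 pa_min_sensors = pa_min_sensors,
                 sleep_sensor_count = 0L,  # fixed: sleep means zero sensors
                 outlier_step_threshold = as.numeric(outlier_step_threshold),
                 noise_filter_enabled = isTRUE(noise_filter_enabled),
                 three_way_mode = isTRUE(three_way_mode),
                 away_min_intervals = away_min_intervals),
            class = "classifier_config")
}

# the PA cutoff actually applied (three-way variant reads it as 3)
effective_pa_min <- function(config) {
  if (config$three_way_mode) 3L else config$pa_min_sensors
}

#' @export
print.classifier_config <- function(x, ...) {
  cat("<classifier_config> waking ", x$waking_start_str, "-",
      x$waking_end_str, ", PA >= ", effective_pa_min(x), " sensors",
      if (x$three_way_mode) " (three-way mode)", ", outlier > ",
      x$outlier_step_threshold, " steps, noise filter ",
      if (x$noise_filter_enabled) "on" else "off", "\n", sep = "")
  invisible(x)
}

#' Read a classifier configuration from a JSON file
#'
#' The JSON keys mirror the [classifier_config()] arguments; absent keys keep
#' their defaults.
#'
#' @param path JSON file path.
#' @return A `classifier_config`.
#' @export
read_classifier_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  allowed <- names(formals(classifier_config))
  unknown <- setdiff(names(raw), allowed)
  if (length(unknown))
    warning("ignoring unknown config keys: ",
            paste(unknown, collapse = ", "), call. = FALSE)
  do.call(classifier_config, raw[intersect(names(raw), allowed)])
}
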