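cfg <- classifier_config()

one <- function(count, clock, config = cfg) {
  classify_interval(list(activation_count = count,
                         timestamp = paste0("2024-01-01T", clock, ":00")),
                    config)$label
}

test_that("single-interval rule table covers the five states", {
  expect_identical(one(3, "14:00"), "PHYSICAL_ACTIVITY")
  expect_identical(one(2, "14:00"), "PHYSICAL_ACTIVITY")  # default cutoff 2
  expect_identical(one(1, "14:00"), "SEDENTARY")
  expect_identical(one(0, "14:00"), "AWAY")
  expect_identical(one(0, "03:00"), "SLEEP")
  expect_identical(one(1, "03:00"), "DISTURBED_SLEEP")

  # waking-window boundaries are half-open [08:00, 22:00)
  expect_identical(one(0, "08:00"), "AWAY")
  expect_identical(one(0, "07:55"), "SLEEP")
  expect_identical(one(0, "22:00"), "SLEEP")
  expect_identical(one(0, "21:55"), "AWAY")
})

test_that("three-way mode reinterprets the cutoff as 3 sensors", {
  cfg3 <- classifier_config(three_way_mode = TRUE)
  expect_identical(one(3, "14:00", cfg3), "PHYSICAL_ACTIVITY")
  expect_identical(one(2, "14:00", cfg3), "SEDENTARY")
  expect_identical(one(1, "14:00", cfg3), "SEDENTARY")
  # sleep-window rules unchanged
  expect_identical(one(1, "03:00", cfg3), "DISTURBED_SLEEP")
})

test_that("missing activation count yields EXCLUDED/MISSING", {
  r <- classify_interval(list(activation_count = NA_integer_,
                              timestamp = "2024-01-01T14:00:00"), cfg)
  expect_identical(r$label, "EXCLUDED")
  expect_identical(r$exclusion_reason, "MISSING")
})

test_that("step-outlier filter excludes strictly above the threshold", {
  rec <- make_records(c(2, 2, 2, 2), start = "2024-01-01T10:00:00",
                      steps = c(150L, 100L, 101L, NA))
  out <- filter_step_outliers(rec, cfg)
  expect_identical(out$label,
                   c("EXCLUDED", NA, "EXCLUDED", NA))
  expect_identical(out$exclusion_reason,
                   c("STEP_OUTLIER", NA, "STEP_OUTLIER", NA))
  # idempotent
  expect_identical(as.data.frame(filter_step_outliers(out, cfg)),
                   as.data.frame(out))
  # configurable threshold
  out2 <- filter_step_outliers(rec, classifier_config(
    outlier_step_threshold = 200))
  expect_true(all(is.na(out2$label)))
})

test_that("noise filter removes isolated zero-step single activations", {
  # pattern (0,1,0) with steps 0 in the middle: middle excluded as noise
  rec <- make_records(c(0, 1, 0), start = "2024-01-01T10:00:00",
                      steps = c(0L, 0L, 0L))
  out <- filter_noise(rec, cfg)
  expect_identical(out$exclusion_reason, c(NA, "NOISE", NA))

  # pattern (0,1,1): not isolated, nothing excluded
  rec2 <- make_records(c(0, 1, 1), steps = c(0L, 0L, 0L))
  expect_true(all(is.na(filter_noise(rec2, cfg)$label)))

  # steps present and nonzero: genuine movement, retained
  rec3 <- make_records(c(0, 1, 0), steps = c(0L, 6L, 0L))
  expect_true(all(is.na(filter_noise(rec3, cfg)$label)))

  # absent step data still qualifies
  rec4 <- make_records(c(0, 1, 0))
  expect_identical(filter_noise(rec4, cfg)$exclusion_reason[2], "NOISE")

  # disabled mode is identity
  off <- classifier_config(noise_filter_enabled = FALSE)
  expect_identical(as.data.frame(filter_noise(rec, off)[, 1:4]),
                   as.data.frame(rec))

  # evaluated against original neighbor counts: both blips in (0,1,0,1,0) go
  rec5 <- make_records(c(0, 1, 0, 1, 0), steps = rep(0L, 5))
  out5 <- filter_noise(rec5, cfg)
  expect_identical(which(out5$exclusion_reason == "NOISE"), c(2L, 4L))

  # idempotent
  expect_identical(as.data.frame(filter_noise(out, cfg)),
                   as.data.frame(out))

  # neighbors in a different house do not count
  rec6 <- rbind(make_records(c(0, 1), house_id = "a", steps = c(0L, 0L)),
                make_records(c(0, 0), house_id = "b", steps = c(0L, 0L)))
  out6 <- filter_noise(rec6, cfg)
  expect_identical(out6[house_id == "a" & activation_count == 1L,
                        exclusion_reason], "NOISE")
})

test_that("count_interruptions merges consecutive disturbed intervals", {
  night <- function(labels) {
    t0 <- as.POSIXct("2024-01-01 23:00:00", tz = "UTC")
    data.table(house_id = "h1", timestamp = t0 + 300 * (seq_along(labels) - 1),
               label = c(S = "SLEEP", D = "DISTURBED_SLEEP")[labels])
  }
  expect_identical(count_interruptions(night(rep("S", 12))), 0L)
  expect_identical(count_interruptions(night(c("S", "S", "D", "D", "S",
                                               "D", "S"))), 2L)
  expect_identical(count_interruptions(night(rep("D", 12))), 1L)
  # non-adjacent disturbances separated by a gap are distinct interruptions
  gap <- night(c("D", "D"))
  gap$timestamp[2] <- gap$timestamp[2] + 3600
  expect_identical(count_interruptions(gap), 2L)
})

test_that("classify_intervals assigns exactly one label everywhere", {
  sim <- quiet_sim(seed = 31L, noise_rate = 0.05,
                   sleep_interruption_rate = 0.2, workout_rate = 0.01)
  rec <- join_steps(add_counts(sim$intervals), sim$steps)
  lab <- classify_intervals(rec, cfg)
  expect_identical(nrow(lab), nrow(rec))
  expect_true(all(lab$label %in% BEHAVIOR_LABELS))
  expect_false(any(is.na(lab$label)))
  # exclusion_reason present iff EXCLUDED
  expect_identical(is.na(lab$exclusion_reason), lab$label != "EXCLUDED")
})

test_that("raising the PA cutoff never increases physical-activity intervals", {
  sim <- quiet_sim(seed = 13L, noise_rate = 0.03,
                   sleep_interruption_rate = 0.2,
                   activity_bouts = list(list("09:00", "10:00", 2),
                                         list("15:00", "16:30", 4)))
  rec <- join_steps(add_counts(sim$intervals), sim$steps)
  pa_counts <- vapply(1:6, function(k) {
    lab <- classify_intervals(rec, classifier_config(pa_min_sensors = k))
    sum(lab$label == "PHYSICAL_ACTIVITY")
  }, integer(1))
  expect_true(all(diff(pa_counts) <= 0))
  # three-way mode equals an explicit cutoff of 3
  lab3 <- classify_intervals(rec, classifier_config(three_way_mode = TRUE))
  labk3 <- classify_intervals(rec, classifier_config(pa_min_sensors = 3))
  expect_identical(lab3$label, labk3$label)
})

test_that("away_min_intervals folds short zero-runs into sedentary", {
  rec <- make_records(c(1, 0, 1, 0, 0, 0, 1), start = "2024-01-01T10:00:00")
  lab1 <- classify_intervals(rec, classifier_config(
    noise_filter_enabled = FALSE))
  expect_identical(sum(lab1$label == "AWAY"), 4L)
  lab3 <- classify_intervals(rec, classifier_config(
    noise_filter_enabled = FALSE, away_min_intervals = 3))
  expect_identical(sum(lab3$label == "AWAY"), 3L)
  expect_identical(lab3$label[2], "SEDENTARY")
})

test_that("predicted labels recover ground truth away from bout boundaries", {
  sim <- quiet_sim(seed = 41L, n_days = 3, noise_rate = 0,
                   sleep_interruption_rate = 0)
  rec <- join_steps(add_counts(sim$intervals), sim$steps)
  lab <- classify_intervals(rec, cfg)
  truth <- sim$truth[lab, on = c("house_id", "timestamp")]
  keep <- lab$label != "EXCLUDED"
  expect_true(all(lab$label[keep] == truth$label[keep]))
})
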