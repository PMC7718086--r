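test_that("daily indicators are interval counts times five minutes", {
  # degenerate: an all-sleep day
  day <- make_labeled_day(c(SLEEP = 288L))
  ind <- compute_daily_indicators(day)
  expect_equal(ind$sleep_h, 24)
  expect_equal(ind$disturbed_sleep_h + ind$sedentary_h + ind$away_h +
                 ind$pa_min + ind$excluded_h, 0)

  # oracle: hand tally of a scheduled day
  day2 <- make_labeled_day(c(SLEEP = 96L, DISTURBED_SLEEP = 6L,
                             SEDENTARY = 102L, PHYSICAL_ACTIVITY = 18L,
                             AWAY = 66L))
  ind2 <- compute_daily_indicators(day2)
  expect_equal(ind2$sleep_h, 8.0)
  expect_equal(ind2$disturbed_sleep_h, 0.5)
  expect_equal(ind2$sedentary_h, 8.5)
  expect_equal(ind2$pa_min, 90)
  expect_equal(ind2$away_h, 5.5)
  expect_equal(ind2$excluded_h, 0)

  # conservation holds with EXCLUDED intervals present
  day3 <- make_labeled_day(c(SLEEP = 100L, SEDENTARY = 150L,
                             EXCLUDED = 38L))
  ind3 <- compute_daily_indicators(day3)
  expect_equal(ind3$sleep_h + ind3$disturbed_sleep_h + ind3$sedentary_h +
                 ind3$away_h + ind3$pa_min / 60 + ind3$excluded_h, 24)

  # wrong interval count names the offending day
  expect_error(compute_daily_indicators(day[-1]), "2024-01-01")
})

test_that("interruption counts flow into the daily table", {
  day <- make_labeled_day(c(SLEEP = 286L, SEDENTARY = 2L))
  # carve two separated disturbances out of the night
  day$label[c(10, 11, 40)] <- "DISTURBED_SLEEP"
  ind <- compute_daily_indicators(day)
  expect_identical(ind$n_interruptions, 2L)
})

test_that("summary stratifies, averages and reports PASS deltas", {
  mkday <- function(house, date, sleep = 96L) {
    d <- make_labeled_day(c(SLEEP = sleep,
                            SEDENTARY = 288L - sleep - 18L,
                            PHYSICAL_ACTIVITY = 18L),
                          house_id = house, date = date)
    d
  }
  daily <- compute_daily_indicators(rbind(
    mkday("solo", "2024-01-01"), mkday("solo", "2024-01-02"),
    mkday("family", "2024-01-01", sleep = 120L)))
  meta <- data.table(house_id = c("solo", "family"),
                     num_occupants = c(1L, 3L))
  s <- summarize_indicators(daily, meta)

  expect_setequal(s$stratum, c("INDIVIDUAL", "HOUSEHOLD", "ALL"))
  expect_identical(s[s$stratum == "INDIVIDUAL", ]$n_houses, 1L)
  expect_identical(s[s$stratum == "HOUSEHOLD", ]$n_houses, 1L)
  expect_identical(s[s$stratum == "ALL", ]$n_houses, 2L)

  # single house with identical days: summary equals the daily values
  expect_equal(s[s$stratum == "INDIVIDUAL", ]$sleep_h, 8)
  expect_equal(s[s$stratum == "INDIVIDUAL", ]$pa_min, 90)

  # PASS reference deltas: reporting only
  expect_equal(s[s$stratum == "HOUSEHOLD", ]$delta_sleep_h, 10 - 7.2)
  expect_equal(s[s$stratum == "INDIVIDUAL", ]$delta_pa_min, 90 - 24.1)
  expect_equal(s[s$stratum == "INDIVIDUAL", ]$delta_sedentary_h,
               (288 - 96 - 18) * 5 / 60 - 9.6)

  # a pipeline sleep mean of 7.9 h reports a +0.7 delta
  d79 <- compute_daily_indicators(
    make_labeled_day(c(SLEEP = 95L, SEDENTARY = 193L), house_id = "x"))
  # 95 intervals = 7.9166; adjust by mixing two days averaging 7.9 h
  d79b <- compute_daily_indicators(
    make_labeled_day(c(SLEEP = 94L, SEDENTARY = 194L), house_id = "x",
                     date = "2024-01-02"))
  sx <- summarize_indicators(rbind(d79, d79b),
                             data.table(house_id = "x", num_occupants = 1L))
  expect_equal(sx[sx$stratum == "ALL", ]$sleep_h, 7.875)
  expect_equal(sx[sx$stratum == "ALL", ]$delta_sleep_h, 7.875 - 7.2)
})

test_that("summary is invariant to day order and supports house weighting", {
  sim <- quiet_sim(seed = 8L, n_days = 3, noise_rate = 0.02,
                   sleep_interruption_rate = 0.2)
  rec <- join_steps(add_counts(sim$intervals), sim$steps)
  daily <- compute_daily_indicators(classify_intervals(rec,
                                                       classifier_config()))
  meta <- data.table(house_id = "house_01", num_occupants = 1L)
  s1 <- summarize_indicators(daily, meta)
  s2 <- summarize_indicators(daily[sample.int(nrow(daily)), ], meta)
  expect_equal(as.data.frame(s1), as.data.frame(s2))

  # unequal day counts per house: the two weightings disagree as expected
  daily2 <- rbind(
    compute_daily_indicators(make_labeled_day(c(SLEEP = 288L), "a")),
    compute_daily_indicators(make_labeled_day(c(SEDENTARY = 288L), "b")),
    compute_daily_indicators(make_labeled_day(c(SEDENTARY = 288L), "b",
                                              date = "2024-01-02")))
  meta2 <- data.table(house_id = c("a", "b"), num_occupants = c(1L, 1L))
  pooled <- summarize_indicators(daily2, meta2, weighting = "house_day")
  byhouse <- summarize_indicators(daily2, meta2, weighting = "house")
  expect_equal(pooled[pooled$stratum == "ALL", ]$sleep_h, 8)
  expect_equal(byhouse[byhouse$stratum == "ALL", ]$sleep_h, 12)
})

test_that("houses without metadata are excluded with a warning", {
  daily <- compute_daily_indicators(rbind(
    make_labeled_day(c(SLEEP = 288L), "known"),
    make_labeled_day(c(SEDENTARY = 288L), "mystery")))
  meta <- data.table(house_id = "known", num_occupants = 1L)
  expect_warning(s <- summarize_indicators(daily, meta), "missing from")
  expect_identical(s[s$stratum == "ALL", ]$n_houses, 1L)
  expect_equal(s[s$stratum == "ALL", ]$sleep_h, 24)
})

test_that("noise-free synthetic indicators match the scheduled durations", {
  # schedule: sleep 22:00-08:00 (10 h), away 1.5 h, activity 60 min
  sim <- quiet_sim(seed = 2L, n_days = 2, noise_rate = 0,
                   sleep_interruption_rate = 0)
  rec <- join_steps(add_counts(sim$intervals), sim$steps)
  daily <- compute_daily_indicators(classify_intervals(rec,
                                                       classifier_config()))
  expect_equal(daily$sleep_h, rep(10, 2))
  expect_equal(daily$away_h, rep(1.5, 2))
  expect_equal(daily$pa_min, rep(60, 2))
  expect_equal(daily$sedentary_h, rep(24 - 10 - 1.5 - 1, 2))
})

test_that("plain-text report mirrors the indicator table layout", {
  daily <- compute_daily_indicators(make_labeled_day(c(SLEEP = 288L), "a"))
  s <- summarize_indicators(daily, data.table(house_id = "a",
                                              num_occupants = 1L))
  rep <- format_indicator_report(s)
  expect_match(rep[1], "Individual")
  expect_match(rep[1], "PASS")
  expect_match(rep[grep("Nighttime sleep", rep)], "7.2")
  expect_length(grep("hours|minutes|count", rep), 6L)
})
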