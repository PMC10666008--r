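# Wearable stream cleaning: steps, sleep, heart rate, completeness.

mk_epochs <- function(times, steps, pid = "P1") {
  data.table::data.table(participant_id = pid, timestamp = ts_utc(times),
                         steps = steps)
}

test_that("Tanaka maximal heart rate", {
  expect_equal(max_hr(40), 180)
  expect_equal(max_hr(20), 194)
  for (a in c(18, 35.5, 60)) expect_equal(max_hr(a) - max_hr(a + 10), 7)
  expect_error(max_hr(0), "positive")
})

test_that("step cleaning removes zeros and duplicates, idempotently", {
  raw <- mk_epochs(c("2022-01-05 08:00:00", "2022-01-05 08:15:00",
                     "2022-01-05 08:15:00", "2022-01-05 08:30:00"),
                   steps = c(0L, 12L, 12L, 30L))
  cl <- clean_steps(raw)
  expect_equal(nrow(cl), 2L)
  expect_equal(cl$steps, c(12L, 30L))
  ex <- attr(cl, "exclusions")
  expect_equal(ex[reason == "duplicate", n], 1L)
  expect_equal(ex[reason == "zero_steps", n], 1L)
  # idempotence
  cl2 <- clean_steps(cl)
  expect_equal(as.data.frame(cl2), as.data.frame(cl), ignore_attr = TRUE)
  expect_equal(nrow(attr(cl2, "exclusions")), 0L)
})

test_that("wear time bridges gaps up to one hour and matches the union oracle", {
  # epochs every 15 min covering 08:00-18:00 -> 10 h
  full <- mk_epochs(seq(ts_utc("2022-01-05 08:00:00"),
                        ts_utc("2022-01-05 17:45:00"), by = "15 min"), 10L)
  expect_equal(wear_time(full, "2022-01-05"), 10)
  # a 3-hour gap does not count as wear
  two <- mk_epochs(c("2022-01-05 08:00:00", "2022-01-05 11:00:00"), 10L)
  expect_equal(wear_time(two, "2022-01-05"), 0.5)
  expect_equal(wear_time(two, "2022-01-06"), 0)
  # random gap patterns vs interval-union oracle
  set.seed(5)
  grid <- seq(ts_utc("2022-01-05 00:00:00"), ts_utc("2022-01-05 23:45:00"),
              by = "15 min")
  for (r in 1:25) {
    t <- sort(sample(grid, sample(3:60, 1)))
    expect_equal(wear_time(mk_epochs(t, 5L), "2022-01-05"),
                 oracle_wear_hours(t) / 3600)
  }
})

test_that("daily step totals respect the 10-hour wear filter inclusively", {
  # 40 epochs at 15 min = 10.0 h wear (boundary -> included)
  t10 <- seq(ts_utc("2022-01-05 08:00:00"), by = "15 min", length.out = 40)
  d <- daily_steps(mk_epochs(t10, 225L))
  expect_equal(nrow(d), 1L)
  expect_equal(d$steps, 9000L)
  expect_equal(d$wear_hours, 10)
  # 39 epochs = 9.75 h -> the day is absent, not zero
  d2 <- daily_steps(mk_epochs(t10[-40], 225L))
  expect_equal(nrow(d2), 0L)
})

test_that("15-minute step binning matches a string-keyed oracle", {
  one <- mk_epochs("2022-01-05 10:07:00", 50L)
  b <- bin_steps_15min(one)
  expect_equal(b$bin_start, ts_utc("2022-01-05 10:00:00"))
  set.seed(6)
  t <- ts_utc("2022-01-05 00:00:00") + sort(sample(0:86000, 200))
  e <- mk_epochs(t, sample(1:100, 200, replace = TRUE),
                 pid = sample(c("P1", "P2"), 200, replace = TRUE))
  expect_equal(sort(bin_steps_15min(e)$steps), oracle_bin_steps(e))
})

mk_sleep <- function(pid, onset, offset, dur_h, waso = 0) {
  data.table::data.table(participant_id = pid, onset = ts_utc(onset),
                         offset = ts_utc(offset), duration_h = dur_h,
                         waso_min = waso)
}

test_that("sleep merging adds durations and counts the gap as wake time", {
  recs <- rbind(
    mk_sleep("P1", "2022-01-05 20:00:00", "2022-01-05 23:00:00", 3.0, 10),
    mk_sleep("P1", "2022-01-06 00:30:00", "2022-01-06 05:30:00", 5.0, 5))
  n <- clean_sleep(recs)
  expect_equal(nrow(n), 1L)
  expect_equal(n$night_date, as.Date("2022-01-05"))
  expect_equal(n$duration_h, 8.0)
  expect_equal(n$waso_min, 10 + 5 + 90)  # records' wake time + 90-min gap
  expect_equal(n$onset, ts_utc("2022-01-05 20:00:00"))
  expect_equal(n$offset, ts_utc("2022-01-06 05:30:00"))
})

test_that("sleep QC drops short, overlapping and out-of-window records", {
  recs <- rbind(
    mk_sleep("P1", "2022-01-05 21:00:00", "2022-01-05 23:30:00", 2.4),   # <3 h
    mk_sleep("P2", "2022-01-05 22:00:00", "2022-01-06 02:00:00", 3.9),   # overlap
    mk_sleep("P2", "2022-01-06 01:00:00", "2022-01-06 05:00:00", 3.9),   # overlap
    mk_sleep("P3", "2022-01-05 14:00:00", "2022-01-05 19:00:00", 4.9),   # onset 2 PM
    mk_sleep("P4", "2022-01-05 23:00:00", "2022-01-06 14:00:00", 10),    # offset 2 PM
    mk_sleep("P5", "2022-01-05 21:30:00", "2022-01-06 04:30:00", 6.5, 30))
  n <- clean_sleep(recs)
  expect_identical(n$participant_id, "P5")
  ex <- attr(n, "exclusions")
  expect_equal(ex[reason == "short_span", n], 1L)
  expect_equal(ex[reason == "overlap", n], 2L)
  expect_equal(ex[reason == "window", n], 2L)
})

test_that("sleep cleaning equals the brute-force oracle on random fixtures", {
  set.seed(7)
  for (r in 1:10) {
    recs <- do.call(rbind, lapply(1:40, function(i) {
      pid <- sample(c("P1", "P2", "P3"), 1)
      night <- as.Date("2022-02-01") + sample(0:5, 1)
      on <- ts_utc(paste(night, "17:00:00")) + runif(1, 0, 9) * 3600
      span <- runif(1, 1.5, 9)
      mk_sleep(pid, format(on), format(on + span * 3600), span * 0.9,
               round(span * 3))
    }))
    got <- clean_sleep(recs)
    want <- oracle_clean_sleep(recs)
    expect_equal(nrow(got), nrow(want))
    expect_equal(got$duration_h, want$duration_h)
    expect_equal(got$waso_min, want$waso_min)
    expect_equal(got$onset, want$onset)
    # output nights never overlap and all span at least 3 h
    expect_true(got[, all(difftime(offset, onset, units = "hours") >= 3)])
    ov <- got[order(participant_id, onset),
              any(onset[-1] < offset[-.N] &
                    participant_id[-1] == participant_id[-.N])]
    expect_false(isTRUE(ov))
  }
})

test_that("insufficient sleep uses age-specific thresholds", {
  expect_true(flag_insufficient_sleep(6.9, 30))
  expect_false(flag_insufficient_sleep(7.0, 30))
  expect_true(flag_insufficient_sleep(7.5, 16))
  expect_false(flag_insufficient_sleep(7.5, 18))  # 18 counts as adult
})

mk_hr <- function(times, bpm, pid = "P1") {
  data.table::data.table(participant_id = pid, timestamp = ts_utc(times),
                         bpm = bpm)
}
ages1 <- data.table::data.table(participant_id = c("P1", "P2"), age = c(40, 20))

test_that("heart-rate cleaning enforces the ceiling and coverage rules", {
  # 8 populated day bins qualify the day; 7 do not
  t8 <- ts_utc("2022-01-05 09:00:00") + (0:7) * 900
  ok <- clean_hr(mk_hr(t8, 80), ages1)
  expect_equal(nrow(ok$day), 8L)
  short <- clean_hr(mk_hr(t8[-1], 80), ages1)
  expect_equal(nrow(short$day), 0L)
  # 4 populated night bins qualify; 3 do not
  tn <- ts_utc("2022-01-05 23:00:00") + (0:3) * 900
  nt <- clean_hr(mk_hr(tn, c(60, 70, 62, 68)), ages1)
  expect_equal(nrow(nt$nightly), 1L)
  expect_equal(nt$nightly$night_date, as.Date("2022-01-05"))
  expect_equal(nt$nightly$nightly_hr, mean(c(60, 70, 62, 68)))
  expect_equal(nrow(clean_hr(mk_hr(tn[-1], 65), ages1)$nightly), 0L)
  # ceiling: 190 bpm at age 40 (limit 180) is dropped
  sp <- clean_hr(rbind(mk_hr(tn, 65), mk_hr("2022-01-05 23:05:00", 190)), ages1)
  expect_equal(sp$exclusions[reason == "hr_ceiling", n], 1L)
  # per-bin aggregation: two samples 60 and 70 -> mean 65, min 60, max 70
  two <- clean_hr(mk_hr(c("2022-01-05 23:01:00", "2022-01-05 23:10:00"),
                        c(60, 70)), ages1, min_night_bins = 1)
  expect_equal(two$night$mean_bpm, 65)
  expect_equal(two$night$min_bpm, 60)
  expect_equal(two$night$max_bpm, 70)
})

test_that("heart-rate intervals always satisfy min <= mean <= max", {
  set.seed(8)
  t <- ts_utc("2022-01-05 00:00:00") + sort(sample(0:86000, 400))
  res <- clean_hr(mk_hr(t, runif(400, 45, 175),
                        pid = sample(c("P1", "P2"), 400, TRUE)),
                  ages1, min_day_bins = 1, min_night_bins = 1)
  both <- rbind(res$day[, .(mean_bpm, min_bpm, max_bpm)],
                res$night[, .(mean_bpm, min_bpm, max_bpm)])
  expect_true(both[, all(min_bpm <= mean_bpm & mean_bpm <= max_bpm)])
})

test_that("completeness filter keeps participants at or above the threshold", {
  cov <- data.table::data.table(participant_id = c("A", "B", "C"),
                                valid_days = c(80, 79, 140),
                                study_days = 320)
  expect_identical(completeness_filter(cov), c("A", "C"))
  expect_identical(completeness_filter(cov, threshold = 0.5), character(0))
  cov2 <- rbind(cov, data.table::data.table(participant_id = "D",
                                            valid_days = 0, study_days = 0))
  expect_warning(kept <- completeness_filter(cov2), "zero study days")
  expect_false("D" %in% kept)
})
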