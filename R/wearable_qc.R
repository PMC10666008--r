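# Wearable stream cleaning: step epochs, sleep records, heart-rate samples.
# Every exclusion carries a machine-readable reason code
# (duplicate, zero_steps, window, short_span, overlap, hr_ceiling) so the QC
# report can be reconciled against a ground-truth ledger.

.floor_15min <- function(t) {
  as.POSIXct(floor(as.numeric(t) / 900) * 900, origin = "1970-01-01", tz = "UTC")
}

# local-time ISO-8601 (with or without "T") -> POSIXct; idempotent
.parse_ts <- function(x) {
  if (inherits(x, "POSIXct")) return(x)
  as.POSIXct(as.character(x), tz = "UTC",
             tryFormats = c("%Y-%m-%dT%H:%M:%S", "%Y-%m-%d %H:%M:%S",
                            "%Y-%m-%d %H:%M", "%Y-%m-%d"))
}

.exclusion_dt <- function(...) {
  dt <- rbindlist(list(...), use.names = TRUE, fill = TRUE)
  if (nrow(dt) == 0L)
    dt <- data.table(reason = character(), n = integer())
  dt[n > 0L]
}

#' Age-predicted maximal heart rate (Tanaka)
#'
#' @param age Age in years, > 0.
#' @return Maximal heart rate in bpm: `208 - 0.7 * age`.
#' @export
max_hr <- function(age) {
  if (any(!is.finite(age)) || any(age <= 0)) stop("`age` must be positive")
  208 - 0.7 * age
}

#' Clean step epochs
#'
#' Removes duplicated (participant, timestamp) records, then removes
#' zero-step epochs (indistinguishable from non-wear), and sorts by
#' participant and time. Idempotent.
#'
#' @param epochs data.frame with `participant_id`, `timestamp`, `steps`.
#' @return Cleaned data.table with an `exclusions` attribute
#'   (reason x count).
#' @export
clean_steps <- function(epochs) {
  dt <- as.data.table(epochs)
  dt[, timestamp := .parse_ts(timestamp)]
  n0 <- nrow(dt)
  dt <- unique(dt, by = c("participant_id", "timestamp"))
  n_dup <- n0 - nrow(dt)
  n_zero <- dt[steps == 0, .N]
  dt <- dt[steps > 0]
  setkey(dt, participant_id, timestamp)
  setattr(dt, "exclusions", .exclusion_dt(
    data.table(reason = "duplicate", n = n_dup),
    data.table(reason = "zero_steps", n = n_zero)
  ))
  dt[]
}

# wear hours for one participant's sorted epoch times on a single date:
# epochs are 15-min interval starts; bouts split at gaps > 1 h, each bout
# covers first..last epoch plus the final epoch's bin width
.wear_hours <- function(times, bin_width_h = 0.25, max_gap_h = 1) {
  if (length(times) == 0L) return(0)
  times <- sort(as.numeric(times)) / 3600
  gaps <- diff(times)
  bout <- cumsum(c(0, gaps > max_gap_h))
  sum(tapply(times, bout, function(x) max(x) - min(x) + bin_width_h))
}

#' Worn hours on a date
#'
#' Non-wear is any gap of more than 1 hour between consecutive epochs; worn
#' time is the union of wear bouts, each spanning its first to last epoch
#' plus one 15-minute bin width.
#'
#' @param epochs Cleaned step epochs for one participant.
#' @param date Calendar date.
#' @return Hours worn on `date` (0 when no epochs).
#' @export
wear_time <- function(epochs, date) {
  dt <- as.data.table(epochs)
  date <- as.Date(date)
  t <- dt[as.Date(timestamp, tz = "UTC") == date, timestamp]
  .wear_hours(t)
}

#' Daily step totals with the wear-time filter
#'
#' Sums steps per participant-day and excludes days with under 10 hours of
#' wear time; excluded days are absent from the result (missing, not zero).
#'
#' @param epochs Cleaned step epochs (see [clean_steps()]).
#' @param min_wear_hours Inclusion threshold in hours (inclusive).
#'   Default 10.
#' @return data.table `participant_id`, `date`, `steps`, `wear_hours`.
#' @export
daily_steps <- function(epochs, min_wear_hours = 10) {
  dt <- as.data.table(epochs)
  out <- dt[, .(steps = sum(steps), wear_hours = .wear_hours(timestamp)),
            by = .(participant_id, date = as.Date(timestamp, tz = "UTC"))]
  out <- out[wear_hours >= min_wear_hours]
  setkey(out, participant_id, date)
  out[]
}

#' Bin step epochs to the 15-minute grid
#'
#' Left-closed bins starting on :00/:15/:30/:45, steps summed per bin.
#'
#' @param epochs Cleaned step epochs.
#' @return data.table `participant_id`, `bin_start`, `steps`.
#' @export
bin_steps_15min <- function(epochs) {
  dt <- as.data.table(epochs)
  out <- dt[, .(steps = sum(steps)),
            by = .(participant_id, bin_start = .floor_15min(timestamp))]
  setkey(out, participant_id, bin_start)
  out[]
}

.hour_frac <- function(t) {
  as.integer(format(t, "%H", tz = "UTC")) +
    as.integer(format(t, "%M", tz = "UTC")) / 60 +
    as.integer(format(t, "%S", tz = "UTC")) / 3600
}

#' Clean and merge sleep records into one observation per night
#'
#' Applies, in order: (1) the nighttime window — onset at or after 17:00 and
#' offset at or before 13:00 of the following day, each record attributed to
#' the night it starts (records starting between 13:00 and 17:00 are
#' dropped); (2) the minimum span — records with under 3 hours between onset
#' and offset are invalid; (3) overlap exclusion — records of one night that
#' overlap each other in time are dropped as error measurements; (4) merging
#' — the remaining records of a night are combined by summing sleep
#' durations, adding inter-record gaps to wake-after-sleep-onset, and taking
#' the earliest onset and latest offset.
#'
#' @param records data.frame with `participant_id`, `onset`, `offset`
#'   (POSIXct or ISO strings), `duration_h` (hours asleep) and `waso_min`
#'   (minutes awake after onset).
#' @return data.table of one row per participant-night (`night_date` is the
#'   calendar date the night starts on) with an `exclusions` attribute.
#' @export
clean_sleep <- function(records) {
  dt <- as.data.table(records)
  for (col in c("onset", "offset"))
    set(dt, j = col, value = .parse_ts(dt[[col]]))
  dt <- dt[offset > onset]

  oh <- .hour_frac(dt$onset)
  dt[, night := fifelse(oh >= 17, as.Date(onset, tz = "UTC"),
                        as.Date(onset, tz = "UTC") - 1L)]
  in_window <- (oh >= 17 | oh <= 13) &
    dt$offset <= as.POSIXct(paste(dt$night + 1L, "13:00:00"), tz = "UTC")
  n_window <- sum(!in_window)
  dt <- dt[in_window]

  dt[, span_h := as.numeric(difftime(offset, onset, units = "hours"))]
  n_short <- dt[span_h < 3, .N]
  dt <- dt[span_h >= 3]

  # overlap: within a night, flag every record that intersects another
  setkey(dt, participant_id, night, onset)
  dt[, rec_id := seq_len(.N)]
  dt[, overlaps := {
    ov <- rep(FALSE, .N)
    if (.N > 1L) {
      for (i in seq_len(.N - 1L)) {
        for (j in (i + 1L):.N) {
          if (onset[j] < offset[i]) { ov[i] <- TRUE; ov[j] <- TRUE }
        }
      }
    }
    ov
  }, by = .(participant_id, night)]
  n_overlap <- dt[overlaps == TRUE, .N]
  dt <- dt[overlaps == FALSE]

  nights <- dt[, {
    gap_min <- if (.N > 1L)
      sum(as.numeric(difftime(onset[-1L], offset[-.N], units = "mins")))
    else 0
    .(duration_h = sum(duration_h),
      onset = min(onset),
      offset = max(offset),
      waso_min = sum(waso_min) + gap_min)
  }, by = .(participant_id, night_date = night)]
  setkey(nights, participant_id, night_date)
  setattr(nights, "exclusions", .exclusion_dt(
    data.table(reason = "window", n = n_window),
    data.table(reason = "short_span", n = n_short),
    data.table(reason = "overlap", n = n_overlap)
  ))
  nights[]
}

#' Flag insufficient sleep by age group
#'
#' Under 8 hours is insufficient below age 18; under 7 hours at 18 and
#' above (age exactly 18 is treated as adult).
#'
#' @param duration_h Nightly sleep duration, hours; vectorised.
#' @param age Age in years (recycled).
#' @return Logical vector.
#' @export
flag_insufficient_sleep <- function(duration_h, age) {
  threshold <- fifelse(age < 18, 8, 7)
  duration_h < threshold
}

#' Clean heart-rate samples and aggregate to 15-minute intervals
#'
#' Removes duplicate samples and samples above the Tanaka age-predicted
#' maximum, rounds bpm to integers, aggregates to 15-minute bins
#' (mean/min/max/n), and splits bins into daytime and nighttime using the
#' 22:00-06:00 night window (a night is attributed to the date it starts).
#' A participant-day qualifies when at least 8 daytime bins (2 hours) hold a
#' sample; a participant-night qualifies when at least 4 nighttime bins
#' (1 hour at one sample per 15 minutes) hold a sample. The nightly outcome
#' is the mean of the qualifying night's bin means. Disqualified days and
#' nights are absent from the outputs, never zero.
#'
#' @param samples data.frame with `participant_id`, `timestamp`, `bpm`.
#' @param ages data.frame with `participant_id`, `age` (years at study
#'   start).
#' @param min_day_bins,min_night_bins Qualification thresholds (bins with at
#'   least one sample). Defaults 8 and 2 h / 4 and 1 h.
#' @return List: `day` and `night` interval tables
#'   (`participant_id`, `bin_start`, `mean_bpm`, `min_bpm`, `max_bpm`,
#'   `n_samples`), `nightly` (`participant_id`, `night_date`, `nightly_hr`,
#'   `n_bins`), and `exclusions`.
#' @export
clean_hr <- function(samples, ages, min_day_bins = 8, min_night_bins = 4) {
  dt <- as.data.table(samples)
  dt[, timestamp := .parse_ts(timestamp)]
  ages <- as.data.table(ages)[, .(participant_id, age)]

  n0 <- nrow(dt)
  dt <- unique(dt, by = c("participant_id", "timestamp"))
  n_dup <- n0 - nrow(dt)

  dt <- merge(dt, ages, by = "participant_id", all.x = TRUE)
  if (anyNA(dt$age)) stop("heart-rate samples reference unknown participants")
  n_ceiling <- dt[bpm > max_hr(age), .N]
  dt <- dt[bpm <= max_hr(age)]
  dt[, bpm := round(bpm)]

  bins <- dt[, .(mean_bpm = mean(bpm), min_bpm = min(bpm), max_bpm = max(bpm),
                 n_samples = .N),
             by = .(participant_id, bin_start = .floor_15min(timestamp))]
  hr <- as.integer(format(bins$bin_start, "%H", tz = "UTC"))
  is_night <- hr >= 22 | hr < 6
  day_bins <- bins[!is_night]
  night_bins <- bins[is_night]
  night_bins[, night_date := fifelse(
    as.integer(format(bin_start, "%H", tz = "UTC")) >= 22,
    as.Date(bin_start, tz = "UTC"), as.Date(bin_start, tz = "UTC") - 1L)]

  # day qualification: >= min_day_bins populated bins on the calendar day
  day_bins[, date := as.Date(bin_start, tz = "UTC")]
  day_ok <- day_bins[, .(n_bins = .N), by = .(participant_id, date)][
    n_bins >= min_day_bins]
  day_out <- day_bins[day_ok[, .(participant_id, date)],
                      on = c("participant_id", "date")]

  night_ok <- night_bins[, .(n_bins = .N), by = .(participant_id, night_date)][
    n_bins >= min_night_bins]
  night_out <- night_bins[night_ok[, .(participant_id, night_date)],
                          on = c("participant_id", "night_date")]
  nightly <- night_out[, .(nightly_hr = mean(mean_bpm), n_bins = .N),
                       by = .(participant_id, night_date)]
  setkey(nightly, participant_id, night_date)

  list(
    day = day_out[order(participant_id, bin_start)],
    night = night_out[order(participant_id, bin_start)],
    nightly = nightly[],
    exclusions = .exclusion_dt(
      data.table(reason = "duplicate", n = n_dup),
      data.table(reason = "hr_ceiling", n = n_ceiling)
    )
  )
}

#' Completeness filter over measurement days
#'
#' Keeps participants whose fraction of valid days (or nights) over their
#' total study days reaches the threshold, per stream.
#'
#' @param coverage data.frame with `participant_id`, `valid_days`,
#'   `study_days`.
#' @param threshold Minimum fraction, inclusive. Default 0.25 (0.5 as the
#'   sensitivity setting).
#' @return Character vector of included participant ids.
#' @export
completeness_filter <- function(coverage, threshold = 0.25) {
  dt <- as.data.table(coverage)
  if (any(dt$study_days <= 0)) {
    warning("participants with zero study days are excluded")
    dt <- dt[study_days > 0]
  }
  dt[valid_days / study_days >= threshold, as.character(participant_id)]
}

#' Combine QC exclusion tallies into one report
#'
#' @param ... Cleaned objects carrying an `exclusions` attribute, or
#'   exclusion tables themselves, named by stream.
#' @return data.table `stream`, `reason`, `n`.
#' @export
qc_report <- function(...) {
  parts <- list(...)
  out <- rbindlist(lapply(names(parts), function(nm) {
    x <- parts[[nm]]
    ex <- if (is.data.frame(x) && all(c("reason", "n") %in% names(x))) x
          else attr(x, "exclusions")
    if (is.null(ex)) return(NULL)
    data.table(stream = nm, as.data.table(ex))
  }), fill = TRUE)
  if (nrow(out) == 0L) out <- data.table(stream = character(),
                                         reason = character(), n = integer())
  out[]
}
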