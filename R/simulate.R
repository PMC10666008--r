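# Synthetic study-world generator: seasonal weather, a cohort roster, and
# wearable streams decomposed from known-truth linked outcomes, with
# configurable missingness and QC-violation injection (ledgered) so every
# pipeline stage is testable against ground truth.

.sub_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 7919 + k * 104729) %% 2147483629) + 1L
}

#' Simulation configuration
#'
#' All true parameters of the synthetic study world. Defaults emulate the
#' study conditions: a 5-station, 25-village rural region with a rainy
#' (June-September), cool dry (October-January) and hot dry (February-May)
#' season; seasonal mean air temperatures of 27.6 / 26.8 / 31.1 deg C; a
#' cohort of roughly half females with mean age 43 (SD 13) years and mean
#' BMI 22.3 (SD 2.7); true exposure effects near the headline estimates
#' (sleep -0.04 h per deg C of nightly minimum heat index, +0.01 h per mm
#' of rain; an inverted-U daily-activity response to WBGT peaking near
#' 27 deg C with -39 steps per mm of rain; no heat effect and -0.04 bpm
#' per mm on nighttime heart rate); and wearable missingness near the
#' observed completeness levels.
#'
#' @param n_participants Cohort size. Default 60.
#' @param study_days Days of follow-up. Default 120.
#' @param study_start First study date.
#' @param n_stations,n_villages Region layout.
#' @param weather Per-season weather parameters (means, diurnal amplitudes,
#'   noise SDs, rain probability and gamma amount, radiation, wind).
#' @param effects Per-outcome true fixed effects and variance components.
#' @param missingness Per-stream fraction of participant-days/nights with
#'   no usable record.
#' @param violations Injection rates for QC-violating records (duplicated
#'   step epochs, zero-step epochs, overlapping and short sleep records,
#'   heart-rate spikes above the Tanaka ceiling, duplicated heart-rate
#'   samples).
#' @param sleep_split_prob Probability that a (long enough) night is
#'   emitted as two records separated by a wake gap, to exercise merging.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_participants = 60,
                       study_days = 120,
                       study_start = as.Date("2021-08-01"),
                       n_stations = 5,
                       n_villages = 25,
                       weather = list(
                         temp_mean = c(rainy = 27.6, cool_dry = 26.8, hot_dry = 31.1),
                         temp_diurnal_amp = c(rainy = 4, cool_dry = 7, hot_dry = 7),
                         temp_day_sd = 1.5, temp_noise_sd = 0.8,
                         rh_mean = c(rainy = 75, cool_dry = 35, hot_dry = 30),
                         rh_day_sd = 12, rh_temp_slope = -2.5, rh_noise_sd = 5,
                         rain_prob = c(rainy = 0.30, cool_dry = 0.01, hot_dry = 0.04),
                         rain_shape = 0.8, rain_scale = 15,
                         rad_max = 850, rad_rain_attenuation = 0.5,
                         cloud_mean = 0.2, cloud_sd = 0.15,
                         wind_mean = 1.5, wind_sd = 0.8
                       ),
                       effects = list(
                         sleep = list(intercept = 7.8, heat = -0.04, heat2 = 0,
                                      rain = 0.01, weekend = 0.05,
                                      intercept_sd = 0.6, resid_sd = 1.0),
                         steps = list(intercept = 900, heat = 648, heat2 = -12,
                                      rain = -39, weekend = -400,
                                      intercept_sd = 2500, resid_sd = 4000),
                         hr = list(intercept = 69, heat = 0, heat2 = 0,
                                   rain = -0.04, weekend = 0,
                                   intercept_sd = 8, resid_sd = 5)
                       ),
                       missingness = c(steps = 0.5, sleep = 0.5, hr = 0.8),
                       violations = c(dup_steps = 0.01, zero_steps = 0.02,
                                      sleep_overlap = 0.01, sleep_short = 0.01,
                                      hr_spike = 0.005, dup_hr = 0.005),
                       sleep_split_prob = 0.3) {
  stopifnot(all(missingness >= 0 & missingness <= 1),
            all(violations >= 0 & violations <= 1),
            sleep_split_prob >= 0 && sleep_split_prob <= 1)
  for (e in effects) stopifnot(e$intercept_sd >= 0, e$resid_sd >= 0)
  structure(list(n_participants = n_participants, study_days = study_days,
                 study_start = as.Date(study_start), n_stations = n_stations,
                 n_villages = n_villages, weather = weather, effects = effects,
                 missingness = missingness, violations = violations,
                 sleep_split_prob = sleep_split_prob),
            class = "sim_config")
}

#' Simulate 15-minute weather-station series
#'
#' Air temperature follows a per-season daily mean plus a diurnal sinusoid
#' (coolest near 03:00, warmest near 15:00) with day-level and
#' interval-level noise; relative humidity is anti-correlated with the
#' temperature anomaly around its seasonal mean; rain falls as per-day
#' Bernoulli events (seasonal probability) with gamma-distributed totals
#' spread over afternoon intervals; global radiation is a daytime sinusoid
#' attenuated on rain days; wind is folded normal. Deterministic given
#' (config, seed). The series extends 6 hours past the last study day so
#' the final night window is complete.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed.
#' @return data.table of weather observations (one per station x 15 min).
#' @export
simulate_weather <- function(config, seed) {
  set.seed(.sub_seed(seed, 1L))
  w <- config$weather
  days <- seq(config$study_start, by = "day", length.out = config$study_days)
  grid <- CJ(station_id = sprintf("S%02d", seq_len(config$n_stations)),
             date = days, slot = 0:95)
  # trailing 6 h so the last night (22:00 -> 06:00 next day) has data
  tail_grid <- CJ(station_id = sprintf("S%02d", seq_len(config$n_stations)),
                  date = max(days) + 1L, slot = 0:23)
  grid <- rbind(grid, tail_grid)
  grid[, timestamp := as.POSIXct(paste(date, "00:00:00"), tz = "UTC") + slot * 900]
  grid[, obs_hour := slot / 4]
  grid[, season := season_of(as.integer(format(date, "%m")))]

  # day-level structure
  day_tab <- unique(grid[, .(station_id, date, season)])
  day_tab[, temp_day_mean := w$temp_mean[season] + rnorm(.N, 0, w$temp_day_sd)]
  # day-to-day humidity and cloud-cover waves: these decorrelate WBGT and
  # heat index from bare air temperature, as in real station data
  day_tab[, rh_day_mean := w$rh_mean[season] + rnorm(.N, 0, w$rh_day_sd)]
  day_tab[, cloud_day := pmin(1, pmax(0, rnorm(.N, w$cloud_mean, w$cloud_sd)))]
  day_tab[, rain_day := rbinom(.N, 1, w$rain_prob[season])]
  day_tab[, rain_amount := rain_day * rgamma(.N, shape = w$rain_shape,
                                             scale = w$rain_scale)]
  grid <- merge(grid, day_tab, by = c("station_id", "date", "season"))

  grid[, air_temp_c := temp_day_mean +
         w$temp_diurnal_amp[season] * sin(2 * pi * (obs_hour - 9) / 24) +
         rnorm(.N, 0, w$temp_noise_sd)]
  grid[, rel_humidity_pct := pmin(100, pmax(5,
         rh_day_mean + w$rh_temp_slope * (air_temp_c - temp_day_mean) +
           rnorm(.N, 0, w$rh_noise_sd)))]
  # rain spread over the 13:00-18:00 intervals of rain days
  grid[, precip_mm := 0]
  grid[rain_day == 1 & obs_hour >= 13 & obs_hour < 18,
       precip_mm := rain_amount / 20]
  grid[, global_radiation_wm2 := pmax(0,
         w$rad_max * sin(pi * (obs_hour - 6) / 12) *
           (obs_hour >= 6 & obs_hour <= 18) *
           (1 - cloud_day) * (1 - w$rad_rain_attenuation * rain_day) +
           fifelse(obs_hour >= 6 & obs_hour <= 18, rnorm(.N, 0, 15), 0))]
  grid[, wind_speed_ms := abs(rnorm(.N, w$wind_mean, w$wind_sd))]

  out <- grid[, .(station_id, timestamp, air_temp_c, rel_humidity_pct,
                  precip_mm, wind_speed_ms, global_radiation_wm2)]
  setkey(out, station_id, timestamp)
  out[]
}

#' Simulate the region layout and cohort roster
#'
#' Stations and villages are placed around a rural-region centre; the
#' roster draws sex (about half female), age (mean 43, SD 13 years, ages 16
#' to 79), height and BMI (mean 22.3, SD 2.7), and per-participant true
#' random intercepts for each outcome.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed.
#' @return List: `roster`, `stations`, `villages`, `intercepts` (the
#'   ground-truth per-participant deviations per outcome).
#' @export
simulate_cohort <- function(config, seed) {
  set.seed(.sub_seed(seed, 2L))
  centre <- c(lat = 12.73, lon = -3.87)
  stations <- data.table(
    station_id = sprintf("S%02d", seq_len(config$n_stations)),
    lat = centre["lat"] + runif(config$n_stations, -0.15, 0.15),
    lon = centre["lon"] + runif(config$n_stations, -0.15, 0.15))
  villages <- data.table(
    village_id = sprintf("V%02d", seq_len(config$n_villages)),
    lat = centre["lat"] + runif(config$n_villages, -0.18, 0.18),
    lon = centre["lon"] + runif(config$n_villages, -0.18, 0.18))

  n <- config$n_participants
  age <- pmin(79, pmax(16, rnorm(n, 43, 13)))
  height_cm <- rnorm(n, 170, 8)
  bmi <- pmin(33, pmax(16, rnorm(n, 22.3, 2.7)))
  roster <- data.table(
    participant_id = sprintf("P%03d", seq_len(n)),
    sex = fifelse(rbinom(n, 1, 0.5) == 1, "female", "male"),
    birth_date = config$study_start - round(age * 365.25),
    height_cm = height_cm,
    weight_kg = bmi * (height_cm / 100)^2,
    village_id = sample(villages$village_id, n, replace = TRUE))

  intercepts <- data.table(participant_id = roster$participant_id)
  for (oc in names(config$effects))
    intercepts[[paste0("b_", oc)]] <-
      rnorm(n, 0, config$effects[[oc]]$intercept_sd)
  list(roster = roster, stations = stations, villages = villages,
       intercepts = intercepts)
}

#' Simulate the linked ground-truth panel
#'
#' Generates weather and cohort, links each participant to their nearest
#' station's daily weather, and builds the true per-day (steps) and
#' per-night (sleep, heart rate) outcomes on the linked scale:
#' `intercept + b_heat * Heat + b_heat2 * Heat^2 + b_rain * Rain +
#' b_weekend * weekend + participant intercept + noise`, with the daily
#' maximum WBGT as the heat exposure for steps and the nightly minimum heat
#' index for sleep and heart rate. Missingness then drops whole
#' participant-days/nights at the configured per-stream rates.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed.
#' @param weather,cohort Optional pre-simulated inputs (reuse across
#'   replicates).
#' @return List: `panels` (data.tables `steps`, `sleep`, `hr`),
#'   `daily_weather`, `cohort`, `participants` (roster with covariates and
#'   station), `truth` (config effects and true intercepts).
#' @export
simulate_panel <- function(config, seed, weather = NULL, cohort = NULL) {
  if (is.null(weather)) weather <- simulate_weather(config, seed)
  if (is.null(cohort)) cohort <- simulate_cohort(config, seed)
  set.seed(.sub_seed(seed, 3L))

  daily <- summarize_daily_weather(weather)
  vs <- assign_nearest_station(cohort$villages, cohort$stations)
  pts <- derive_covariates(cohort$roster, config$study_start)
  pts <- merge(pts, vs[, .(village_id, station_id)], by = "village_id")

  days <- seq(config$study_start, by = "day", length.out = config$study_days)
  base <- CJ(participant_id = pts$participant_id, date = days)
  base <- merge(base, pts[, .(participant_id, station_id)],
                by = "participant_id")
  base <- merge(base, daily[, .(station_id, date, wbgt_max_day, hi_min_night,
                                rain_total)],
                by = c("station_id", "date"), all.x = TRUE)
  base[, weekend := format(date, "%u") %in% c("6", "7")]
  base <- merge(base, cohort$intercepts, by = "participant_id")

  mk <- function(e, heat, b_i) {
    e$intercept + e$heat * heat + e$heat2 * heat^2 +
      e$rain * base$rain_total + e$weekend * base$weekend + b_i +
      rnorm(nrow(base), 0, e$resid_sd)
  }
  outcomes <- list(
    steps = copy(base)[, .(participant_id, date,
                           steps = mk(config$effects$steps, wbgt_max_day,
                                      b_steps))],
    sleep = copy(base)[, .(participant_id, night_date = date,
                           duration_h = mk(config$effects$sleep, hi_min_night,
                                           b_sleep))],
    hr = copy(base)[, .(participant_id, night_date = date,
                        nightly_hr = mk(config$effects$hr, hi_min_night,
                                        b_hr))]
  )
  panels <- list()
  for (nm in names(outcomes)) {
    o <- outcomes[[nm]]
    o <- o[runif(nrow(o)) >= config$missingness[[nm]]]
    panels[[nm]] <- build_panel(o, daily, pts,
                                type = if (nm == "steps") "day" else "night")
  }
  list(panels = panels, daily_weather = daily, cohort = cohort,
       participants = pts,
       truth = list(effects = config$effects,
                    intercepts = cohort$intercepts))
}

# distribute a day's steps over 15-min epochs with a bimodal diurnal shape
.steps_epoch_weights <- local({
  h <- seq(6, 21.75, by = 0.25)
  w <- exp(-((h - 8.5) / 2.2)^2 / 2) + 0.8 * exp(-((h - 17) / 2.8)^2 / 2) + 0.05
  list(hours = h, w = w / sum(w))
})

#' Decompose the ground-truth panel into raw wearable streams
#'
#' Each kept participant-day's step total is spread over 15-minute epochs
#' between 06:00 and 22:00 with a bimodal (morning/late-afternoon) diurnal
#' profile; each kept night's sleep becomes one record (or two records
#' separated by a wake gap, to exercise merging); each kept night's heart
#' rate becomes per-15-minute samples around the nightly mean. QC-violating
#' records are then injected at the configured rates and tallied in a
#' ground-truth ledger whose per-reason counts must equal the QC module's
#' exclusion counts exactly.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed.
#' @param sim Output of [simulate_panel()] (generated if `NULL`).
#' @return List: `steps`, `sleep`, `hr` raw streams, `ledger`
#'   (stream x reason x count), `clean_nights` (nights untouched by sleep
#'   injections, for recovery checks) and the originating `sim`.
#' @export
simulate_outcomes <- function(config, seed, sim = NULL) {
  if (is.null(sim)) sim <- simulate_panel(config, seed)
  set.seed(.sub_seed(seed, 4L))
  vi <- config$violations
  pts <- sim$participants

  ## ---- step epochs ----
  sp <- sim$panels$steps[!is.na(steps)]
  ep_list <- vector("list", nrow(sp))
  wts <- .steps_epoch_weights
  day0 <- as.POSIXct(paste(sp$date, "00:00:00"), tz = "UTC")
  totals <- pmax(200L, as.integer(round(sp$steps)))
  counts <- matrix(0L, nrow = length(wts$hours), ncol = nrow(sp))
  for (i in seq_len(nrow(sp)))
    counts[, i] <- rmultinom(1, totals[i], wts$w)
  idx <- which(counts > 0, arr.ind = TRUE)
  steps_stream <- data.table(
    participant_id = sp$participant_id[idx[, 2]],
    timestamp = day0[idx[, 2]] + wts$hours[idx[, 1]] * 3600,
    steps = counts[idx])
  setkey(steps_stream, participant_id, timestamp)

  n_dup_steps <- as.integer(round(vi[["dup_steps"]] * nrow(steps_stream)))
  if (n_dup_steps > 0)
    steps_stream <- rbind(steps_stream,
                          steps_stream[sample(.N, n_dup_steps, replace = FALSE)])
  n_zero <- as.integer(round(vi[["zero_steps"]] * nrow(sp)))
  if (n_zero > 0) {
    zi <- sample(nrow(sp), n_zero, replace = FALSE)
    # 03:00 epochs: outside the generation window, so timestamps are unique
    steps_stream <- rbind(steps_stream, data.table(
      participant_id = sp$participant_id[zi],
      timestamp = day0[zi] + 3 * 3600, steps = 0L))
  }

  ## ---- sleep records ----
  sl <- sim$panels$sleep[!is.na(duration_h)]
  sl[, duration_h := pmin(10, pmax(3.05, duration_h))]
  n_sl <- nrow(sl)
  onset <- as.POSIXct(paste(sl$night_date, "21:00:00"), tz = "UTC") +
    pmin(2.4, pmax(-3.4, rnorm(n_sl, 0, 0.7))) * 3600
  waso_min <- round(abs(rnorm(n_sl, 36, 20)))
  split <- runif(n_sl) < config$sleep_split_prob & sl$duration_h >= 7
  rec <- vector("list", n_sl)
  for (i in seq_len(n_sl)) {
    if (split[i]) {
      d1 <- sl$duration_h[i] * 0.5
      d2 <- sl$duration_h[i] - d1
      w1 <- waso_min[i] * 0.3
      gap <- waso_min[i] * 0.4
      w2 <- waso_min[i] - w1 - gap
      off1 <- onset[i] + (d1 + w1 / 60) * 3600
      on2 <- off1 + gap * 60
      rec[[i]] <- data.table(
        participant_id = sl$participant_id[i],
        onset = c(onset[i], on2),
        offset = c(off1, on2 + (d2 + w2 / 60) * 3600),
        duration_h = c(d1, d2), waso_min = c(w1, w2))
    } else {
      rec[[i]] <- data.table(
        participant_id = sl$participant_id[i], onset = onset[i],
        offset = onset[i] + (sl$duration_h[i] + waso_min[i] / 60) * 3600,
        duration_h = sl$duration_h[i], waso_min = as.numeric(waso_min[i]))
    }
  }
  sleep_stream <- rbindlist(rec)

  n_ov <- as.integer(round(vi[["sleep_overlap"]] * n_sl))
  ov_idx <- if (n_ov > 0) sample(which(!split), min(n_ov, sum(!split))) else integer()
  if (length(ov_idx)) {
    extra <- data.table(
      participant_id = sl$participant_id[ov_idx],
      onset = onset[ov_idx] + 3600,
      offset = onset[ov_idx] + 4.5 * 3600,
      duration_h = 3.0, waso_min = 15)
    sleep_stream <- rbind(sleep_stream, extra)
  }
  n_short <- as.integer(round(vi[["sleep_short"]] * n_sl))
  sh_pool <- setdiff(seq_len(n_sl), ov_idx)
  sh_idx <- if (n_short > 0) sample(sh_pool, min(n_short, length(sh_pool))) else integer()
  if (length(sh_idx)) {
    short <- data.table(
      participant_id = sl$participant_id[sh_idx],
      onset = as.POSIXct(paste(sl$night_date[sh_idx], "17:10:00"), tz = "UTC"),
      offset = as.POSIXct(paste(sl$night_date[sh_idx], "19:40:00"), tz = "UTC"),
      duration_h = 2.2, waso_min = 5)
    sleep_stream <- rbind(sleep_stream, short)
  }

  ## ---- heart-rate samples ----
  hrp <- sim$panels$hr[!is.na(nightly_hr)]
  hr_ages <- merge(hrp[, .(participant_id, night_date, nightly_hr)],
                   pts[, .(participant_id, age)], by = "participant_id")
  slots <- seq(0, 7.75, by = 0.25)  # 22:00 .. 05:45 relative to 22:00
  hr_stream <- hr_ages[, {
    night0 <- as.POSIXct(paste(night_date, "22:00:00"), tz = "UTC")
    bpm <- round(pmin(max_hr(age) - 5, pmax(40, nightly_hr +
                                              rnorm(length(slots), 0, 2))))
    .(timestamp = night0 + slots * 3600, bpm = bpm)
  }, by = .(participant_id, night_date)][, .(participant_id, timestamp, bpm)]

  n_spike <- as.integer(round(vi[["hr_spike"]] * nrow(hr_stream)))
  if (n_spike > 0) {
    si <- sample(nrow(hr_ages), n_spike, replace = TRUE)
    spike_ts <- as.POSIXct(paste(hr_ages$night_date[si], "14:00:00"),
                           tz = "UTC") + seq_len(n_spike)  # unique seconds
    hr_stream <- rbind(hr_stream, data.table(
      participant_id = hr_ages$participant_id[si],
      timestamp = spike_ts,
      bpm = max_hr(hr_ages$age[si]) + 15))
  }
  n_dup_hr <- as.integer(round(vi[["dup_hr"]] * nrow(hr_stream)))
  if (n_dup_hr > 0)
    hr_stream <- rbind(hr_stream,
                       hr_stream[sample(.N, n_dup_hr, replace = FALSE)])

  ledger <- rbindlist(list(
    data.table(stream = "steps", reason = "duplicate", n = n_dup_steps),
    data.table(stream = "steps", reason = "zero_steps", n = n_zero),
    data.table(stream = "sleep", reason = "overlap", n = 2L * length(ov_idx)),
    data.table(stream = "sleep", reason = "short_span", n = length(sh_idx)),
    data.table(stream = "hr", reason = "hr_ceiling", n = n_spike),
    data.table(stream = "hr", reason = "duplicate", n = n_dup_hr)
  ))[n > 0]

  clean_nights <- sl[setdiff(seq_len(n_sl), ov_idx),
                     .(participant_id, night_date, duration_h)]
  list(steps = steps_stream[], sleep = sleep_stream[], hr = hr_stream[],
       ledger = ledger[], clean_nights = clean_nights[], sim = sim)
}

#' Simulate every pipeline input and write it as CSV
#'
#' Writes the weather, coordinate, roster and wearable-stream CSVs the
#' pipeline consumes, plus ground-truth files (true effects, intercepts,
#' violation ledger) for recovery testing. Byte-identical for identical
#' (config, seed).
#'
#' @param config A [sim_config()].
#' @param seed Integer seed.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the list of written file paths.
#' @export
simulate_all <- function(config, seed, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  raw <- simulate_outcomes(config, seed)
  sim <- raw$sim
  fmt_ts <- function(x) format(x, "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  p <- function(f) file.path(out_dir, f)

  wx <- simulate_weather(config, seed)
  wx_out <- copy(wx)[, timestamp := fmt_ts(timestamp)]
  fwrite(wx_out, p("weather.csv"))
  fwrite(sim$cohort$stations, p("stations.csv"))
  fwrite(sim$cohort$villages, p("villages.csv"))
  fwrite(sim$cohort$roster, p("roster.csv"))
  st <- copy(raw$steps)[, timestamp := fmt_ts(timestamp)]
  fwrite(st, p("steps.csv"))
  sl <- copy(raw$sleep)[, `:=`(onset = fmt_ts(onset), offset = fmt_ts(offset))]
  fwrite(sl, p("sleep.csv"))
  hr <- copy(raw$hr)[, timestamp := fmt_ts(timestamp)]
  fwrite(hr, p("hr.csv"))
  fwrite(raw$ledger, p("truth_violations.csv"))
  fwrite(sim$cohort$intercepts, p("truth_intercepts.csv"))
  eff <- rbindlist(lapply(names(config$effects), function(oc)
    data.table(outcome = oc, term = names(config$effects[[oc]]),
               value = unlist(config$effects[[oc]]))))
  fwrite(eff, p("truth_effects.csv"))
  invisible(list.files(out_dir, full.names = TRUE))
}
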