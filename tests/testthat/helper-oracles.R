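# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's vectorised implementations: scalar loops, naive scans
# and direct re-derivations only.

ts_utc <- function(x) as.POSIXct(x, tz = "UTC")

# --- NWS heat index, independent scalar re-evaluation (Fahrenheit in/out) ---
oracle_hi_f <- function(t_f, rh) {
  hi <- 0.5 * (t_f + 61.0 + (t_f - 68.0) * 1.2 + rh * 0.094)
  if (hi >= 80) {
    co <- c(-42.379, 2.04901523, 10.14333127, -0.22475541, -0.00683783,
            -0.05481717, 0.00122874, 0.00085282, -0.00000199)
    hi <- co[1] + co[2] * t_f + co[3] * rh + co[4] * t_f * rh +
      co[5] * t_f^2 + co[6] * rh^2 + co[7] * t_f^2 * rh +
      co[8] * t_f * rh^2 + co[9] * t_f^2 * rh^2
    if (rh < 13 && t_f >= 80 && t_f <= 112)
      hi <- hi - ((13 - rh) / 4) * sqrt((17 - abs(t_f - 95)) / 17)
    if (rh > 85 && t_f >= 80 && t_f <= 87)
      hi <- hi + ((rh - 85) / 10) * ((87 - t_f) / 5)
  }
  hi
}
oracle_hi_c <- function(t_c, rh) (oracle_hi_f(t_c * 1.8 + 32, rh) - 32) / 1.8

# --- wear time: union of bridged [t, t + 15 min) intervals, minute scan ---
oracle_wear_hours <- function(times) {
  if (length(times) == 0) return(0)
  t <- sort(as.numeric(times))
  total <- 0
  bout_start <- t[1]
  prev <- t[1]
  for (x in t[-1]) {
    if (x - prev > 3600) {
      total <- total + (prev - bout_start) + 900
      bout_start <- x
    }
    prev <- x
  }
  total + (prev - bout_start) + 900
}

# --- 15-min binning by string key ---
oracle_bin_steps <- function(epochs) {
  key <- format(ts_utc(epochs$timestamp), "%Y-%m-%d %H")
  qmin <- (as.integer(format(ts_utc(epochs$timestamp), "%M")) %/% 15) * 15
  full <- paste(key, sprintf("%02d", qmin))
  agg <- tapply(epochs$steps, paste(epochs$participant_id, full), sum)
  sort(as.vector(agg))
}

# --- sleep merge: naive per-night interval logic mirroring the stated rules ---
oracle_clean_sleep <- function(records) {
  records <- as.data.frame(records)
  records$onset <- ts_utc(records$onset)
  records$offset <- ts_utc(records$offset)
  out <- list()
  hfrac <- function(t) as.integer(format(t, "%H")) +
    as.integer(format(t, "%M")) / 60 + as.integer(format(t, "%S")) / 3600
  for (pid in unique(records$participant_id)) {
    rr <- records[records$participant_id == pid & records$offset > records$onset, ]
    oh <- hfrac(rr$onset)
    night <- as.Date(ifelse(oh >= 17, as.Date(rr$onset, tz = "UTC"),
                            as.Date(rr$onset, tz = "UTC") - 1),
                     origin = "1970-01-01")
    ok <- (oh >= 17 | oh <= 13) &
      rr$offset <= ts_utc(paste(night + 1, "13:00:00"))
    rr <- rr[ok, ]; night <- night[ok]
    span <- as.numeric(difftime(rr$offset, rr$onset, units = "hours"))
    rr <- rr[span >= 3, ]; night <- night[span >= 3]
    for (nd in unique(night)) {
      sub <- rr[night == nd, ]
      sub <- sub[order(sub$onset), ]
      if (nrow(sub) > 1) {
        bad <- rep(FALSE, nrow(sub))
        for (i in 1:(nrow(sub) - 1)) for (j in (i + 1):nrow(sub))
          if (sub$onset[j] < sub$offset[i]) bad[c(i, j)] <- TRUE
        sub <- sub[!bad, ]
      }
      if (nrow(sub) == 0) next
      gaps <- if (nrow(sub) > 1)
        sum(as.numeric(difftime(sub$onset[-1], sub$offset[-nrow(sub)],
                                units = "mins"))) else 0
      out[[length(out) + 1]] <- data.frame(
        participant_id = pid, night_date = as.Date(nd, origin = "1970-01-01"),
        duration_h = sum(sub$duration_h),
        onset = min(sub$onset), offset = max(sub$offset),
        waso_min = sum(sub$waso_min) + gaps)
    }
  }
  res <- do.call(rbind, out)
  res[order(res$participant_id, res$night_date), ]
}

# --- extreme index counts by scalar filter-and-count ---
oracle_extremes <- function(daily) {
  daily <- as.data.frame(daily)
  cnt <- function(x, f) sum(!is.na(x) & f(x))
  list(heavy_rain_days = cnt(daily$rain_total, function(x) x >= 20),
       tropical_nights = cnt(daily$tmin_night, function(x) x > 20),
       hot_days = cnt(daily$tmax_day, function(x) x >= 35),
       heat_stress_days = cnt(daily$wbgt_max_day, function(x) x >= 30),
       heat_stress_nights = cnt(daily$hi_min_night, function(x) x >= 25))
}

# --- day/night window scan for one station-date ---
oracle_day_summary <- function(obs, date) {
  obs <- as.data.frame(obs)
  obs$timestamp <- ts_utc(obs$timestamp)
  date <- as.Date(date)
  day_lo <- ts_utc(paste(date, "06:00:00"))
  day_hi <- ts_utc(paste(date, "22:00:00"))
  night_hi <- ts_utc(paste(date + 1, "06:00:00"))
  in_day <- obs$timestamp >= day_lo & obs$timestamp < day_hi
  in_night <- obs$timestamp >= day_hi & obs$timestamp < night_hi
  in_date <- as.Date(obs$timestamp, tz = "UTC") == date
  mx <- function(x) if (length(x) == 0) NA_real_ else max(x)
  mn <- function(x) if (length(x) == 0) NA_real_ else min(x)
  list(tmax_day = mx(obs$air_temp_c[in_day]),
       tmin_night = mn(obs$air_temp_c[in_night]),
       rain_total = sum(obs$precip_mm[in_date]))
}

# small fixture: a cleaned-feeling panel with known linear structure
make_toy_panel <- function(n_id = 10, n_day = 15, b0 = 7, b_heat = -0.05,
                           b_rain = 0.02, sd_id = 0.5, sd_e = 0.3,
                           seed = 99) {
  set.seed(seed)
  g <- expand.grid(participant_id = sprintf("P%02d", seq_len(n_id)),
                   day = seq_len(n_day), stringsAsFactors = FALSE)
  g$hi_min_night <- runif(nrow(g), 18, 30)
  g$rain_total <- rgamma(nrow(g), 0.5, scale = 8) * rbinom(nrow(g), 1, 0.3)
  u <- rnorm(n_id, 0, sd_id)
  names(u) <- sprintf("P%02d", seq_len(n_id))
  g$duration_h <- b0 + b_heat * g$hi_min_night + b_rain * g$rain_total +
    u[g$participant_id] + rnorm(nrow(g), 0, sd_e)
  data.table::as.data.table(g)
}
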