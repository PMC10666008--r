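# Weather-station processing: heat metrics, day/night exposure windows,
# climate extreme indices and nearest-station assignment.

#' Exposure thresholds
#'
#' Single source of truth for every exposure cut-off used by the pipeline.
#' Boundary semantics follow the Climpact-style index definitions: inclusive
#' (`>=`) for heavy rain, hot days and WBGT/HI heat stress; strictly greater
#' (`>`) for tropical nights.
#'
#' @param heavy_rain_mm Daily rainfall total defining a heavy-precipitation
#'   day (mm, inclusive). Default 20.
#' @param hot_day_c Daily maximum air temperature defining a hot day
#'   (deg C, inclusive). Default 35.
#' @param tropical_night_c Nightly minimum air temperature defining a
#'   tropical night (deg C, strict). Default 20.
#' @param heat_stress_day_wbgt_c Daily maximum WBGT defining a heat stress
#'   day (deg C, inclusive). Default 30.
#' @param heat_stress_night_hi_c Nightly minimum heat index defining a heat
#'   stress night (deg C, inclusive). Default 25.
#' @param day_start_hour,night_start_hour Clock hours bounding the daytime
#'   window `[day_start, night_start)`; the night labelled with date `d`
#'   spans `d night_start` to `d+1 day_start`. Defaults 6 and 22.
#' @return A named list of thresholds.
#' @export
weather_thresholds <- function(heavy_rain_mm = 20,
                               hot_day_c = 35,
                               tropical_night_c = 20,
                               heat_stress_day_wbgt_c = 30,
                               heat_stress_night_hi_c = 25,
                               day_start_hour = 6,
                               night_start_hour = 22) {
  stopifnot(day_start_hour < night_start_hour)
  list(
    heavy_rain_mm = heavy_rain_mm,
    hot_day_c = hot_day_c,
    tropical_night_c = tropical_night_c,
    heat_stress_day_wbgt_c = heat_stress_day_wbgt_c,
    heat_stress_night_hi_c = heat_stress_night_hi_c,
    day_start_hour = day_start_hour,
    night_start_hour = night_start_hour
  )
}

#' Season of a calendar month
#'
#' Maps months to the three local seasons: rainy (June-September), cool dry
#' (October-January) and hot dry (February-May).
#'
#' @param month Integer month(s) in 1..12.
#' @return Character vector in `c("rainy", "cool_dry", "hot_dry")`.
#' @export
season_of <- function(month) {
  if (any(is.na(month)) || !all(month %in% 1:12))
    stop("`month` must be integers in 1..12")
  out <- character(length(month))
  out[month %in% 6:9] <- "rainy"
  out[month %in% c(10:12, 1)] <- "cool_dry"
  out[month %in% 2:5] <- "hot_dry"
  out
}

.check_coords <- function(lat, lon) {
  if (any(!is.finite(lat)) || any(!is.finite(lon)) ||
      any(lat < -90 | lat > 90) || any(lon < -180 | lon > 180))
    stop("coordinates out of bounds: latitude in [-90,90], longitude in [-180,180]")
  invisible(TRUE)
}

#' Geodesic distance on the WGS 84 ellipsoid
#'
#' Shortest distance between two points on the WGS 84 ellipsoid (not a
#' sphere), in kilometres.
#'
#' @param lat1,lon1,lat2,lon2 Coordinates in decimal degrees; vectorised.
#' @return Distance(s) in kilometres.
#' @export
geodesic_distance <- function(lat1, lon1, lat2, lon2) {
  .check_coords(lat1, lon1)
  .check_coords(lat2, lon2)
  geosphere::distGeo(cbind(lon1, lat1), cbind(lon2, lat2)) / 1000
}

#' Assign the nearest weather station to each village
#'
#' @param villages data.frame with columns `village_id`, `lat`, `lon`.
#' @param stations data.frame with columns `station_id`, `lat`, `lon`.
#' @return data.table of `village_id`, `station_id`, `distance_km`. Ties are
#'   broken by lexicographic station id.
#' @export
assign_nearest_station <- function(villages, stations) {
  stations <- as.data.table(stations)
  villages <- as.data.table(villages)
  if (nrow(stations) == 0L) stop("at least one station is required")
  # order stations by id so which.min's first-hit rule implements the tie-break
  stations <- stations[order(as.character(station_id))]
  res <- villages[, {
    d <- geodesic_distance(lat, lon, stations$lat, stations$lon)
    i <- which.min(d)
    .(station_id = as.character(stations$station_id[i]), distance_km = d[i])
  }, by = village_id]
  res[]
}

.c_to_f <- function(c) c * 9 / 5 + 32
.f_to_c <- function(f) (f - 32) * 5 / 9

#' NWS heat index
#'
#' Apparent temperature from air temperature and relative humidity following
#' the US National Weather Service algorithm: the Rothfusz regression with
#' the published low-humidity and high-humidity adjustments, and the simple
#' formula for mild conditions. Computation is Fahrenheit-native internally;
#' inputs and outputs are in degrees Celsius, kept at full precision (round
#' on output where a fixed precision is needed).
#'
#' The simple branch is `0.5 * (T + 61 + (T - 68) * 1.2 + RH * 0.094)`
#' (already an average with the air temperature); the full regression is
#' applied when that value reaches 80 deg F.
#'
#' @param air_temp_c Air temperature, deg C; vectorised.
#' @param rel_humidity_pct Relative humidity in percent, within [0, 100].
#' @return Heat index in deg C; `NA` inputs propagate to `NA`.
#' @export
heat_index <- function(air_temp_c, rel_humidity_pct) {
  if (any(rel_humidity_pct < 0 | rel_humidity_pct > 100, na.rm = TRUE))
    stop("relative humidity must be within [0, 100]")
  t_f <- .c_to_f(air_temp_c)
  rh <- rel_humidity_pct
  simple <- 0.5 * (t_f + 61 + (t_f - 68) * 1.2 + rh * 0.094)
  hi <- simple
  use_full <- !is.na(simple) & simple >= 80
  if (any(use_full)) {
    tf <- t_f[use_full]
    rf <- rh[use_full]
    full <- -42.379 + 2.04901523 * tf + 10.14333127 * rf -
      0.22475541 * tf * rf - 6.83783e-3 * tf^2 - 5.481717e-2 * rf^2 +
      1.22874e-3 * tf^2 * rf + 8.5282e-4 * tf * rf^2 - 1.99e-6 * tf^2 * rf^2
    low_rh <- rf < 13 & tf >= 80 & tf <= 112
    full[low_rh] <- full[low_rh] -
      ((13 - rf[low_rh]) / 4) * sqrt((17 - abs(tf[low_rh] - 95)) / 17)
    high_rh <- rf > 85 & tf >= 80 & tf <= 87
    full[high_rh] <- full[high_rh] +
      ((rf[high_rh] - 85) / 10) * ((87 - tf[high_rh]) / 5)
    hi[use_full] <- full
  }
  .f_to_c(hi)
}

#' Psychrometric wet-bulb temperature (Stull 2011)
#'
#' Empirical wet-bulb estimate from air temperature and relative humidity,
#' valid for RH above roughly 5% at standard pressure.
#'
#' @param air_temp_c Air temperature, deg C.
#' @param rel_humidity_pct Relative humidity, percent.
#' @return Wet-bulb temperature, deg C.
#' @export
wet_bulb_stull <- function(air_temp_c, rel_humidity_pct) {
  t <- air_temp_c
  rh <- rel_humidity_pct
  t * atan(0.151977 * sqrt(rh + 8.313659)) + atan(t + rh) -
    atan(rh - 1.676331) + 0.00391838 * rh^1.5 * atan(0.023101 * rh) -
    4.686035
}

# Default natural wet-bulb estimator: psychrometric wet bulb raised by solar
# loading and lowered by ventilation. Monotone non-decreasing in radiation.
.nwb_default <- function(air_temp_c, rel_humidity_pct, global_radiation_wm2,
                         wind_speed_ms) {
  wet_bulb_stull(air_temp_c, rel_humidity_pct) +
    0.0021 * global_radiation_wm2 / (1 + 0.10 * wind_speed_ms)
}

# Default globe-temperature estimator: air temperature plus a radiative
# offset attenuated by wind. Monotone non-decreasing in radiation.
.globe_default <- function(air_temp_c, rel_humidity_pct, global_radiation_wm2,
                           wind_speed_ms) {
  air_temp_c + 0.0175 * global_radiation_wm2 / (1 + 0.35 * wind_speed_ms)
}

#' Outdoor wet-bulb globe temperature estimate
#'
#' Composes the standard outdoor WBGT weighting
#' `0.7 * Tnwb + 0.2 * Tglobe + 0.1 * Tair` from station variables. The
#' natural-wet-bulb and globe sub-estimators are pluggable; the defaults are
#' a Stull (2011) psychrometric wet bulb with a radiation/wind adjustment
#' and a radiation/wind-aware globe offset. Any input `NA` yields `NA`.
#'
#' @param air_temp_c Air temperature, deg C.
#' @param rel_humidity_pct Relative humidity, percent.
#' @param global_radiation_wm2 Global (solar) radiation, W/m^2, >= 0.
#' @param wind_speed_ms Wind speed, m/s, >= 0.
#' @param nwb_fun,globe_fun Sub-estimators with the same four arguments,
#'   returning deg C.
#' @return WBGT estimate, deg C.
#' @export
wbgt_estimate <- function(air_temp_c, rel_humidity_pct, global_radiation_wm2,
                          wind_speed_ms,
                          nwb_fun = .nwb_default,
                          globe_fun = .globe_default) {
  if (any(global_radiation_wm2 < 0, na.rm = TRUE) ||
      any(wind_speed_ms < 0, na.rm = TRUE))
    stop("radiation and wind speed must be non-negative")
  tnwb <- nwb_fun(air_temp_c, rel_humidity_pct, global_radiation_wm2,
                  wind_speed_ms)
  tg <- globe_fun(air_temp_c, rel_humidity_pct, global_radiation_wm2,
                  wind_speed_ms)
  0.7 * tnwb + 0.2 * tg + 0.1 * air_temp_c
}

.as_weather_dt <- function(obs) {
  obs <- as.data.table(obs)
  need <- c("station_id", "timestamp", "air_temp_c", "rel_humidity_pct",
            "precip_mm", "wind_speed_ms", "global_radiation_wm2")
  miss <- setdiff(need, names(obs))
  if (length(miss)) stop("weather observations missing columns: ",
                         paste(miss, collapse = ", "))
  obs[, timestamp := .parse_ts(timestamp)]
  obs
}

#' Daily weather summaries per station
#'
#' Collapses a 15-minute station series into one row per station-date:
#' daytime maxima (air temperature and WBGT over `[06:00, 22:00)`),
#' nighttime minima (air temperature and heat index over `[22:00, 06:00)`
#' of the following day, attributed to the starting date), the calendar-day
#' rainfall total, the season, and the five extreme-weather flags. A window
#' with no observations yields `NA` summary fields and `NA` flags (never
#' false-by-default). No imputation is performed.
#'
#' @param obs Weather observations (`station_id`, `timestamp`, `air_temp_c`,
#'   `rel_humidity_pct`, `precip_mm`, `wind_speed_ms`,
#'   `global_radiation_wm2`).
#' @param thresholds See [weather_thresholds()].
#' @return data.table keyed by `station_id`, `date`.
#' @export
summarize_daily_weather <- function(obs, thresholds = weather_thresholds()) {
  obs <- .as_weather_dt(obs)
  th <- thresholds
  obs <- copy(obs)
  obs[, hi_c := heat_index(air_temp_c, rel_humidity_pct)]
  obs[, wbgt_c := wbgt_estimate(air_temp_c, rel_humidity_pct,
                                global_radiation_wm2, wind_speed_ms)]
  obs[, obs_date := as.Date(timestamp, tz = "UTC")]
  obs[, obs_hour := as.integer(format(timestamp, "%H", tz = "UTC"))]

  day_obs <- obs[obs_hour >= th$day_start_hour & obs_hour < th$night_start_hour]
  day_sum <- day_obs[, .(
    tmax_day = suppressWarnings(max(air_temp_c, na.rm = TRUE)),
    wbgt_max_day = suppressWarnings(max(wbgt_c, na.rm = TRUE))
  ), by = .(station_id, date = obs_date)]

  night_obs <- obs[obs_hour >= th$night_start_hour | obs_hour < th$day_start_hour]
  night_obs[, night_key := fifelse(obs_hour >= th$night_start_hour,
                                   obs_date, obs_date - 1L)]
  night_sum <- night_obs[, .(
    tmin_night = suppressWarnings(min(air_temp_c, na.rm = TRUE)),
    hi_min_night = suppressWarnings(min(hi_c, na.rm = TRUE))
  ), by = .(station_id, date = night_key)]

  rain_sum <- obs[, .(rain_total = sum(precip_mm, na.rm = TRUE)),
                  by = .(station_id, date = obs_date)]

  daily <- merge(merge(day_sum, night_sum, by = c("station_id", "date"),
                       all = TRUE),
                 rain_sum, by = c("station_id", "date"), all = TRUE)
  # empty-window aggregates come back as +/-Inf; those are missing summaries
  for (col in c("tmax_day", "tmin_night", "wbgt_max_day", "hi_min_night"))
    set(daily, which(!is.finite(daily[[col]])), col, NA_real_)

  daily[, season := season_of(as.integer(format(date, "%m")))]
  daily[, is_heavy_rain_day := rain_total >= th$heavy_rain_mm]
  daily[, is_hot_day := tmax_day >= th$hot_day_c]
  daily[, is_tropical_night := tmin_night > th$tropical_night_c]
  daily[, is_heat_stress_day := wbgt_max_day >= th$heat_stress_day_wbgt_c]
  daily[, is_heat_stress_night := hi_min_night >= th$heat_stress_night_hi_c]
  setkey(daily, station_id, date)
  daily[]
}

#' Single-date daily weather summary
#'
#' Convenience wrapper around [summarize_daily_weather()] for one
#' station-date.
#'
#' @param obs Observations for one station.
#' @param date The calendar date to summarise.
#' @param thresholds See [weather_thresholds()].
#' @return One-row data.table (all-`NA` summary fields when no observation
#'   falls in any window of that date).
#' @export
daily_weather_summary <- function(obs, date, thresholds = weather_thresholds()) {
  target <- as.Date(date)
  daily <- summarize_daily_weather(obs, thresholds)
  out <- daily[daily$date == target]
  if (nrow(out) == 0L) {
    out <- daily[1L][, names(daily) := NA]
    out[, `:=`(station_id = unique(daily$station_id)[1], date = target,
               season = season_of(as.integer(format(target, "%m"))))]
  }
  out[]
}

#' Extreme-weather index counts
#'
#' Counts, over a daily summary series, the five extreme indices: heavy
#' precipitation days (rain total >= 20 mm), tropical nights (night minimum
#' air temperature strictly > 20 deg C), hot days (day maximum air
#' temperature >= 35 deg C), heat stress days (day maximum WBGT >= 30 deg C)
#' and heat stress nights (night minimum heat index >= 25 deg C). Days whose
#' flag is missing (no observation in the window) do not count.
#'
#' @param daily Output of [summarize_daily_weather()] (only the summary
#'   value columns are used; counts are recomputed from the thresholds, the
#'   single source of the boundary semantics).
#' @param thresholds See [weather_thresholds()].
#' @return Named list of five integer counts.
#' @export
extreme_indexes <- function(daily, thresholds = weather_thresholds()) {
  daily <- as.data.table(daily)
  th <- thresholds
  cnt <- function(x) sum(x, na.rm = TRUE)
  list(
    heavy_rain_days = cnt(daily$rain_total >= th$heavy_rain_mm),
    tropical_nights = cnt(daily$tmin_night > th$tropical_night_c),
    hot_days = cnt(daily$tmax_day >= th$hot_day_c),
    heat_stress_days = cnt(daily$wbgt_max_day >= th$heat_stress_day_wbgt_c),
    heat_stress_nights = cnt(daily$hi_min_night >= th$heat_stress_night_hi_c)
  )
}
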