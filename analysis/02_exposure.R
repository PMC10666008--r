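#!/usr/bin/env Rscript
# Stage 2 — weather exposure processing.
#
# Collapses the 15-min station series into daily summaries (daytime WBGT
# maximum, nighttime heat-index minimum, rainfall totals, extreme-weather
# flags) and tabulates the five climate extreme indices per station and
# season.

suppressMessages(library(heatwear))
suppressMessages(library(data.table))

wx <- fread("scratch/analysis/input/weather.csv")
daily <- summarize_daily_weather(wx)
dir.create("results", showWarnings = FALSE)
fwrite(daily, "results/daily_weather.csv")

idx <- daily[, c(extreme_indexes(.SD)), by = .(station_id, season)]
fwrite(idx, "results/extreme_indexes.csv")

cat("Daily weather summaries:", nrow(daily), "station-days\n\n")
cat("Seasonal means across stations:\n")
print(daily[, .(mean_tmax = round(mean(tmax_day, na.rm = TRUE), 1),
                mean_wbgt_max = round(mean(wbgt_max_day, na.rm = TRUE), 1),
                mean_hi_min = round(mean(hi_min_night, na.rm = TRUE), 1),
                rain_mm_day = round(mean(rain_total, na.rm = TRUE), 1)),
            by = season])
cat("\nExtreme indices (totals across stations):\n")
print(idx[, lapply(.SD, sum), by = season,
          .SDcols = c("heavy_rain_days", "tropical_nights", "hot_days",
                      "heat_stress_days", "heat_stress_nights")])
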