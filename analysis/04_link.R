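#!/usr/bin/env Rscript
# Stage 4 — exposure linkage.
#
# Assigns each village its nearest weather station (WGS 84 geodesic
# distance), attaches demographic covariates, and joins each cleaned
# outcome to its station's daily exposures: WBGT_max for daily activity,
# HI_min and the night window for sleep and nighttime heart rate, rainfall
# for both.

suppressMessages(library(heatwear))
suppressMessages(library(data.table))

ind <- "scratch/analysis/input"
daily <- fread("results/daily_weather.csv")
roster <- fread(file.path(ind, "roster.csv"))
pts <- derive_covariates(roster, as.Date("2021-08-01"))
vs <- assign_nearest_station(fread(file.path(ind, "villages.csv")),
                             fread(file.path(ind, "stations.csv")))
pts <- merge(pts, vs[, .(village_id, station_id)], by = "village_id")

cat("Village-station assignment (distances in km):\n")
print(vs[, .(mean_km = round(mean(distance_km), 1),
             max_km = round(max(distance_km), 1))])

panels <- list(
  steps = build_panel(fread("scratch/analysis/steps_daily.csv"), daily, pts,
                      type = "day"),
  sleep = build_panel(fread("scratch/analysis/sleep_nights.csv"), daily, pts,
                      type = "night"),
  hr = build_panel(fread("scratch/analysis/hr_nightly.csv"), daily, pts,
                   type = "night"))

for (nm in names(panels)) {
  fwrite(panels[[nm]], sprintf("scratch/analysis/panel_%s.csv", nm))
  cat(sprintf("panel_%s: %d rows, %d participants\n", nm,
              nrow(panels[[nm]]), uniqueN(panels[[nm]]$participant_id)))
}
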