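#!/usr/bin/env Rscript
# Stage 3 — wearable quality control.
#
# Cleans the three wearable streams with the study's filters (duplicate and
# zero-step removal, the 10-hour wear-time filter, the 17:00-13:00 sleep
# window with 3-hour minimum span, overlap exclusion and night merging, the
# Tanaka heart-rate ceiling and day/night coverage rules), then reconciles
# the exclusion tallies against the generator's injected-violation ledger.

suppressMessages(library(heatwear))
suppressMessages(library(data.table))

ind <- "scratch/analysis/input"
roster <- fread(file.path(ind, "roster.csv"))
pts <- derive_covariates(roster, as.Date("2021-08-01"))

steps <- clean_steps(fread(file.path(ind, "steps.csv")))
steps_daily <- daily_steps(steps)
nights <- clean_sleep(fread(file.path(ind, "sleep.csv")))
hr <- clean_hr(fread(file.path(ind, "hr.csv")), pts[, .(participant_id, age)])

report <- qc_report(steps = steps, sleep = nights, hr = hr$exclusions)
fwrite(steps_daily, "scratch/analysis/steps_daily.csv")
fwrite(nights, "scratch/analysis/sleep_nights.csv")
fwrite(hr$nightly, "scratch/analysis/hr_nightly.csv")
fwrite(report, "results/qc_report.csv")

cat("QC results:\n")
cat("  analysis-ready participant-days (steps):", nrow(steps_daily), "\n")
cat("  analysis-ready participant-nights (sleep):", nrow(nights), "\n")
cat("  analysis-ready participant-nights (HR):", nrow(hr$nightly), "\n\n")
cat("Exclusions by reason:\n")
print(report)

ledger <- fread(file.path(ind, "truth_violations.csv"))
merged <- merge(report, ledger, by = c("stream", "reason"),
                suffixes = c("_qc", "_injected"), all = TRUE)
cat("\nReconciliation against the injected-violation ledger",
    if (isTRUE(all.equal(merged$n_qc, merged$n_injected))) "(exact match):\n"
    else "(MISMATCH):\n")
print(merged)

# insufficient-sleep share, by the age-specific thresholds
ns <- merge(nights, pts[, .(participant_id, age)], by = "participant_id")
ins <- ns[, mean(flag_insufficient_sleep(duration_h, age))]
cat(sprintf("\nNights with insufficient sleep: %.1f%%\n", 100 * ins))
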