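#!/usr/bin/env Rscript
# Stage 1 — generate the synthetic study world.
#
# Writes every raw input the pipeline consumes (15-min weather series for 5
# stations, village/station coordinates, a 60-participant roster, and the
# wearable streams: step epochs, sleep records, heart-rate samples) plus the
# ground-truth files (true effects, true random intercepts, the injected
# QC-violation ledger). Raw streams are large and reproducible, so they go
# under scratch/, not results/.

suppressMessages(library(heatwear))

seed <- 42
cfg <- sim_config()  # the default study conditions
out <- "scratch/analysis/input"

files <- simulate_all(cfg, seed, out)
cat("Simulated study world (seed", seed, "):\n")
cat("  participants:", cfg$n_participants, "| study days:", cfg$study_days,
    "| stations:", cfg$n_stations, "\n")
cat("  true sleep heat slope:", cfg$effects$sleep$heat, "h per deg C HI_min\n")
cat("  true activity response: ", cfg$effects$steps$heat, " * WBGT ",
    cfg$effects$steps$heat2, " * WBGT^2 (peak at ",
    round(-cfg$effects$steps$heat / (2 * cfg$effects$steps$heat2), 1),
    " deg C)\n", sep = "")
cat("  files written to", out, ":\n")
for (f in files) cat("   ", basename(f), "\n")
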