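#!/usr/bin/env Rscript
# Stage 5 — mixed-effects exposure-response models.
#
# For each outcome: test for curvature in the heat response (quadratic term
# by likelihood-ratio test), select adjustment covariates stepwise
# (month, weekend, age group, sex, BMI group; chi-square LRT at 5%), report
# the coefficient table with marginal heat effects at 20 and 30 deg C,
# compare the WBGT/HI model against a bare-temperature model by AIC, fit
# the binary extreme-weather contrast, test subgroup interactions, and
# cross-validate with leave-one-subject-out.

suppressMessages(library(heatwear))
suppressMessages(library(data.table))

jobs <- list(
  steps = list(outcome = "steps", heat = "wbgt_max_day", alt = "tmax_day",
               flag = "is_heat_stress_day"),
  sleep = list(outcome = "duration_h", heat = "hi_min_night",
               alt = "tmin_night", flag = "is_heat_stress_night"),
  hr = list(outcome = "nightly_hr", heat = "hi_min_night",
            alt = "tmin_night", flag = "is_heat_stress_night"))

for (nm in names(jobs)) {
  j <- jobs[[nm]]
  pan <- fread(sprintf("scratch/analysis/panel_%s.csv", nm))
  pan[, month := factor(month, levels = month.abb)]
  if (uniqueN(pan$participant_id) < 3) {
    cat("==", nm, ": too few participants after QC; skipped\n")
    next
  }
  cat("\n==", nm, "(", nrow(pan), "rows ) ==\n")

  base <- model_spec(j$outcome, j$heat)
  quad <- add_quadratic_if_curved(base, pan)
  cat("quadratic heat term:", if (quad$spec$quadratic) "kept" else "not needed",
      sprintf("(LRT p = %.3g)\n", quad$lrt$p))

  sel <- stepwise_build(quad$spec, pan)
  cat("covariates retained:",
      if (length(sel$spec$covariates)) paste(sel$spec$covariates, collapse = ", ")
      else "none", "\n")
  fwrite(sel$trail, sprintf("results/model_%s_lrt_trail.csv", nm))
  fwrite(sel$fit$coefficients, sprintf("results/model_%s_coefficients.csv", nm))

  co <- sel$fit$coefficients
  b1 <- co[term == j$heat, estimate]
  b2 <- if (sel$spec$quadratic) co[term == sprintf("I(%s^2)", j$heat), estimate] else 0
  cat(sprintf("heat effect: %+.4g per deg C at 20 C, %+.4g at 30 C\n",
              marginal_effect(b1, b2, 20), marginal_effect(b1, b2, 30)))

  cmp <- compare_heat_metrics(sel$spec, pan, c(j$heat, j$alt))
  fwrite(cmp, sprintf("results/model_%s_aic_comparison.csv", nm))
  cat("heat metric ranking by AIC:", paste(cmp$metric, collapse = " < "),
      sprintf("(delta AIC = %.1f)\n", cmp$delta_aic[2]))

  ext <- try(extreme_contrast(sel$spec, pan, j$flag), silent = TRUE)
  if (!inherits(ext, "try-error")) {
    fwrite(ext$coefficients, sprintf("results/model_%s_extremes.csv", nm))
    fl <- ext$coefficients[grepl(j$flag, term)]
    cat(sprintf("extreme contrast (%s): %+.4g [%.4g, %.4g]\n",
                j$flag, fl$estimate, fl$ci_lo, fl$ci_hi))
  }

  for (fac in c("sex", "age_group")) {
    sg <- try(subgroup_sensitivity(sel$spec, pan, fac), silent = TRUE)
    if (inherits(sg, "try-error")) next
    cat(sprintf("interaction heat x %s: %s (LRT p = %.3g)\n", fac,
                if (sg$interaction_kept) "significant" else "not significant",
                sg$lrt$p))
    if (sg$interaction_kept)
      fwrite(sg$table, sprintf("results/model_%s_subgroups_%s.csv", nm, fac))
  }

  cv <- loso_cv(sel$spec, pan)
  fwrite(cv$folds, sprintf("results/model_%s_loso.csv", nm))
  cat(sprintf("LOSO: mean R2 = %.2f (max %.2f), mean RMSE = %.3g\n",
              cv$mean_r2, max(cv$folds$r2, na.rm = TRUE), cv$mean_rmse))
}
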