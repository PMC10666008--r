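---
title: "Linking wearable health outcomes to heat and rainfall exposure: methods"
author: "heatwear"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linking wearable health outcomes to heat and rainfall exposure: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(heatwear)
library(data.table)
```

## The problem

Consumer wearables make it possible to observe, day by day, how rural
populations in hot climates respond to weather: do people walk less on very
hot or very wet days, sleep less on hot nights, and show elevated nighttime
heart rate under heat stress? `heatwear` implements the full analysis
pipeline for such a panel study — weather-station processing, wearable
quality control, exposure linkage and mixed-effects exposure-response
modelling — together with a synthetic-data generator with known ground
truth, so that every stage is testable without access to field data.

The study design it targets is a single-timezone rural region (the defaults
describe a West African setting with one rainy season) observed by a small
network of weather stations at 15-minute resolution, and a cohort wearing
wrist devices continuously for months. All timestamps are local time,
ISO-8601, without offsets.

## Exposure metrics

Two heat metrics are computed per 15-minute interval and summarised per
day:

* **Heat index (HI)** — apparent temperature from air temperature and
  relative humidity, following the US National Weather Service algorithm:
  the Rothfusz regression with the published low-humidity and
  high-humidity adjustments, and the simple formula
  `0.5 (T + 61 + 1.2 (T - 68) + 0.094 RH)` (Fahrenheit) below the 80 °F
  switch point. Computation is Fahrenheit-native internally; values are
  converted at the boundary and kept at full precision (round to 0.1 °C on
  presentation output only).
* **Wet-bulb globe temperature (WBGT)** — the outdoor composite
  `0.7 T_nwb + 0.2 T_g + 0.1 T_a`. Because standard stations do not carry
  black-globe or natural-wet-bulb sensors, the two sub-estimators are
  approximations and are *pluggable* (`nwb_fun`, `globe_fun` arguments).
  The defaults are the Stull (2011) psychrometric wet bulb plus a solar
  loading term damped by wind, `T_w + 0.0021 S / (1 + 0.1 v)`, and a globe
  offset `T_a + 0.0175 S / (1 + 0.35 v)` with `S` in W/m² and `v` in m/s.
  Only the composition weights and monotonicity (WBGT never decreases with
  radiation) are contractual; the sub-formula constants are documented
  choices that a user can replace.

Days run 06:00–22:00 and the night labelled with date *d* runs *d* 22:00 to
*d*+1 06:00, matching the cohort's median sleep timing rounded to the hour.
Daily activity is paired with the daytime WBGT maximum; sleep and nighttime
heart rate with the nighttime HI minimum (people are mostly indoors at
night, where a radiation-based metric is less appropriate). Rainfall is the
calendar-day total, also for night outcomes (the night of date *d* is paired
with day *d*'s rainfall; the alternative, a preceding-24-hour window, was
considered and rejected for simplicity and reproducibility).

Five extreme-weather indices are counted with exactly these boundary
semantics, encoded once in `weather_thresholds()`:

| index | rule |
|---|---|
| heavy precipitation day | rain total ≥ 20 mm |
| hot day | day max air temperature ≥ 35 °C |
| tropical night | night min air temperature **>** 20 °C (strict) |
| heat stress day | day max WBGT ≥ 30 °C |
| heat stress night | night min HI ≥ 25 °C |

A day or night window with zero observations yields missing summary fields
and *missing* flags — never false-by-default — and nothing is imputed.

## Wearable quality control

Each cleaning rule carries a machine-readable reason code so exclusion
tallies can be audited (`duplicate`, `zero_steps`, `window`, `short_span`,
`overlap`, `hr_ceiling`):

* **Steps.** Duplicate (participant, timestamp) epochs collapse to one;
  zero-step epochs are removed because the device cannot distinguish them
  from non-wear. Non-wear is any gap over 1 hour between epochs; wear time
  on a date is the union of wear bouts, each spanning its first to last
  epoch plus one 15-minute bin. Days with under 10 hours of wear are
  excluded (missing, not zero); the boundary 10.0 h is included.
* **Sleep.** Records must start at or after 17:00 and end by 13:00 of the
  next day, and span at least 3 hours onset-to-offset (shorter records are
  device errors by the manufacturer's declaration). Overlapping records of
  one night are both dropped as error measurements — only the mutually
  overlapping records, not the whole night. The remaining records of a
  night merge: durations add, inter-record gaps add to wake-after-sleep-
  onset, onset is the earliest and offset the latest. Nights are labelled
  by the date they start on. A night is insufficient sleep below 8 h under
  age 18 and below 7 h otherwise; age exactly 18 is treated as adult.
* **Heart rate.** Duplicates are removed, samples above the Tanaka
  age-predicted maximum (208 − 0.7 × age) are excluded, values are rounded
  to integer bpm and aggregated to 15-minute bins (mean/min/max). A day
  qualifies with ≥ 8 populated daytime bins (2 h); a night with ≥ 4
  populated night bins (1 h at one sample per 15 min). The 2-hour day rule
  is interpreted as bin coverage, not raw sample count — the stricter and
  more symmetric reading. The nightly outcome is the mean over the night's
  bin means.
* **Completeness.** Participants qualify per stream when their valid
  days/nights reach 25% of the study days (configurable; 0.5 is the
  sensitivity setting). Ages are fixed at study start.

## The models

For outcome `Y` (daily steps, nightly sleep hours, or nightly mean heart
rate) of participant *i*:

`Y_i = b0 + b1 Heat_i + [b2 Heat_i^2] + b3 Rain_i + bz Z_i + u_i + e_i`

with a per-participant random intercept `u_i` and ML estimation
(`lme4::lmer`, REML off, so that log-likelihoods are comparable across
nested fixed-effect structures). Workflow:

1. **Curvature.** The quadratic heat term replaces visual residual-plot
   inspection with an automated surrogate: keep `Heat²` iff the chi-square
   likelihood-ratio test improves on the linear model at 5%. The
   residuals-versus-heat table is exported for human review.
2. **Covariate selection.** Candidates are offered in the fixed order
   month, weekend, age group, sex, BMI group and retained iff the LRT
   against the current model has p < 0.05. The order is a convention (the
   candidates are listed without one in the study design); the panel is
   first restricted to rows complete for all candidates so every test runs
   on identical rows. An audit trail records every test. Candidates with a
   single observed level are skipped as untestable.
3. **Marginal effects.** With a quadratic term, the per-degree effect at
   reference `x` is `b1 + b2 (2x + 1)` — the exact difference
   `f(x+1) − f(x)` — reported at 20 °C and 30 °C. Full-precision
   coefficients are used; rounding the coefficients first can change these
   numbers appreciably.
4. **Subgroups.** Heat-by-factor interactions (age group, BMI group, sex,
   month) are tested by LRT; when significant, the model is refitted per
   level and the per-level heat estimates and marginal effects tabulated.
5. **Extremes.** The binary contrast model replaces continuous exposures
   with the heat-stress and heavy-rain flags; a constant flag is an error
   (no contrast), not a silent zero.
6. **Metric comparison.** The same specification is refitted once per heat
   metric (WBGT/HI versus bare temperature) on common rows and ranked by
   AIC (`2k − 2 logLik`).
7. **LOSO cross-validation.** Each participant in turn is held out, the
   model refitted, and the held-out rows predicted from fixed effects only
   — the random intercept of an unseen subject is unknowable, so
   predictions are population-level. Per fold, `R² = 1 − SSE/SST` about
   the held-out subject's own mean and RMSE; a constant held-out outcome
   gives a missing R², excluded from the average. Because the subject's
   intercept is not predicted, fold R² is regularly negative when
   between-subject variance is large; this is a property of the
   fixed-effects-only definition (the R² variant was not further
   specified), and RMSE is the more interpretable companion.

Wald 95% CIs are `estimate ± 1.96 SE` with large-sample normal p-values;
Satterthwaite small-sample corrections are deliberately out of scope since
every panel here has thousands of rows. Rows with any missing model
variable are dropped listwise (no imputation). A singular fit (random
intercept variance estimated at the zero boundary) is legitimate — it is
the expected outcome when between-participant heterogeneity is absent, and
in that limit the fixed effects coincide with pooled OLS — so it is
flagged in the result rather than raised as an error; genuine optimizer
non-convergence errors out with diagnostics.

Two descriptive/design calculations round out the workflow: the
finite-population-corrected sample size
`n0 = z² p (1−p) / e²`, `n = n0 / (1 + (n0 − 1)/N)` (with N = 100,000,
95% confidence, 8% margin this gives 150), and count/proportion formatting
(`"55/137, 40.1%"`).

## The synthetic study world

`sim_config()` holds every true parameter; all generated records are
reproducible from (config, seed), with one derived seed stream per
sub-generator so weather, cohort and outcomes can be regenerated
independently.

**Weather.** Per season (rainy June–September, cool dry October–January,
hot dry February–May) the generator uses daily mean temperatures of
27.6 / 26.8 / 31.1 °C with diurnal sinusoids (coolest ~03:00, warmest
~15:00) of amplitude 4 / 7 / 7 °C, day-level noise (SD 1.5 °C) and
interval noise. Relative humidity has seasonal means 75 / 35 / 30%,
*day-to-day humidity waves* (SD 12 points) and anti-correlation with the
intra-day temperature anomaly. Rain falls as per-day Bernoulli events
(probability 0.30 / 0.01 / 0.04) with gamma totals spread over afternoon
intervals. Radiation is a daytime sinusoid under day-level cloud cover
(mean 0.2, SD 0.15) with extra attenuation on rain days. The day-level
humidity and cloud structure matters: it is what decorrelates daily
WBGT/HI from bare air temperature (in this climate the rainy season has
the highest WBGT while the dry seasons have the highest air temperature),
and without it a WBGT-versus-temperature model comparison would be
meaningless.

**Cohort.** About half female; ages normal (43, 13) truncated to 16–79;
BMI normal (22.3, 2.7); villages assigned to nearest stations by WGS 84
geodesic distance.

**Outcomes.** Generated on the linked per-day/per-night scale by
inverting the model — `b0 + b1 Heat + b2 Heat² + b3 Rain + weekend effect
+ participant intercept + noise` — and then decomposed into raw streams,
which guarantees the ground truth survives QC when no violations are
injected. Defaults sit near the regime the method is meant for: sleep
slope −0.04 h per °C HI with +0.01 h per mm rain (intercept 7.8 h,
residual SD 1.0 h — onset/offset variability of order an hour, not
minutes); an inverted-U activity response `648 WBGT − 12 WBGT²` peaking at
27 °C with −39 steps per mm rain (residual SD 4,000 steps); no true heat
effect on nighttime heart rate with −0.04 bpm per mm rain. Step totals
spread over 06:00–22:00 epochs with a bimodal morning/late-afternoon
profile; sleep becomes one record per night or two records separated by a
wake gap (probability 0.3, only for nights ≥ 7 h so both records clear the
3-hour minimum) to exercise merging; heart rate becomes per-15-minute
night samples around the nightly mean. Missingness drops whole
participant-days/nights per stream (defaults 0.5 / 0.5 / 0.8, near the
observed completeness of such deployments).

**Violation injection.** Duplicated step epochs, zero-step epochs at
timestamps outside the generation window (so they collide with nothing),
overlapping sleep records (injected only on unsplit nights so exactly two
records are involved), short sleep records placed before the night's true
onset (removed by the span rule before overlap detection, so they cannot
interact with it), heart-rate spikes above the Tanaka ceiling, and
duplicated heart-rate samples — each tallied in a ground-truth ledger
whose per-reason counts must equal the QC module's exclusion counts
exactly. This exactness is the core decomposition invariant and is what
the 50-fixture acceptance suite checks.

**What passing tests do not show.** The generator's missingness is
independent at the participant-day level, whereas real deployments lose
data in politically and logistically driven streaks; its weather is
stationary within seasons (no climate trend, no multi-day heat waves
beyond what day-level noise produces); wearable error enters only through
the modelled violation channels, not through the device's proprietary
step/sleep/PPG algorithms, whose outputs are taken at face value. Results
on synthetic data therefore validate the *pipeline*, not the device or the
epidemiology.

## Numerical and design choices

* Problem sizes: the default study world is 60 participants × 120 days ×
  5 stations — large enough that the sleep model's CIs are a few times
  narrower than its effects, small enough to simulate a hundred replicates
  routinely. Calibration suites use 100 fixed-seed replicates; QC
  reconciliation uses 50 small fixtures (6 × 12 days).
* Station assignment ties break lexicographically by station id;
  assignments are fixed for the whole study (home-village mobility is out
  of scope).
* Weekend means Saturday and Sunday; month enters models as a categorical
  factor with unused levels dropped.
* The wear-time rule reads epochs as 15-minute interval starts: "epochs
  every 15 minutes from 08:00 to 18:00" means starts 08:00–17:45 and
  10.0 h of wear.
* `Heat²` is only ever present together with `Heat`; interaction factors
  are restricted to age group, BMI group, sex and month.
* Marginal-effect reporting: with rounded coefficients (606, −12) the
  formula gives +114 at 20 °C, whereas full-precision coefficients from
  the same fit can legitimately give numbers tens of steps away (the
  quadratic term multiplies by `2x + 1` ≈ 41–61, so a coefficient rounding
  error of 0.5 moves the effect by ~25 steps). The package always reports
  from full precision.
* Determinism: the pipeline contains no randomness; `run_all` twice on the
  same inputs is byte-identical. All generator seeds are explicit.

## Known limitations

No spatial interpolation between stations; no distributed-lag or
nonlinear (spline) exposure-response models; no multiple-testing
correction across outcome families (none is applied by design); daytime
heart rate is processed but not modelled by default, mirroring its poor
completeness in this class of deployment.
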