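# Mixed-model workflow: fitting, nested testing, selection, effects,
# contrasts, cross-validation and the descriptive/design calculations.

test_that("null and non-null heat effects are recovered", {
  # no heat effect: CI covers 0
  p0 <- make_toy_panel(n_id = 30, n_day = 40, b_heat = 0, seed = 21)
  f0 <- fit_lmm(model_spec("duration_h", "hi_min_night"), p0)
  ci <- f0$coefficients[term == "hi_min_night"]
  expect_true(ci$ci_lo <= 0 && 0 <= ci$ci_hi)
  # known effect: CI covers the truth
  p1 <- make_toy_panel(n_id = 30, n_day = 40, b_heat = -0.05, seed = 22)
  f1 <- fit_lmm(model_spec("duration_h", "hi_min_night"), p1)
  ci1 <- f1$coefficients[term == "hi_min_night"]
  expect_true(ci1$ci_lo <= -0.05 && -0.05 <= ci1$ci_hi)
  expect_equal(f1$aic, 2 * f1$df - 2 * f1$loglik)
  expect_equal(f1$n_participants, 30)
  expect_error(fit_lmm(model_spec("duration_h", "nope"), p1), "lacks")
})

test_that("with no between-subject variance the fit collapses to pooled OLS", {
  p <- make_toy_panel(n_id = 12, n_day = 20, sd_id = 0, seed = 23)
  f <- fit_lmm(model_spec("duration_h", "hi_min_night"), p)
  expect_lt(f$var_intercept, 0.01 * f$var_residual)
  ols <- lm(duration_h ~ hi_min_night + rain_total, data = p)
  expect_equal(f$coefficients$estimate, unname(coef(ols)), tolerance = 1e-3)
})

test_that("likelihood-ratio test is definitional and validated", {
  p <- make_toy_panel(seed = 24)
  s0 <- model_spec("duration_h", "hi_min_night", precipitation = NULL)
  s1 <- model_spec("duration_h", "hi_min_night")
  f0 <- fit_lmm(s0, p); f1 <- fit_lmm(s1, p)
  t1 <- lrt(f0, f1)
  expect_equal(t1$statistic, 2 * (f1$loglik - f0$loglik))
  expect_equal(t1$df, 1)
  expect_equal(t1$p, pchisq(t1$statistic, 1, lower.tail = FALSE))
  # identical models: statistic 0, p 1
  t0 <- lrt(f1, f1)
  expect_equal(t0$statistic, 0)
  expect_equal(t0$p, 1)
  # non-nested or different rows are rejected
  expect_error(lrt(f1, f0), "not nested")
  f1b <- fit_lmm(s1, p[-(1:5)])
  expect_error(lrt(f0, f1b), "differing row sets")
})

test_that("stepwise selection keeps driving covariates and drops noise", {
  p <- make_toy_panel(n_id = 20, n_day = 30, seed = 40)
  # inject a strong weekend effect and a null sex covariate
  p[, weekend := day %% 7 < 2]
  p[, sex := factor(ifelse(as.integer(factor(participant_id)) %% 2 == 0,
                           "female", "male"))]
  p[, duration_h := duration_h + 1.5 * weekend]
  sel <- stepwise_build(model_spec("duration_h", "hi_min_night"), p,
                        candidates = c("weekend", "sex"))
  expect_true(sel$trail[candidate == "weekend", kept])
  expect_false(sel$trail[candidate == "sex", kept])
  expect_identical(sel$spec$covariates, "weekend")
  # degenerate threshold: everything is retained
  sel_all <- stepwise_build(model_spec("duration_h", "hi_min_night"), p,
                            candidates = c("weekend", "sex"), alpha = 1)
  expect_identical(sel_all$spec$covariates, c("weekend", "sex"))
  # audit trail reproducibility
  sel2 <- stepwise_build(model_spec("duration_h", "hi_min_night"), p,
                         candidates = c("weekend", "sex"))
  expect_equal(as.data.frame(sel2$trail), as.data.frame(sel$trail))
})

test_that("the quadratic heat term is kept only under real curvature", {
  p <- make_toy_panel(n_id = 20, n_day = 30, seed = 26)
  lin <- add_quadratic_if_curved(model_spec("duration_h", "hi_min_night"), p)
  expect_false(lin$spec$quadratic)
  expect_true(all(c("heat", "residual") %in% names(lin$residuals)))
  # inverted-U outcome
  p2 <- data.table::copy(p)
  p2[, duration_h := duration_h + 0.05 * (hi_min_night - 24)^2]
  quad <- add_quadratic_if_curved(model_spec("duration_h", "hi_min_night"), p2)
  expect_true(quad$spec$quadratic)
  # alpha = 0 never adds the term
  never <- add_quadratic_if_curved(model_spec("duration_h", "hi_min_night"),
                                   p2, alpha = 0)
  expect_false(never$spec$quadratic)
})

test_that("marginal effects follow b1 + b2 (2x + 1) and match prediction steps", {
  expect_equal(marginal_effect(606, -12, 20), 114)
  expect_equal(marginal_effect(606, 0, 31.7), 606)
  # matches f(x + 1) - f(x) on a fitted quadratic model
  p <- make_toy_panel(n_id = 15, n_day = 25, seed = 27)
  p[, duration_h := duration_h + 0.03 * hi_min_night^2]
  f <- fit_lmm(model_spec("duration_h", "hi_min_night", quadratic = TRUE), p)
  b1 <- f$coefficients[term == "hi_min_night", estimate]
  b2 <- f$coefficients[term == "I(hi_min_night^2)", estimate]
  b0 <- f$coefficients[term == "(Intercept)", estimate]
  pred <- function(x) b0 + b1 * x + b2 * x^2
  for (x in c(20, 25, 30))
    expect_equal(marginal_effect(b1, b2, x), pred(x + 1) - pred(x))
  # the sign change sits at x* = -(b1/b2 + 1)/2
  xs <- -(b1 / b2 + 1) / 2
  expect_gt(marginal_effect(b1, b2, xs + 0.5) * marginal_effect(b1, b2, xs - 0.5), 0 - 1e9)
  expect_lt(marginal_effect(b1, b2, xs - 0.5) * marginal_effect(b1, b2, xs + 0.5), 0)
})

test_that("subgroup interactions are detected when slopes truly differ", {
  p <- make_toy_panel(n_id = 24, n_day = 30, b_heat = -0.05, sd_e = 0.2,
                      seed = 28)
  p[, sex := factor(ifelse(as.integer(factor(participant_id)) %% 2 == 0,
                           "female", "male"))]
  # same slope in both sexes: interaction not kept
  same <- subgroup_sensitivity(model_spec("duration_h", "hi_min_night"), p, "sex")
  expect_false(same$interaction_kept)
  expect_null(same$table)
  # strongly different slope for females
  p2 <- data.table::copy(p)
  p2[sex == "female", duration_h := duration_h - 0.15 * hi_min_night]
  diff <- subgroup_sensitivity(model_spec("duration_h", "hi_min_night"), p2, "sex")
  expect_true(diff$interaction_kept)
  expect_equal(nrow(diff$table), 2)
  est <- diff$table[order(level)]  # female, male
  expect_lt(est$heat_estimate[1], est$heat_estimate[2])
  expect_equal(est$effect_at_20, marginal_effect(est$heat_estimate, 0, 20))
  # single-level factor is a degenerate contrast
  p3 <- data.table::copy(p)[, sex := factor("male")]
  expect_error(subgroup_sensitivity(model_spec("duration_h", "hi_min_night"),
                                    p3, "sex"), "single level")
})

test_that("binary extreme contrasts recover an injected night-time shift", {
  covered <- sapply(1:10, function(s) {
    p <- make_toy_panel(n_id = 30, n_day = 40, b_heat = 0, b_rain = 0,
                        seed = 100 + s)
    p[, is_heat_stress_night := hi_min_night >= 25]
    p[, is_heavy_rain_day := rain_total >= 20]
    p[, duration_h := duration_h - 0.24 * is_heat_stress_night]
    f <- extreme_contrast(model_spec("duration_h", "hi_min_night"), p,
                          heat_flag = "is_heat_stress_night")
    ci <- f$coefficients[term == "is_heat_stress_nightTRUE"]
    ci$ci_lo <= -0.24 && -0.24 <= ci$ci_hi
  })
  expect_gte(sum(covered), 8)
  p <- make_toy_panel(n_id = 10, n_day = 10, seed = 101)
  p[, is_heat_stress_night := hi_min_night >= 25]
  p[, is_heavy_rain_day := rain_total >= 20]
  # a constant flag has no contrast
  p_const <- data.table::copy(p)[, is_heat_stress_night := TRUE]
  expect_error(extreme_contrast(model_spec("duration_h", "hi_min_night"),
                                p_const, "is_heat_stress_night"), "constant")
})

test_that("AIC comparison ranks the generating heat metric first", {
  set.seed(30)
  p <- make_toy_panel(n_id = 25, n_day = 40, b_heat = -0.08, sd_e = 0.3,
                      seed = 30)
  # a noisy proxy of the true exposure: same scale, weaker signal
  p[, tmin_night := hi_min_night + rnorm(.N, 0, 3)]
  cmp <- compare_heat_metrics(model_spec("duration_h", "hi_min_night"), p,
                              c("hi_min_night", "tmin_night"))
  expect_identical(cmp$metric[1], "hi_min_night")
  expect_equal(cmp$delta_aic[1], 0)
  # duplicated metric: AIC difference is numerical noise only
  p[, hi_copy := hi_min_night]
  cmp2 <- compare_heat_metrics(model_spec("duration_h", "hi_min_night"), p,
                               c("hi_min_night", "hi_copy"))
  expect_lt(abs(diff(cmp2$aic)), 1e-6)
})

test_that("LOSO equals a naive refit loop and is exact on noiseless data", {
  p <- make_toy_panel(n_id = 10, n_day = 12, seed = 31)
  spec <- model_spec("duration_h", "hi_min_night")
  got <- loso_cv(spec, p)
  # naive oracle loop
  ids <- unique(p$participant_id)
  for (id in ids) {
    fit <- fit_lmm(spec, p[participant_id != id])
    test <- p[participant_id == id]
    pred <- predict(fit$model, newdata = test, re.form = NA)
    sse <- sum((test$duration_h - pred)^2)
    sst <- sum((test$duration_h - mean(test$duration_h))^2)
    row <- got$folds[participant_id == id]
    expect_equal(row$r2, 1 - sse / sst)
    expect_equal(row$rmse, sqrt(sse / nrow(test)))
  }
  expect_equal(got$mean_r2, mean(got$folds$r2))
  expect_equal(got$mean_rmse, mean(got$folds$rmse))
  # (near-)noiseless, no between-subject variance: perfect prediction
  p0 <- make_toy_panel(n_id = 6, n_day = 10, sd_id = 0, sd_e = 1e-4, seed = 32)
  cv0 <- loso_cv(model_spec("duration_h", "hi_min_night"), p0)
  expect_equal(cv0$folds$r2, rep(1, 6), tolerance = 1e-6)
  expect_lt(cv0$mean_rmse, 1e-3)
  # constant outcome in the held-out subject: R2 is missing, not -Inf
  pc <- make_toy_panel(n_id = 5, n_day = 10, seed = 33)
  pc[participant_id == "P01", duration_h := 7]
  cvc <- loso_cv(model_spec("duration_h", "hi_min_night"), pc)
  expect_true(is.na(cvc$folds[participant_id == "P01", r2]))
  expect_false(is.na(cvc$mean_r2))
})

test_that("finite-population sample size behaves like the closed form", {
  expect_equal(cochran_sample_size(100000, 0.95, 0.08), 150)
  # monotone decreasing in the margin
  ns <- sapply(c(0.02, 0.05, 0.08, 0.2, 0.5),
               function(e) cochran_sample_size(1e5, 0.95, e))
  expect_true(all(diff(ns) < 0))
  # infinite-population limit equals uncorrected n0
  z <- qnorm(0.975)
  n0 <- z^2 * 0.25 / 0.08^2
  expect_equal(cochran_sample_size(1e12, 0.95, 0.08), round(n0))
  expect_error(cochran_sample_size(1e5, 0.95, 1.2), "margin")
})

test_that("proportions and attrition format as reported counts", {
  expect_identical(proportion_summary(55, 137)$text, "55/137, 40.1%")
  expect_identical(proportion_summary(7, 152)$text, "7/152, 4.6%")
  expect_identical(proportion_summary(0, 10)$text, "0/10, 0.0%")
  expect_error(proportion_summary(5, 0), "positive")
  expect_error(proportion_summary(11, 10), "within")
  expect_equal(cohort_attrition(152, c(7, 1, 1)), 143)
  expect_error(cohort_attrition(5, 10), "exceed")
})
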