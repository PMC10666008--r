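# Mixed-effects modelling workflow: random-intercept models estimated by
# maximum likelihood, chi-square likelihood-ratio covariate selection,
# quadratic heat terms, subgroup interactions, binary extreme-weather
# contrasts, AIC heat-metric comparison and LOSO cross-validation.

#' Describe a mixed-model specification
#'
#' A specification holds the outcome, the continuous heat and precipitation
#' exposures, whether a quadratic heat term is included, the adjustment
#' covariates, and an optional heat-by-factor interaction. Every model adds
#' a per-participant random intercept and is estimated by maximum
#' likelihood.
#'
#' @param outcome Outcome column name (e.g. `"steps"`, `"duration_h"`,
#'   `"nightly_hr"`).
#' @param heat Heat exposure column (e.g. `"wbgt_max_day"`,
#'   `"hi_min_night"`, or a binary heat-stress flag).
#' @param precipitation Precipitation column (`"rain_total"` or the heavy
#'   rain flag); `NULL` to omit.
#' @param quadratic Include `heat^2`? The quadratic requires the linear
#'   term.
#' @param covariates Character vector of adjustment covariates
#'   (subset of month, weekend, age_group, sex, bmi_group).
#' @param interaction Optional factor name crossed with the heat term(s);
#'   one of age_group, bmi_group, sex, month.
#' @return An object of class `hw_spec`.
#' @export
model_spec <- function(outcome, heat, precipitation = "rain_total",
                       quadratic = FALSE, covariates = character(),
                       interaction = NULL) {
  if (!is.null(interaction) &&
      !interaction %in% c("age_group", "bmi_group", "sex", "month"))
    stop("interaction factor must be one of age_group, bmi_group, sex, month")
  structure(list(outcome = outcome, heat = heat,
                 precipitation = precipitation, quadratic = quadratic,
                 covariates = covariates, interaction = interaction),
            class = "hw_spec")
}

.spec_terms <- function(spec) {
  heat2 <- sprintf("I(%s^2)", spec$heat)
  terms <- spec$heat
  if (spec$quadratic) terms <- c(terms, heat2)
  if (!is.null(spec$precipitation)) terms <- c(terms, spec$precipitation)
  terms <- c(terms, spec$covariates)
  if (!is.null(spec$interaction)) {
    terms <- union(terms, spec$interaction)
    terms <- c(terms, sprintf("%s:%s", spec$heat, spec$interaction))
    if (spec$quadratic)
      terms <- c(terms, sprintf("%s:%s", heat2, spec$interaction))
  }
  terms
}

.spec_formula <- function(spec) {
  as.formula(paste(spec$outcome, "~",
                   paste(.spec_terms(spec), collapse = " + "),
                   "+ (1 | participant_id)"))
}

.spec_vars <- function(spec) {
  unique(c(spec$outcome, spec$heat, spec$precipitation, spec$covariates,
           spec$interaction, "participant_id"))
}

#' Fit a random-intercept linear mixed model by maximum likelihood
#'
#' Rows with any missing model variable are dropped listwise (no
#' imputation). The fit is deterministic given the data. Non-convergence
#' raises an error with the optimizer diagnostics; a singular fit (random
#' intercept variance estimated at zero) is legitimate — it corresponds to
#' no between-participant heterogeneity — and is flagged, not silently
#' altered.
#'
#' @param spec A [model_spec()].
#' @param panel Model-ready panel from [build_panel()].
#' @return An object of class `hw_fit`: coefficient table (estimate, SE,
#'   Wald z, p, 95% CI as estimate +/- 1.96 SE), random-intercept and
#'   residual variances, log-likelihood, AIC (`2k - 2 logLik`),
#'   observation/participant counts, the underlying `lmerMod`, and the rows
#'   used.
#' @export
fit_lmm <- function(spec, panel) {
  dt <- as.data.table(panel)
  vars <- intersect(.spec_vars(spec), names(dt))
  miss <- setdiff(.spec_vars(spec), names(dt))
  if (length(miss)) stop("panel lacks model variables: ",
                         paste(miss, collapse = ", "))
  dt <- dt[complete.cases(dt[, vars, with = FALSE])]
  dt <- droplevels(dt)
  if (uniqueN(dt$participant_id) < 2)
    stop("at least 2 participants are required")

  fm <- .spec_formula(spec)
  fit <- lme4::lmer(fm, data = dt, REML = FALSE)
  conv <- fit@optinfo$conv$opt
  msgs <- fit@optinfo$conv$lme4$messages
  bad <- !is.null(msgs) && any(grepl("failed to converge", msgs, ignore.case = TRUE))
  if (conv != 0 || bad)
    stop("mixed-model fit did not converge: ",
         paste(c(msgs, fit@optinfo$message), collapse = "; "))

  est <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(vcov(fit))))
  z <- est / se
  p <- 2 * stats::pnorm(-abs(z))
  coefs <- data.table(term = names(est), estimate = unname(est),
                      se = unname(se), z = unname(z), p = unname(p),
                      ci_lo = unname(est - 1.96 * se),
                      ci_hi = unname(est + 1.96 * se))
  vc <- as.data.frame(lme4::VarCorr(fit))
  ll <- logLik(fit)
  structure(list(
    spec = spec, formula = fm, coefficients = coefs,
    var_intercept = vc$vcov[vc$grp == "participant_id"][1],
    var_residual = vc$vcov[vc$grp == "Residual"][1],
    loglik = as.numeric(ll), df = attr(ll, "df"),
    aic = 2 * attr(ll, "df") - 2 * as.numeric(ll),
    n_obs = nrow(dt), n_participants = uniqueN(dt$participant_id),
    singular = lme4::isSingular(fit), model = fit, data = dt
  ), class = "hw_fit")
}

#' @export
print.hw_fit <- function(x, ...) {
  cat(sprintf("Linear mixed model (ML): %s\n", deparse(x$formula)))
  cat(sprintf("n = %d observations, %d participants | logLik = %.2f | AIC = %.1f\n",
              x$n_obs, x$n_participants, x$loglik, x$aic))
  cat(sprintf("Random intercept variance = %.4g, residual variance = %.4g%s\n",
              x$var_intercept, x$var_residual,
              if (x$singular) " (singular: intercept variance at boundary)" else ""))
  print(x$coefficients, digits = 4)
  invisible(x)
}

#' Chi-square likelihood-ratio test between nested fits
#'
#' @param nested,full `hw_fit` objects fitted on the same rows, with the
#'   nested fixed-effect terms a subset of the full ones.
#' @return List with `statistic` (`2 * (logLik_full - logLik_nested)`),
#'   `df` (parameter-count difference) and `p`.
#' @export
lrt <- function(nested, full) {
  if (nested$n_obs != full$n_obs)
    stop("models were fitted on differing row sets (",
         nested$n_obs, " vs ", full$n_obs, " rows)")
  if (!all(.spec_terms(nested$spec) %in% .spec_terms(full$spec)))
    stop("models are not nested")
  df <- full$df - nested$df
  if (df < 0) stop("full model has fewer parameters than the nested model")
  stat <- 2 * (full$loglik - nested$loglik)
  p <- if (df == 0) 1 else pchisq(stat, df = df, lower.tail = FALSE)
  list(statistic = stat, df = df, p = p)
}

.with_covariates <- function(spec, covariates) {
  s <- spec
  s$covariates <- covariates
  s
}

#' Stepwise covariate selection by likelihood-ratio testing
#'
#' Starting from the base exposure model, candidates are offered one at a
#' time in a fixed order (month, weekend, age_group, sex, bmi_group by
#' default) and kept when the chi-square likelihood-ratio test against the
#' current model is significant at `alpha`. To keep every test on identical
#' rows, the panel is first restricted to rows complete for the base model
#' and all candidates.
#'
#' @param spec Base [model_spec()] (heat + precipitation, no covariates).
#' @param panel Model-ready panel.
#' @param candidates Candidate covariates in testing order.
#' @param alpha Retention threshold on the LRT p-value. Default 0.05.
#' @return List: `spec` (final specification), `fit` (final `hw_fit`) and
#'   `trail` (one row per candidate: log-likelihoods, statistic, df, p,
#'   kept).
#' @export
stepwise_build <- function(spec, panel,
                           candidates = c("month", "weekend", "age_group",
                                          "sex", "bmi_group"),
                           alpha = 0.05) {
  dt <- as.data.table(panel)
  vars <- unique(c(.spec_vars(spec), candidates))
  dt <- dt[complete.cases(dt[, intersect(vars, names(dt)), with = FALSE])]

  current <- .with_covariates(spec, character())
  fit0 <- fit_lmm(current, dt)
  trail <- vector("list", length(candidates))
  for (i in seq_along(candidates)) {
    cand <- candidates[i]
    v <- dt[[cand]]
    if (uniqueN(v[!is.na(v)]) < 2) {
      # a single observed level carries no information; not testable
      trail[[i]] <- data.table(candidate = cand,
                               loglik_without = fit0$loglik,
                               loglik_with = NA_real_,
                               statistic = NA_real_, df = NA_integer_,
                               p = NA_real_, kept = FALSE)
      next
    }
    trial <- .with_covariates(current, c(current$covariates, cand))
    fit1 <- fit_lmm(trial, dt)
    test <- lrt(fit0, fit1)
    kept <- test$p < alpha
    trail[[i]] <- data.table(candidate = cand,
                             loglik_without = fit0$loglik,
                             loglik_with = fit1$loglik,
                             statistic = test$statistic, df = test$df,
                             p = test$p, kept = kept)
    if (kept) { current <- trial; fit0 <- fit1 }
  }
  list(spec = current, fit = fit0, trail = rbindlist(trail))
}

#' Add a quadratic heat term when curvature is supported
#'
#' Automated surrogate for residual-plot inspection: the model is fitted
#' with and without `heat^2` and the quadratic is kept when the
#' likelihood-ratio test is significant at `alpha`. The linear fit's
#' residuals against heat are returned for human review.
#'
#' @param spec Base [model_spec()] with a linear heat term.
#' @param panel Model-ready panel.
#' @param alpha Threshold on the LRT p-value; 0 never adds the term.
#' @return List: `spec` (with `quadratic` set accordingly), `fit`,
#'   `lrt`, and `residuals` (heat value vs residual from the linear fit).
#' @export
add_quadratic_if_curved <- function(spec, panel, alpha = 0.05) {
  lin <- spec; lin$quadratic <- FALSE
  quad <- spec; quad$quadratic <- TRUE
  fit_lin <- fit_lmm(lin, panel)
  fit_quad <- fit_lmm(quad, fit_lin$data)  # identical rows
  test <- lrt(fit_lin, fit_quad)
  keep <- test$df > 0 && test$p < alpha
  resid_tab <- data.table(heat = fit_lin$data[[spec$heat]],
                          residual = stats::residuals(fit_lin$model))
  list(spec = if (keep) quad else lin,
       fit = if (keep) fit_quad else fit_lin,
       lrt = test, residuals = resid_tab)
}

#' Marginal (combined) effect of a 1-degree heat increase
#'
#' In a model with linear and quadratic heat terms, the predicted outcome
#' change for a move from `x` to `x + 1` degrees:
#' `b1 + b2 * ((x + 1)^2 - x^2) = b1 + b2 * (2 x + 1)`.
#'
#' @param b1 Linear heat coefficient.
#' @param b2 Quadratic heat coefficient (0 for a linear model).
#' @param x Reference exposure, deg C.
#' @return Outcome units per +1 deg C.
#' @export
marginal_effect <- function(b1, b2 = 0, x) {
  b1 + b2 * (2 * x + 1)
}

.coef_of <- function(fit, term) {
  i <- match(term, fit$coefficients$term)
  if (is.na(i)) NA_real_ else fit$coefficients$estimate[i]
}
.p_of <- function(fit, term) {
  i <- match(term, fit$coefficients$term)
  if (is.na(i)) NA_real_ else fit$coefficients$p[i]
}

#' Subgroup heat-sensitivity analysis via interaction terms
#'
#' Tests whether the heat effect differs across the levels of a grouping
#' factor by a likelihood-ratio test on the heat-by-factor interaction
#' (both heat terms when the model is quadratic). When the interaction is
#' significant at `alpha`, the model is refitted on each level's subset and
#' the heat estimates, p-values and marginal effects at 20 and 30 deg C are
#' tabulated.
#'
#' @param spec [model_spec()] without interaction.
#' @param panel Model-ready panel.
#' @param factor_x One of `"age_group"`, `"bmi_group"`, `"sex"`, `"month"`.
#' @param alpha Significance threshold for the interaction. Default 0.05.
#' @return List: `lrt`, `interaction_kept`, and (when kept) `table` with
#'   one row per level.
#' @export
subgroup_sensitivity <- function(spec, panel, factor_x, alpha = 0.05) {
  dt <- as.data.table(panel)
  if (!factor_x %in% names(dt)) stop("unknown factor: ", factor_x)
  lv <- unique(as.character(dt[[factor_x]][!is.na(dt[[factor_x]])]))
  if (length(lv) < 2) stop("factor `", factor_x, "` has a single level; no contrast")

  base <- spec
  base$covariates <- union(base$covariates, factor_x)
  full <- base
  full$interaction <- factor_x
  fit_base <- fit_lmm(base, dt)
  fit_full <- fit_lmm(full, fit_base$data)
  test <- lrt(fit_base, fit_full)
  kept <- test$p < alpha
  out <- list(lrt = test, interaction_kept = kept, table = NULL)
  if (!kept) return(out)

  heat2 <- sprintf("I(%s^2)", spec$heat)
  sub_spec <- spec
  sub_spec$covariates <- setdiff(spec$covariates, factor_x)
  rows <- lapply(lv, function(level) {
    sub <- dt[as.character(dt[[factor_x]]) == level]
    if (uniqueN(sub$participant_id) < 2) {
      warning("subgroup level `", level, "` has fewer than 2 participants; skipped")
      return(NULL)
    }
    f <- fit_lmm(sub_spec, sub)
    b1 <- .coef_of(f, spec$heat)
    b2 <- if (spec$quadratic) .coef_of(f, heat2) else 0
    data.table(level = level, n_participants = f$n_participants,
               n_obs = f$n_obs,
               heat_estimate = b1, heat_p = .p_of(f, spec$heat),
               heat2_estimate = if (spec$quadratic) b2 else NA_real_,
               heat2_p = if (spec$quadratic) .p_of(f, heat2) else NA_real_,
               effect_at_20 = marginal_effect(b1, b2, 20),
               effect_at_30 = marginal_effect(b1, b2, 30))
  })
  out$table <- rbindlist(rows)
  out
}

#' Binary extreme-weather contrast model
#'
#' Refits the specification with binary heat-stress and heavy-rain flags in
#' place of the continuous exposures.
#'
#' @param spec Continuous-exposure [model_spec()].
#' @param panel Model-ready panel carrying the flag columns.
#' @param heat_flag Binary heat variable (e.g. `"is_heat_stress_day"` or
#'   `"is_heat_stress_night"`).
#' @param rain_flag Binary rain variable. Default `"is_heavy_rain_day"`.
#' @return `hw_fit` for the binary model.
#' @export
extreme_contrast <- function(spec, panel, heat_flag,
                             rain_flag = "is_heavy_rain_day") {
  bin <- spec
  bin$heat <- heat_flag
  bin$quadratic <- FALSE
  bin$precipitation <- rain_flag
  dt <- as.data.table(panel)
  dt <- dt[complete.cases(dt[, intersect(.spec_vars(bin), names(dt)),
                             with = FALSE])]
  for (fl in c(heat_flag, rain_flag)) {
    v <- dt[[fl]]
    if (uniqueN(v) < 2)
      stop("flag `", fl, "` is constant (all ", v[1], "); no contrast to estimate")
  }
  fit_lmm(bin, dt)
}

#' Compare heat metrics by AIC
#'
#' Fits the specification once per candidate heat metric on the common
#' complete rows and ranks the models by AIC (lower wins).
#'
#' @param spec [model_spec()]; its `heat` field is replaced by each metric.
#' @param panel Model-ready panel.
#' @param metrics Character vector of heat exposure columns.
#' @return data.table ranked by AIC with `metric`, `aic`, `loglik`,
#'   `delta_aic`.
#' @export
compare_heat_metrics <- function(spec, panel, metrics) {
  dt <- as.data.table(panel)
  vars <- unique(c(setdiff(.spec_vars(spec), spec$heat), metrics))
  dt <- dt[complete.cases(dt[, intersect(vars, names(dt)), with = FALSE])]
  fits <- lapply(metrics, function(m) {
    s <- spec; s$heat <- m
    fit_lmm(s, dt)
  })
  out <- data.table(metric = metrics,
                    aic = vapply(fits, `[[`, numeric(1), "aic"),
                    loglik = vapply(fits, `[[`, numeric(1), "loglik"))
  setorder(out, aic)
  out[, delta_aic := aic - aic[1]]
  out[]
}

#' Leave-one-subject-out cross-validation
#'
#' Each participant's rows form one held-out fold; the model is refitted on
#' the remaining participants and the held-out outcomes are predicted from
#' the fixed effects alone (the random intercept of an unseen subject is
#' unavailable, so predictions are population-level). Performance per fold
#' is `R^2 = 1 - SSE/SST` (SST about the held-out mean; reported missing
#' when the held-out outcome is constant) and RMSE.
#'
#' @param spec [model_spec()].
#' @param panel Model-ready panel with at least 3 participants.
#' @param min_rows Folds with fewer rows are skipped with a warning.
#'   Default 2.
#' @return List: `folds` (per-participant `r2`, `rmse`, `n`) and the
#'   averages `mean_r2`, `mean_rmse` (means of the per-participant values,
#'   missing R^2 excluded).
#' @export
loso_cv <- function(spec, panel, min_rows = 2) {
  dt <- as.data.table(panel)
  vars <- intersect(.spec_vars(spec), names(dt))
  dt <- dt[complete.cases(dt[, vars, with = FALSE])]
  ids <- unique(dt$participant_id)
  if (length(ids) < 3) stop("LOSO requires at least 3 participants")

  folds <- lapply(ids, function(id) {
    test <- dt[participant_id == id]
    if (nrow(test) < min_rows) {
      warning("participant ", id, " has fewer than ", min_rows,
              " rows; fold skipped")
      return(NULL)
    }
    fit <- fit_lmm(spec, dt[participant_id != id])
    pred <- predict(fit$model, newdata = test, re.form = NA,
                    allow.new.levels = TRUE)
    y <- test[[spec$outcome]]
    sse <- sum((y - pred)^2)
    sst <- sum((y - mean(y))^2)
    data.table(participant_id = id, n = nrow(test),
               r2 = if (sst > 0) 1 - sse / sst else NA_real_,
               rmse = sqrt(sse / nrow(test)))
  })
  folds <- rbindlist(folds)
  list(folds = folds[],
       mean_r2 = mean(folds$r2, na.rm = TRUE),
       mean_rmse = mean(folds$rmse))
}

#' Finite-population-corrected sample size (Cochran)
#'
#' `n0 = z^2 p (1 - p) / margin^2`, corrected to
#' `n0 / (1 + (n0 - 1) / N)` and rounded to the nearest integer.
#'
#' @param population Eligible population size `N`.
#' @param confidence Confidence level as a fraction (e.g. 0.95).
#' @param margin Margin of error as a fraction (e.g. 0.08).
#' @param p Anticipated proportion. Default 0.5 (most conservative).
#' @return Required number of participants (integer).
#' @export
cochran_sample_size <- function(population, confidence = 0.95, margin = 0.08,
                                p = 0.5) {
  if (margin <= 0 || margin >= 1 || confidence <= 0 || confidence >= 1 ||
      p < 0 || p > 1 || population < 1)
    stop("confidence, margin in (0,1); p in [0,1]; population >= 1")
  z <- qnorm(1 - (1 - confidence) / 2)
  n0 <- z^2 * p * (1 - p) / margin^2
  round(n0 / (1 + (n0 - 1) / population))
}

#' Format a count as a proportion
#'
#' @param k Numerator count.
#' @param n Denominator count (> 0).
#' @return List with `k`, `n`, `pct` (one decimal) and `text` formatted
#'   `"k/n, p%"`.
#' @export
proportion_summary <- function(k, n) {
  if (n <= 0) stop("`n` must be positive")
  if (k < 0 || k > n) stop("`k` must be within [0, n]")
  pct <- round(100 * k / n, 1)
  list(k = k, n = n, pct = pct,
       text = sprintf("%d/%d, %.1f%%", as.integer(k), as.integer(n), pct))
}

#' Cohort attrition arithmetic
#'
#' @param enrolled Number initially recruited.
#' @param losses Vector of losses (withdrawals, deaths, migrations, ...).
#' @return Final analysed cohort size.
#' @export
cohort_attrition <- function(enrolled, losses) {
  out <- enrolled - sum(losses)
  if (out < 0) stop("losses exceed enrolment")
  out
}
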