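# End-to-end driver: input validation, stage composition (exposure -> QC ->
# linkage -> models), CSV intermediates and a JSON run manifest. Local-time
# ISO-8601 timestamps throughout (single-timezone study, no offsets).

.required_columns <- list(
  weather = c("station_id", "timestamp", "air_temp_c", "rel_humidity_pct",
              "precip_mm", "wind_speed_ms", "global_radiation_wm2"),
  stations = c("station_id", "lat", "lon"),
  villages = c("village_id", "lat", "lon"),
  roster = c("participant_id", "sex", "birth_date", "height_cm", "weight_kg",
             "village_id"),
  steps = c("participant_id", "timestamp", "steps"),
  sleep = c("participant_id", "onset", "offset", "duration_h", "waso_min"),
  hr = c("participant_id", "timestamp", "bpm")
)

#' Validate pipeline input files
#'
#' Schema and sanity checks on the input CSVs: required columns, parseable
#' timestamps, relative humidity within [0, 100], non-negative
#' rain/wind/radiation and steps, strictly increasing station timestamps,
#' duplicate keys. Problems are reported with file, row and message;
#' nothing is repaired.
#'
#' @param paths Named list/vector of file paths; names among
#'   `weather`, `stations`, `villages`, `roster`, `steps`, `sleep`, `hr`.
#' @return List with `ok` (logical) and `problems` (data.table `file`,
#'   `row`, `message`).
#' @export
validate_inputs <- function(paths) {
  problems <- list()
  note <- function(file, row, msg)
    problems[[length(problems) + 1L]] <<-
      data.table(file = file, row = row, message = msg)

  for (nm in names(paths)) {
    path <- paths[[nm]]
    if (!file.exists(path)) { note(nm, NA_integer_, "file does not exist"); next }
    dt <- fread(path)
    need <- .required_columns[[nm]]
    miss <- setdiff(need, names(dt))
    if (length(miss)) {
      note(nm, NA_integer_, paste("missing columns:", paste(miss, collapse = ", ")))
      next
    }
    ts_cols <- intersect(c("timestamp", "onset", "offset"), need)
    for (tc in ts_cols) {
      parsed <- tryCatch(.parse_ts(dt[[tc]]),
                         error = function(e) rep(as.POSIXct(NA), nrow(dt)))
      bad <- which(is.na(parsed) & !is.na(dt[[tc]]))
      for (r in head(bad, 20)) note(nm, r, paste("unparseable", tc))
    }
    if (nm == "weather") {
      bad_rh <- which(dt$rel_humidity_pct < 0 | dt$rel_humidity_pct > 100)
      for (r in head(bad_rh, 20))
        note(nm, r, sprintf("relative humidity out of [0,100]: %g",
                            dt$rel_humidity_pct[r]))
      for (col in c("precip_mm", "wind_speed_ms", "global_radiation_wm2")) {
        bad <- which(dt[[col]] < 0)
        for (r in head(bad, 20)) note(nm, r, paste0("negative ", col))
      }
      ts <- .parse_ts(dt$timestamp)
      mono <- data.table(station_id = dt$station_id, ts = ts)[
        , .(ok = all(diff(as.numeric(ts)) > 0)), by = station_id]
      for (s in mono[ok == FALSE, station_id])
        note(nm, NA_integer_,
             paste("non-monotone timestamps for station", s))
    }
    if (nm == "steps" && any(dt$steps < 0))
      note(nm, which(dt$steps < 0)[1], "negative step count")
  }
  problems <- rbindlist(problems)
  if (nrow(problems) == 0L)
    problems <- data.table(file = character(), row = integer(),
                           message = character())
  list(ok = nrow(problems) == 0L, problems = problems[])
}

#' Pipeline configuration
#'
#' @param input_dir Directory holding the input CSVs (as written by
#'   [simulate_all()] or supplied externally).
#' @param out_dir Output directory for every intermediate and result.
#' @param study_start Study start date (for age computation).
#' @param thresholds Exposure thresholds, see [weather_thresholds()].
#' @param completeness Completeness fraction for participant inclusion
#'   (0.25 default; 0.5 is the sensitivity setting).
#' @param min_wear_hours Daily wear-time filter, hours.
#' @param alpha Significance level for covariate selection and the
#'   quadratic-term test.
#' @param candidates Stepwise candidate order.
#' @param run_models,run_loso Toggle the modelling / cross-validation
#'   stages.
#' @param seed Seed recorded in the manifest (the pipeline itself is
#'   deterministic given its inputs).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(input_dir, out_dir,
                            study_start = as.Date("2021-08-01"),
                            thresholds = weather_thresholds(),
                            completeness = 0.25,
                            min_wear_hours = 10,
                            alpha = 0.05,
                            candidates = c("month", "weekend", "age_group",
                                           "sex", "bmi_group"),
                            run_models = TRUE, run_loso = FALSE,
                            seed = 1L) {
  structure(list(input_dir = input_dir, out_dir = out_dir,
                 study_start = as.Date(study_start), thresholds = thresholds,
                 completeness = completeness,
                 min_wear_hours = min_wear_hours, alpha = alpha,
                 candidates = candidates, run_models = run_models,
                 run_loso = run_loso, seed = seed),
            class = "pipeline_config")
}

.write_csv <- function(dt, dir, name, counts) {
  path <- file.path(dir, name)
  out <- copy(as.data.table(dt))
  for (col in names(out)) {
    if (inherits(out[[col]], "POSIXct"))
      set(out, j = col, value = format(out[[col]], "%Y-%m-%dT%H:%M:%S",
                                       tz = "UTC"))
  }
  fwrite(out, path)
  counts[[name]] <- nrow(out)
  counts
}

#' Run the full pipeline
#'
#' Composes exposure summarisation, wearable QC, linkage and (optionally)
#' the modelling workflow over the CSVs in `config$input_dir`, writing
#' every intermediate as plain CSV under `config$out_dir` plus a JSON run
#' manifest (configuration echo, per-stage row counts, per-rule exclusion
#' counts and output checksums). Identical inputs and configuration yield
#' byte-identical outputs.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, the manifest list.
#' @export
run_all <- function(config) {
  ind <- config$input_dir
  outd <- config$out_dir
  dir.create(outd, recursive = TRUE, showWarnings = FALSE)
  inputs <- list(weather = file.path(ind, "weather.csv"),
                 stations = file.path(ind, "stations.csv"),
                 villages = file.path(ind, "villages.csv"),
                 roster = file.path(ind, "roster.csv"),
                 steps = file.path(ind, "steps.csv"),
                 sleep = file.path(ind, "sleep.csv"),
                 hr = file.path(ind, "hr.csv"))
  val <- validate_inputs(inputs)
  if (!val$ok)
    stop("stage `validate`: invalid inputs:\n",
         paste(utils::capture.output(print(val$problems)), collapse = "\n"))
  counts <- list()

  ## exposure
  weather <- fread(inputs$weather)
  daily <- summarize_daily_weather(weather, config$thresholds)
  counts <- .write_csv(daily, outd, "daily_weather.csv", counts)
  idx <- daily[, c(.(season = "all"), extreme_indexes(.SD, config$thresholds)),
               by = station_id]
  idx_season <- daily[, c(extreme_indexes(.SD, config$thresholds)),
                      by = .(station_id, season)]
  idx <- rbind(idx, idx_season, use.names = TRUE)
  counts <- .write_csv(idx, outd, "extreme_indexes.csv", counts)

  ## QC
  roster <- fread(inputs$roster)
  pts <- derive_covariates(roster, config$study_start)
  vs <- assign_nearest_station(fread(inputs$villages), fread(inputs$stations))
  pts <- merge(pts, vs[, .(village_id, station_id)], by = "village_id")

  steps_clean <- clean_steps(fread(inputs$steps))
  steps_daily <- daily_steps(steps_clean, config$min_wear_hours)
  nights <- clean_sleep(fread(inputs$sleep))
  hr <- clean_hr(fread(inputs$hr), pts[, .(participant_id, age)])
  report <- qc_report(steps = steps_clean, sleep = nights,
                      hr = hr$exclusions)
  counts <- .write_csv(steps_daily, outd, "steps_daily.csv", counts)
  counts <- .write_csv(nights, outd, "sleep_nights.csv", counts)
  counts <- .write_csv(hr$nightly, outd, "hr_nightly.csv", counts)
  counts <- .write_csv(report, outd, "qc_report.csv", counts)

  ## completeness per stream
  study_days <- daily[, uniqueN(date)]
  keep_ids <- function(tab, idcol = "participant_id") {
    cov <- tab[, .(valid_days = .N), by = participant_id]
    cov[, study_days := study_days]
    completeness_filter(cov, config$completeness)
  }
  steps_daily <- steps_daily[participant_id %in% keep_ids(steps_daily)]
  nights <- nights[participant_id %in% keep_ids(nights)]
  hr_nightly <- hr$nightly[participant_id %in% keep_ids(hr$nightly)]

  ## linkage
  panel_steps <- build_panel(steps_daily, daily, pts, type = "day")
  panel_sleep <- build_panel(nights, daily, pts, type = "night")
  panel_hr <- build_panel(hr_nightly, daily, pts, type = "night")
  counts <- .write_csv(panel_steps, outd, "panel_steps.csv", counts)
  counts <- .write_csv(panel_sleep, outd, "panel_sleep.csv", counts)
  counts <- .write_csv(panel_hr, outd, "panel_hr.csv", counts)

  ## models
  if (config$run_models) {
    jobs <- list(
      steps = list(panel = panel_steps, outcome = "steps",
                   heat = "wbgt_max_day", alt = "tmax_day",
                   flag = "is_heat_stress_day"),
      sleep = list(panel = panel_sleep, outcome = "duration_h",
                   heat = "hi_min_night", alt = "tmin_night",
                   flag = "is_heat_stress_night"),
      hr = list(panel = panel_hr, outcome = "nightly_hr",
                heat = "hi_min_night", alt = "tmin_night",
                flag = "is_heat_stress_night")
    )
    for (nm in names(jobs)) {
      j <- jobs[[nm]]
      if (uniqueN(j$panel$participant_id) < 3) next
      base <- model_spec(j$outcome, j$heat)
      quad <- add_quadratic_if_curved(base, j$panel, config$alpha)
      sel <- stepwise_build(quad$spec, j$panel, config$candidates,
                            config$alpha)
      counts <- .write_csv(sel$trail, outd,
                           sprintf("model_%s_lrt_trail.csv", nm), counts)
      counts <- .write_csv(sel$fit$coefficients, outd,
                           sprintf("model_%s_coefficients.csv", nm), counts)
      cmp <- compare_heat_metrics(sel$spec, j$panel, c(j$heat, j$alt))
      counts <- .write_csv(cmp, outd,
                           sprintf("model_%s_aic_comparison.csv", nm), counts)
      ext <- try(extreme_contrast(sel$spec, j$panel, j$flag), silent = TRUE)
      if (!inherits(ext, "try-error"))
        counts <- .write_csv(ext$coefficients, outd,
                             sprintf("model_%s_extremes.csv", nm), counts)
      if (config$run_loso) {
        cv <- loso_cv(sel$spec, j$panel)
        counts <- .write_csv(cv$folds, outd,
                             sprintf("model_%s_loso.csv", nm), counts)
      }
    }
  }

  files <- sort(setdiff(list.files(outd), "manifest.json"))
  checksums <- tools::md5sum(file.path(outd, files))
  names(checksums) <- files
  manifest <- list(
    config = list(input_dir = ind, out_dir = outd,
                  study_start = as.character(config$study_start),
                  thresholds = config$thresholds,
                  completeness = config$completeness,
                  min_wear_hours = config$min_wear_hours,
                  alpha = config$alpha, candidates = config$candidates,
                  seed = config$seed),
    row_counts = counts,
    qc_exclusions = split(report$n, paste(report$stream, report$reason,
                                          sep = ":")),
    checksums = as.list(checksums)
  )
  jsonlite::write_json(manifest, file.path(outd, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
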