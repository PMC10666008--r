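# Join cleaned wearable outcomes to station exposures and demographic
# covariates, producing the model-ready panel.

#' Derive participant covariates from the roster
#'
#' Computes age at study start, BMI (`weight / height^2`), and the grouped
#' covariates with half-open intervals: age groups young `< 25`, middle
#' `[25, 65)`, older `>= 65`; BMI groups underweight `< 18.5`, healthy
#' `[18.5, 25)`, overweight `>= 25`.
#'
#' @param roster data.frame with `participant_id`, `sex`
#'   ("male"/"female"), `birth_date`, `height_cm`, `weight_kg`,
#'   `village_id`.
#' @param study_start Date at which age is computed.
#' @return data.table with `age`, `age_group`, `bmi`, `bmi_group` added.
#' @export
derive_covariates <- function(roster, study_start) {
  dt <- as.data.table(roster)
  study_start <- as.Date(study_start)
  if (any(dt$height_cm <= 0) || any(dt$weight_kg <= 0))
    stop("height and weight must be positive")
  dt[, birth_date := as.Date(birth_date)]
  dt[, age := as.numeric(difftime(study_start, birth_date, units = "days")) / 365.25]
  dt[, age_group := fcase(age < 25, "young",
                          age < 65, "middle",
                          default = "older")]
  dt[, bmi := weight_kg / (height_cm / 100)^2]
  dt[, bmi_group := fcase(bmi < 18.5, "underweight",
                          bmi < 25, "healthy",
                          default = "overweight")]
  dt[, age_group := factor(age_group, levels = c("middle", "young", "older"))]
  dt[, bmi_group := factor(bmi_group,
                           levels = c("healthy", "underweight", "overweight"))]
  dt[, sex := factor(sex, levels = c("male", "female"))]
  dt[]
}

.add_calendar <- function(dt, date_col) {
  d <- dt[[date_col]]
  dt[, month := factor(format(d, "%b"), levels = month.abb)]
  dt[, weekend := format(d, "%u") %in% c("6", "7")]
  dt[, season := season_of(as.integer(format(d, "%m")))]
  dt
}

#' Build the model-ready panel
#'
#' Left-joins each cleaned outcome row to the daily weather of its
#' participant's assigned station (same calendar date for day outcomes; the
#' night's starting date for night outcomes), and adds month, weekend
#' (Saturday/Sunday) and season. Rows without matching weather are retained
#' with missing exposure and dropped listwise at fit time.
#'
#' @param outcomes Cleaned outcome table: `daily_steps()` output
#'   (`type = "day"`), or a nightly table with `night_date`
#'   (`type = "night"`).
#' @param daily_weather Output of [summarize_daily_weather()].
#' @param participants Output of [derive_covariates()] with a `station_id`
#'   column (see [assign_nearest_station()]).
#' @param type `"day"` or `"night"`.
#' @return data.table with outcome, exposure and covariate columns; row
#'   count equals the outcome row count.
#' @export
build_panel <- function(outcomes, daily_weather, participants,
                        type = c("day", "night")) {
  type <- match.arg(type)
  out <- as.data.table(outcomes)
  pt <- as.data.table(participants)
  dw <- as.data.table(daily_weather)
  if (!"station_id" %in% names(pt))
    stop("participants must carry an assigned `station_id`")
  unknown <- setdiff(unique(out$participant_id), pt$participant_id)
  if (length(unknown))
    stop("outcomes reference unknown participants: ",
         paste(head(unknown, 5), collapse = ", "))

  keep <- c("participant_id", "sex", "age", "age_group", "bmi_group",
            "village_id", "station_id")
  panel <- merge(out, pt[, keep, with = FALSE], by = "participant_id")

  date_col <- if (type == "day") "date" else "night_date"
  wx_cols <- c("station_id", "date", "tmax_day", "tmin_night", "wbgt_max_day",
               "hi_min_night", "rain_total", "is_heat_stress_day",
               "is_heat_stress_night", "is_heavy_rain_day")
  wx <- dw[, wx_cols, with = FALSE]
  setnames(wx, "date", date_col)
  panel <- merge(panel, wx, by = c("station_id", date_col), all.x = TRUE)
  panel <- .add_calendar(panel, date_col)
  setkeyv(panel, c("participant_id", date_col))
  panel[]
}
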