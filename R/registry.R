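#' Default weekly feature registry
#'
#' The registry defines the ~50 weekly features aggregated from the daily
#' wearable and work-shift streams and the weekly questionnaire. Each entry
#' names the feature, the source variable it is computed from, the
#' aggregation, and a category used for stratified interpretation.
#'
#' Aggregations:
#' \describe{
#'   \item{weekly_mean / weekly_sd}{Mean / unbiased SD of the daily values of
#'     a week. The mean is missing only when all 7 days are missing; the SD
#'     is missing when fewer than 2 daily values are present.}
#'   \item{weekly_sum}{Sum of present daily values; missing only when all
#'     days are missing.}
#'   \item{weekly_count}{Counts over the week (worked days, work-from-home
#'     days, absence days, within-week teleworking rate) or values copied
#'     from the weekly questionnaire (outings, lunches skipped).}
#'   \item{deviation}{Absolute difference between the weekly mean and the
#'     participant's study-long daily mean of the source variable.}
#'   \item{delta}{Week-over-week change of a base weekly feature.}
#'   \item{questionnaire}{Value copied from the same week's questionnaire
#'     (the prior-week K6 total when used as a predictor).}
#' }
#'
#' @param include_prior_k6 logical; include the feature-week K6 total
#'   (`k6_total_prev`, the week before the predicted label) as a predictor.
#'   Default `TRUE`; set `FALSE` to rule out questionnaire carry-over as a
#'   signal source (yields a 49-entry registry).
#' @return A data frame with columns `name`, `source`, `aggregate`,
#'   `category`; the default has exactly 50 rows.
#' @export
#' @examples
#' reg <- default_feature_registry()
#' nrow(reg)          # 50
#' table(reg$category)
default_feature_registry <- function(include_prior_k6 = TRUE) {
  daily <- data.frame(
    source = c("sleep_duration", "sleep_efficiency", "sleep_start",
               "sleep_end", "steps", "distance", "floors", "calories",
               "hr_mean", "hr_sd", "working_hours", "work_start",
               "work_end", "working_hour_gap", "scheduled_hours"),
    category = c("sleep", "sleep", "sleep", "sleep", "activity", "activity",
                 "activity", "activity", "activity", "activity", "work",
                 "work", "work", "work", "work"),
    stringsAsFactors = FALSE
  )
  mean_sd <- do.call(rbind, lapply(seq_len(nrow(daily)), function(i) {
    data.frame(
      name = paste0(daily$source[i], c("_mean", "_sd")),
      source = daily$source[i],
      aggregate = c("weekly_mean", "weekly_sd"),
      category = daily$category[i],
      stringsAsFactors = FALSE
    )
  }))
  counts <- data.frame(
    name = c("worked_days", "wfh_days", "absence_days", "telework_rate_week",
             "outings", "lunches_skipped"),
    source = c("worked_days", "wfh_days", "absence_days",
               "telework_rate_week", "outings", "lunches_skipped"),
    aggregate = "weekly_count",
    category = c("work", "work", "work", "work", "questionnaire",
                 "questionnaire"),
    stringsAsFactors = FALSE
  )
  sums <- data.frame(
    name = paste0(c("steps", "distance", "floors", "calories"), "_sum"),
    source = c("steps", "distance", "floors", "calories"),
    aggregate = "weekly_sum",
    category = "activity",
    stringsAsFactors = FALSE
  )
  devs <- data.frame(
    name = paste0(c("hr_mean", "calories", "sleep_duration", "work_start",
                    "steps"), "_dev"),
    source = c("hr_mean", "calories", "sleep_duration", "work_start",
               "steps"),
    aggregate = "deviation",
    category = c("activity", "activity", "sleep", "work", "activity"),
    stringsAsFactors = FALSE
  )
  deltas <- data.frame(
    name = paste0("delta_", c("sleep_duration_mean", "steps_sum", "hr_mean_mean",
                              "working_hours_mean")),
    source = c("sleep_duration_mean", "steps_sum", "hr_mean_mean",
               "working_hours_mean"),
    aggregate = "delta",
    category = c("sleep", "activity", "activity", "work"),
    stringsAsFactors = FALSE
  )
  reg <- rbind(mean_sd, counts, sums, devs, deltas)
  if (include_prior_k6) {
    reg <- rbind(reg, data.frame(
      name = "k6_total_prev", source = "k6_total",
      aggregate = "questionnaire", category = "questionnaire",
      stringsAsFactors = FALSE
    ))
  }
  rownames(reg) <- NULL
  validate_registry(reg)
  reg
}

#' Validate a feature registry
#'
#' @param registry a data frame as returned by [default_feature_registry()].
#' @return The registry, invisibly, or an error naming the violated rule.
#' @export
validate_registry <- function(registry) {
  needed <- c("name", "source", "aggregate", "category")
  if (!is.data.frame(registry) || !all(needed %in% names(registry))) {
    stopf("registry must be a data frame with columns %s",
          paste(needed, collapse = ", "))
  }
  if (anyDuplicated(registry$name)) {
    stopf("registry feature names must be unique (duplicate: %s)",
          registry$name[duplicated(registry$name)][1])
  }
  ok_agg <- c("weekly_mean", "weekly_sd", "weekly_sum", "weekly_count",
              "deviation", "delta", "questionnaire")
  bad <- setdiff(unique(registry$aggregate), ok_agg)
  if (length(bad)) stopf("unknown aggregation kind: %s", bad[1])
  ok_cat <- c("sleep", "activity", "work", "questionnaire")
  bad <- setdiff(unique(registry$category), ok_cat)
  if (length(bad)) stopf("unknown category: %s", bad[1])
  invisible(registry)
}
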