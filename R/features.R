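#' Aggregate one week of daily values
#'
#' Weekly summaries follow fixed missingness rules: the mean is computed over
#' whatever daily values are present and is missing only when the entire week
#' (all 7 days) is missing; the unbiased (n - 1) SD requires at least 2
#' present values and is missing otherwise; the sum, like the mean, is
#' missing only when every day is missing.
#'
#' @param values numeric vector of at most 7 daily values, `NA` = missing.
#' @param kind one of `"mean"`, `"sd"`, `"sum"`.
#' @return A single numeric value, `NA` under the rules above.
#' @export
#' @examples
#' aggregate_week(c(NA, NA, NA, NA, NA, NA, NA), "mean")  # NA
#' aggregate_week(c(8, NA, NA, NA, NA, NA, NA), "mean")   # 8
#' aggregate_week(c(8, NA, NA, NA, NA, NA, NA), "sd")     # NA
#' aggregate_week(1:7, "sd")                              # sqrt(28/6)
aggregate_week <- function(values, kind = c("mean", "sd", "sum")) {
  kind <- match.arg(kind)
  if (length(values) > 7L) {
    stopf("aggregate_week expects at most 7 daily values, got %d",
          length(values))
  }
  present <- values[!is.na(values)]
  n <- length(present)
  switch(kind,
    mean = if (n == 0L) NA_real_ else mean(present),
    sd   = if (n <  2L) NA_real_ else stats::sd(present),
    sum  = if (n == 0L) NA_real_ else sum(present)
  )
}

#' Map a K6 total to its stress class and binary label
#'
#' K6 totals (0-24) are binned into four classes: class 1 (0-4) is
#' stress-negative; classes 2 (5-8), 3 (9-12) and 4 (13 or more) are
#' stress-positive.
#'
#' @param total integer vector of K6 totals in 0-24.
#' @return A data frame with columns `k6_total`, `k6_class` (1-4) and
#'   `binary` (`"negative"`/`"positive"`).
#' @export
#' @examples
#' binarize_k6(c(0, 4, 5, 12, 13, 24))
binarize_k6 <- function(total) {
  if (any(is.na(total)) || any(total < 0 | total > 24)) {
    stopf("K6 totals must be in 0..24")
  }
  k6_class <- ifelse(total <= 4, 1L,
              ifelse(total <= 8, 2L,
              ifelse(total <= 12, 3L, 4L)))
  data.frame(
    k6_total = as.integer(total),
    k6_class = k6_class,
    binary = ifelse(k6_class == 1L, "negative", "positive"),
    stringsAsFactors = FALSE
  )
}

# Daily derived frame for one participant: a 7 x n_weeks day grid holding
# wearable variables and derived work variables, with the week index.
daily_frame <- function(p, n_weeks, start_date) {
  dates <- start_date + 0:(n_weeks * 7L - 1L)
  grid <- data.frame(date = dates, week = week_of(dates, start_date))

  wcols <- c("sleep_duration", "sleep_efficiency", "sleep_start", "sleep_end",
             "steps", "distance", "floors", "calories", "hr_mean", "hr_sd")
  w <- p$wearable
  if (is.null(w) || nrow(w) == 0L) {
    for (v in wcols) grid[[v]] <- NA_real_
  } else {
    idx <- match(grid$date, w$date)
    for (v in wcols) grid[[v]] <- as.numeric(w[[v]][idx])
  }

  s <- p$shifts
  scols <- c("actual_start", "actual_end", "scheduled_start", "scheduled_end",
             "scheduled_hours")
  if (is.null(s) || nrow(s) == 0L) {
    for (v in scols) grid[[v]] <- NA_real_
    grid$wfh <- NA
    grid$absent <- NA
    grid$has_shift <- FALSE
  } else {
    idx <- match(grid$date, s$date)
    for (v in scols) grid[[v]] <- as.numeric(s[[v]][idx])
    grid$wfh <- s$wfh[idx]
    grid$absent <- s$absent[idx]
    grid$has_shift <- !is.na(idx)
  }

  # Derived work variables; undefined on absent or unrecorded days.
  worked <- grid$has_shift & !is.na(grid$absent) & !grid$absent
  grid$working_hours <- ifelse(worked,
                               (grid$actual_end - grid$actual_start) / 60,
                               NA_real_)
  grid$working_hour_gap <- grid$working_hours - ifelse(worked,
                                                       grid$scheduled_hours,
                                                       NA_real_)
  grid$work_start <- ifelse(worked, grid$actual_start, NA_real_)
  grid$work_end <- ifelse(worked, grid$actual_end, NA_real_)
  grid$scheduled_hours <- ifelse(worked, grid$scheduled_hours, NA_real_)
  grid$worked <- worked
  grid
}

#' Build weekly feature vectors for one participant
#'
#' Aggregates the daily wearable and work-shift streams into one row per
#' study week according to a feature registry, applying the weekly
#' missingness rules of [aggregate_week()]. Derived daily work variables
#' (working hours, working-hour gap, work start/end) are computed before
#' aggregation; count features and questionnaire features are filled per
#' week; deviation and week-over-week change features are derived last.
#'
#' @param p a participant record: a list with elements `participant_id`,
#'   `wearable`, `shifts`, `questionnaires` (as read by the ingest readers
#'   or produced by [simulate_cohort()] + [assemble_participants()]).
#' @param registry a feature registry, see [default_feature_registry()].
#' @param n_weeks number of study weeks (default 12).
#' @param start_date first day of week 1 (a Monday). Defaults to the Monday
#'   on or before the participant's earliest record.
#' @return A data frame with `participant_id`, `week_index`, one column per
#'   registry feature, and `k6_total` (the same week's questionnaire total,
#'   `NA` when unanswered).
#' @export
build_weekly_features <- function(p, registry = default_feature_registry(),
                                  n_weeks = 12L, start_date = NULL) {
  validate_registry(registry)
  if (is.null(start_date)) {
    all_dates <- c(p$wearable$date, p$shifts$date)
    if (length(all_dates) == 0L) {
      stopf("participant %s has no dated records and no start_date given",
            p$participant_id)
    }
    start_date <- week_origin(all_dates)
  }
  grid <- daily_frame(p, n_weeks, start_date)
  wk <- factor(grid$week, levels = seq_len(n_weeks))

  out <- data.frame(participant_id = p$participant_id,
                    week_index = seq_len(n_weeks),
                    stringsAsFactors = FALSE)

  agg_by_week <- function(var, kind) {
    vapply(split(grid[[var]], wk), aggregate_week, numeric(1), kind = kind)
  }

  q <- p$questionnaires
  qidx <- if (!is.null(q) && nrow(q)) match(out$week_index, q$week_index)
          else rep(NA_integer_, n_weeks)

  weekly_cache <- new.env(parent = emptyenv())
  get_weekly <- function(var, kind) {
    key <- paste0(var, ".", kind)
    if (is.null(weekly_cache[[key]])) {
      weekly_cache[[key]] <- agg_by_week(var, kind)
    }
    weekly_cache[[key]]
  }

  counts <- local({
    worked <- as.numeric(tapply(grid$worked, wk, sum))
    wfh <- as.numeric(tapply(grid$worked & !is.na(grid$wfh) & grid$wfh,
                             wk, sum))
    absent <- as.numeric(tapply(grid$has_shift & !is.na(grid$absent) &
                                  grid$absent, wk, sum))
    list(
      worked_days = worked,
      wfh_days = wfh,
      absence_days = absent,
      telework_rate_week = ifelse(worked > 0, wfh / worked, NA_real_)
    )
  })

  # First pass: everything except deviation / delta features.
  for (i in seq_len(nrow(registry))) {
    nm <- registry$name[i]; src <- registry$source[i]
    out[[nm]] <- switch(registry$aggregate[i],
      weekly_mean = get_weekly(src, "mean"),
      weekly_sd = get_weekly(src, "sd"),
      weekly_sum = get_weekly(src, "sum"),
      weekly_count = {
        if (src %in% names(counts)) counts[[src]]
        else if (!is.null(q) && src %in% names(q)) as.numeric(q[[src]][qidx])
        else stopf("unknown count source variable '%s' in registry", src)
      },
      questionnaire = {
        if (is.null(q) || !src %in% names(q)) {
          rep(NA_real_, n_weeks)
        } else as.numeric(q[[src]][qidx])
      },
      deviation = rep(NA_real_, n_weeks),  # second pass
      delta = rep(NA_real_, n_weeks)       # second pass
    )
    if (!registry$aggregate[i] %in% c("deviation", "delta") &&
        !src %in% c(names(counts), "outings", "lunches_skipped", "k6_total") &&
        !src %in% names(grid)) {
      stopf("unknown registry source variable '%s'", src)
    }
  }

  # Second pass: deviations from the participant's study-long daily mean,
  # and week-over-week changes of already-computed weekly features.
  for (i in which(registry$aggregate == "deviation")) {
    src <- registry$source[i]
    if (!src %in% names(grid)) stopf("unknown registry source variable '%s'", src)
    baseline <- if (all(is.na(grid[[src]]))) NA_real_
                else mean(grid[[src]], na.rm = TRUE)
    out[[registry$name[i]]] <- abs(get_weekly(src, "mean") - baseline)
  }
  for (i in which(registry$aggregate == "delta")) {
    src <- registry$source[i]
    if (!src %in% names(out)) {
      stopf("delta feature '%s' needs base feature '%s' in the registry",
            registry$name[i], src)
    }
    v <- out[[src]]
    out[[registry$name[i]]] <- v - c(NA_real_, v[-n_weeks])
  }

  out$k6_total <- if (!is.null(q) && nrow(q)) as.numeric(q$k6_total[qidx])
                  else rep(NA_real_, n_weeks)
  out
}

#' Build weekly features for every participant of a cohort
#'
#' @param participants list of participant records
#'   (see [assemble_participants()]).
#' @inheritParams build_weekly_features
#' @return One stacked data frame of weekly feature vectors.
#' @export
build_cohort_features <- function(participants,
                                  registry = default_feature_registry(),
                                  n_weeks = 12L, start_date = NULL) {
  if (is.null(start_date)) {
    all_dates <- do.call(c, lapply(participants, function(p)
      c(p$wearable$date, p$shifts$date)))
    start_date <- week_origin(all_dates)
  }
  do.call(rbind, lapply(participants, build_weekly_features,
                        registry = registry, n_weeks = n_weeks,
                        start_date = start_date))
}

#' Pair lagged features with next-week stress labels
#'
#' Builds supervised instances: the features of week t - 1 predict the
#' binary stress label of week t, for t = 2..n_weeks. Weeks whose K6 label
#' is missing are dropped (and counted in the `dropped` attribute); a
#' participant with w complete weeks contributes at most w - 1 instances
#' (11 for a 12-week study).
#'
#' @param weekly a weekly feature data frame from [build_cohort_features()]
#'   (must contain `k6_total` label columns).
#' @param registry the registry used to build `weekly`.
#' @return A data frame with `participant_id`, `label_week`, `k6_total`,
#'   `k6_class`, `label` (1 = stress-positive), and the lagged feature
#'   columns; attribute `feature_names` holds the registry order and
#'   attribute `dropped` the number of label-missing week pairs skipped.
#' @export
build_instances <- function(weekly, registry = default_feature_registry()) {
  validate_registry(registry)
  fnames <- registry$name
  missing_cols <- setdiff(fnames, names(weekly))
  if (length(missing_cols)) {
    stopf("weekly features lack registry columns: %s",
          paste(missing_cols, collapse = ", "))
  }
  parts <- split(weekly, weekly$participant_id)
  dropped <- 0L
  rows <- lapply(parts, function(wp) {
    wp <- wp[order(wp$week_index), , drop = FALSE]
    n <- nrow(wp)
    if (n < 2L) return(NULL)
    lab_weeks <- wp$week_index[-1L]
    feat_rows <- wp[match(lab_weeks - 1L, wp$week_index), fnames,
                    drop = FALSE]
    k6 <- wp$k6_total[match(lab_weeks, wp$week_index)]
    keep <- !is.na(k6)
    dropped <<- dropped + sum(!keep)
    if (!any(keep)) return(NULL)
    lab <- binarize_k6(k6[keep])
    cbind(
      data.frame(participant_id = wp$participant_id[1L],
                 label_week = lab_weeks[keep],
                 k6_total = lab$k6_total,
                 k6_class = lab$k6_class,
                 label = as.integer(lab$binary == "positive"),
                 stringsAsFactors = FALSE),
      feat_rows[keep, , drop = FALSE]
    )
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- cbind(data.frame(participant_id = character(0),
                            label_week = integer(0), k6_total = integer(0),
                            k6_class = integer(0), label = integer(0)),
                 as.data.frame(matrix(numeric(0), 0, length(fnames),
                                      dimnames = list(NULL, fnames))))
  }
  rownames(out) <- NULL
  attr(out, "feature_names") <- fnames
  attr(out, "dropped") <- dropped
  out
}
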