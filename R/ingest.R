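# CSV dialects: UTF-8, comma-separated, ISO-8601 dates, blank = missing.
# Clock times are signed minutes from midnight of the record's date
# (sleep_start of -30 means 23:30 the previous evening).

wearable_header <- function() {
  c("participant_id", "date", wearable_value_cols())
}
shifts_header <- function() {
  c("participant_id", "date", shift_value_cols())
}
questionnaire_header <- function() {
  c("participant_id", "week_index", paste0("k6_item", 1:6), "k6_total",
    "outings", "lunches_skipped")
}

read_stream <- function(path, header) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  got <- strsplit(readLines(path, n = 1L), ",", fixed = TRUE)[[1]]
  if (!identical(got, header)) {
    stopf("%s: malformed header; expected columns %s", basename(path),
          paste(header, collapse = ", "))
  }
  utils::read.csv(path, stringsAsFactors = FALSE,
                  colClasses = c(participant_id = "character"))
}

check_range <- function(df, col, lo, hi, path) {
  v <- df[[col]]
  bad <- which(!is.na(v) & (v < lo | v > hi))
  if (length(bad)) {
    stopf("%s: %s out of range [%s, %s] at row %d (value %s)",
          basename(path), col, lo, hi, bad[1], v[bad[1]])
  }
}

#' Read a daily wearable CSV stream
#'
#' One row per participant-day of device data (sleep, activity, daily heart
#' rate summaries). Blank cells become missing values; out-of-range values
#' are rejected with the offending row named rather than dropped silently.
#'
#' @param path path to a `wearable.csv` file.
#' @return A data frame of daily wearable records with `date` parsed.
#' @export
read_wearable <- function(path) {
  df <- read_stream(path, wearable_header())
  if (nrow(df) == 0L) {
    df$date <- as.Date(character(0))
    return(df)
  }
  df$date <- as.Date(df$date)
  if (anyNA(df$date)) {
    stopf("%s: unparseable date at row %d", basename(path),
          which(is.na(df$date))[1])
  }
  check_range(df, "sleep_efficiency", 0, 100, path)
  for (col in c("steps", "distance", "floors", "calories")) {
    check_range(df, col, 0, Inf, path)
  }
  bad <- which(!is.na(df$hr_mean) & (df$hr_mean <= 20 | df$hr_mean >= 250))
  if (length(bad)) {
    stopf("%s: hr_mean outside (20, 250) at row %d", basename(path), bad[1])
  }
  df
}

#' Read a daily work-shift CSV stream
#'
#' @param path path to a `shifts.csv` file.
#' @return A data frame of work-shift records (`wfh`, `absent` logical).
#' @export
read_shifts <- function(path) {
  df <- read_stream(path, shifts_header())
  df$wfh <- as.logical(df$wfh)
  df$absent <- as.logical(df$absent)
  if (nrow(df) == 0L) {
    df$date <- as.Date(character(0))
    return(df)
  }
  df$date <- as.Date(df$date)
  if (anyNA(df$date)) {
    stopf("%s: unparseable date at row %d", basename(path),
          which(is.na(df$date))[1])
  }
  both <- !is.na(df$actual_start) & !is.na(df$actual_end)
  bad <- which(both & df$actual_end < df$actual_start)
  if (length(bad)) {
    stopf("%s: actual_end before actual_start at row %d", basename(path),
          bad[1])
  }
  worked <- !is.na(df$absent) & !df$absent
  bad <- which(worked & !is.na(df$scheduled_hours) & df$scheduled_hours <= 0)
  if (length(bad)) {
    stopf("%s: non-positive scheduled_hours on worked day at row %d",
          basename(path), bad[1])
  }
  bad <- which(!is.na(df$absent) & df$absent &
                 (!is.na(df$actual_start) | !is.na(df$actual_end)))
  if (length(bad)) {
    stopf("%s: absent day has actual work times at row %d", basename(path),
          bad[1])
  }
  df
}

#' Read a weekly questionnaire CSV stream
#'
#' Recomputes each row's K6 total from the six items and rejects mismatches.
#'
#' @param path path to a `questionnaires.csv` file.
#' @return A data frame of weekly questionnaire records.
#' @export
read_questionnaires <- function(path) {
  df <- read_stream(path, questionnaire_header())
  if (nrow(df) == 0L) return(df)
  items <- as.matrix(df[, paste0("k6_item", 1:6)])
  bad <- which(apply(items, 1, function(r) any(is.na(r) | r < 0 | r > 4)))
  if (length(bad)) {
    stopf("%s: K6 item outside 0..4 at row %d", basename(path), bad[1])
  }
  tot <- rowSums(items)
  bad <- which(is.na(df$k6_total) | df$k6_total != tot)
  if (length(bad)) {
    stopf("%s: k6_total (%s) does not equal the item sum (%d) at row %d",
          basename(path), df$k6_total[bad[1]], tot[bad[1]], bad[1])
  }
  check_range(df, "lunches_skipped", 0, 7, path)
  check_range(df, "outings", 0, Inf, path)
  df
}

#' Group the three streams into per-participant records
#'
#' Participants present in only some streams are retained with the missing
#' streams empty (a warning lists them); duplicate dates or week indices
#' within one participant's stream are rejected.
#'
#' @param wearable,shifts,questionnaires data frames from the readers.
#' @return A named list of participant records, each a list with
#'   `participant_id`, `wearable`, `shifts`, `questionnaires`.
#' @export
assemble_participants <- function(wearable, shifts, questionnaires) {
  ids <- sort(unique(c(wearable$participant_id, shifts$participant_id,
                       questionnaires$participant_id)))
  incomplete <- character(0)
  out <- lapply(ids, function(id) {
    w <- wearable[wearable$participant_id == id, , drop = FALSE]
    s <- shifts[shifts$participant_id == id, , drop = FALSE]
    q <- questionnaires[questionnaires$participant_id == id, , drop = FALSE]
    if (anyDuplicated(w$date)) {
      stopf("participant %s: duplicate wearable date %s", id,
            w$date[duplicated(w$date)][1])
    }
    if (anyDuplicated(s$date)) {
      stopf("participant %s: duplicate shift date %s", id,
            s$date[duplicated(s$date)][1])
    }
    if (anyDuplicated(q$week_index)) {
      stopf("participant %s: duplicate questionnaire week %d", id,
            q$week_index[duplicated(q$week_index)][1])
    }
    if (nrow(w) == 0L || nrow(s) == 0L || nrow(q) == 0L) {
      incomplete <<- c(incomplete, id)
    }
    rownames(w) <- rownames(s) <- rownames(q) <- NULL
    list(participant_id = id, wearable = w, shifts = s, questionnaires = q)
  })
  names(out) <- ids
  if (length(incomplete)) {
    warnf("%d participant(s) missing at least one stream: %s",
          length(incomplete), paste(incomplete, collapse = ", "))
  }
  out
}

#' Write a cohort's three CSV streams
#'
#' Emits `wearable.csv`, `shifts.csv` and `questionnaires.csv` in the
#' dialects the ingest readers expect (plus `ground_truth.csv` for
#' synthetic cohorts), so a written cohort round-trips losslessly through
#' [read_cohort()].
#'
#' @param cohort a `telestress_cohort` from [simulate_cohort()], or any
#'   list with the three stream data frames.
#' @param directory output directory, created if needed.
#' @return The directory, invisibly.
#' @export
write_cohort <- function(cohort, directory) {
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(directory)) stopf("cannot create directory %s", directory)
  wr <- function(df, cols, file) {
    df <- as.data.frame(df)[, cols, drop = FALSE]
    utils::write.csv(df, file.path(directory, file), row.names = FALSE,
                     na = "", quote = FALSE)
  }
  wr(cohort$wearable, wearable_header(), "wearable.csv")
  wr(cohort$shifts, shifts_header(), "shifts.csv")
  wr(cohort$questionnaires, questionnaire_header(), "questionnaires.csv")
  if (!is.null(cohort$ground_truth)) {
    utils::write.csv(cohort$ground_truth,
                     file.path(directory, "ground_truth.csv"),
                     row.names = FALSE, na = "", quote = FALSE)
  }
  invisible(directory)
}

#' Read a cohort directory written by [write_cohort()]
#'
#' @param directory directory holding the three stream CSVs.
#' @return A list with `wearable`, `shifts`, `questionnaires` data frames
#'   and `participants` (the assembled per-participant records).
#' @export
read_cohort <- function(directory) {
  w <- read_wearable(file.path(directory, "wearable.csv"))
  s <- read_shifts(file.path(directory, "shifts.csv"))
  q <- read_questionnaires(file.path(directory, "questionnaires.csv"))
  list(wearable = w, shifts = s, questionnaires = q,
       participants = assemble_participants(w, s, q))
}
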