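# Fixture builders shared across test files. All fixtures are constructed in
# code; nothing is read from disk except files the tests write themselves.

MON <- as.Date("2024-01-01")  # a Monday

# A hand-sized participant: `weeks` full weeks of wearable data (7 days) and
# Mon-Fri shifts, plus weekly questionnaires with the given K6 totals.
make_participant <- function(id = "P1", weeks = 3, k6 = rep(3, weeks),
                             wfh_days = 0, sleep = 420, steps = 8000,
                             actual_start = 540, actual_end = 1050,
                             scheduled_hours = 8) {
  nd <- weeks * 7
  dates <- MON + 0:(nd - 1)
  wearable <- data.frame(
    participant_id = id, date = dates,
    sleep_duration = sleep, sleep_efficiency = 92, sleep_start = -30,
    sleep_end = 400, steps = steps, distance = round(steps * 7e-4, 2),
    floors = 9, calories = 2100, hr_mean = 70, hr_sd = 8,
    stringsAsFactors = FALSE
  )
  wd <- dates[rep(1:7, weeks) <= 5]
  shifts <- data.frame(
    participant_id = id, date = wd,
    actual_start = actual_start, actual_end = actual_end,
    scheduled_start = 540, scheduled_end = 1050,
    scheduled_hours = scheduled_hours,
    wfh = FALSE, absent = FALSE, stringsAsFactors = FALSE
  )
  if (wfh_days > 0) shifts$wfh[seq_len(wfh_days)] <- TRUE
  items <- t(vapply(k6, function(tot) {
    v <- integer(6)
    for (j in seq_len(tot)) {
      open <- which(v < 4L)
      v[open[1]] <- v[open[1]] + 1L
    }
    v
  }, integer(6)))
  colnames(items) <- paste0("k6_item", 1:6)
  quest <- cbind(
    data.frame(participant_id = id, week_index = seq_len(weeks),
               stringsAsFactors = FALSE),
    items,
    data.frame(k6_total = k6, outings = 3, lunches_skipped = 1)
  )
  list(participant_id = id, wearable = wearable, shifts = shifts,
       questionnaires = quest)
}

# Teleworking profile frame from explicit rates.
make_profiles <- function(rates, ids = sprintf("P%02d", seq_along(rates))) {
  data.frame(participant_id = ids, days_wfh = round(rates * 60),
             days_worked = 60, rate = rates, stringsAsFactors = FALSE)
}

# Small seeded cohort reused by several modeling tests (cached per session).
small_cohort <- local({
  cache <- new.env()
  function(n = 25, seed = 11) {
    key <- paste0("c", n, "_", seed)
    if (is.null(cache[[key]])) {
      cache[[key]] <- simulate_cohort(cohort_spec(n_participants = n,
                                                  seed = seed))
    }
    cache[[key]]
  }
})
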