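test_that("weekly mean/SD/sum follow the missingness rules", {
  all_na <- rep(NA_real_, 7)
  expect_true(is.na(aggregate_week(all_na, "mean")))
  expect_true(is.na(aggregate_week(all_na, "sd")))
  expect_true(is.na(aggregate_week(all_na, "sum")))

  one <- c(8, rep(NA_real_, 6))
  expect_equal(aggregate_week(one, "mean"), 8)
  expect_true(is.na(aggregate_week(one, "sd")))  # unbiased SD needs >= 2
  expect_equal(aggregate_week(one, "sum"), 8)

  expect_equal(aggregate_week(1:7, "mean"), 4)
  expect_equal(aggregate_week(1:7, "sd"), sqrt(28 / 6), tolerance = 1e-10)
  expect_equal(aggregate_week(c(2, NA, 4), "mean"), 3)
  expect_equal(aggregate_week(c(5, 5, NA, 5), "sd"), 0)
  expect_error(aggregate_week(1:8, "mean"), "at most 7")
})

test_that("K6 totals map to the exact class and binary boundaries", {
  res <- binarize_k6(0:24)
  expect_equal(res$k6_class,
               c(rep(1L, 5), rep(2L, 4), rep(3L, 4), rep(4L, 12)))
  expect_equal(res$binary == "positive", 0:24 >= 5)
  expect_error(binarize_k6(25), "0..24")
  expect_error(binarize_k6(-1), "0..24")
})

test_that("the default registry has 50 uniquely named, categorized entries", {
  reg <- default_feature_registry()
  expect_equal(nrow(reg), 50L)
  expect_false(anyDuplicated(reg$name) > 0)
  expect_true(all(reg$category %in%
                    c("sleep", "activity", "work", "questionnaire")))
  expect_equal(nrow(default_feature_registry(include_prior_k6 = FALSE)), 49L)
  bad <- reg; bad$name[2] <- bad$name[1]
  expect_error(validate_registry(bad), "unique")
})

test_that("weekly vectors carry exactly the registry features for each week", {
  p <- make_participant(weeks = 4)
  reg <- default_feature_registry()
  w <- build_weekly_features(p, reg, n_weeks = 4, start_date = MON)
  expect_equal(nrow(w), 4L)
  expect_true(all(reg$name %in% names(w)))
  expect_equal(w$week_index, 1:4)
})

test_that("work-shift derived features match hand computation", {
  # 9:00-19:00 actual vs 8 scheduled hours, Mon-Fri
  p <- make_participant(weeks = 3, actual_start = 540, actual_end = 1140,
                        scheduled_hours = 8)
  w <- build_weekly_features(p, n_weeks = 3, start_date = MON)
  expect_equal(w$working_hours_mean, rep(10, 3))
  expect_equal(w$working_hour_gap_mean, rep(2, 3))
  expect_equal(w$working_hour_gap_sd, rep(0, 3))
  expect_equal(w$worked_days, rep(5, 3))
  expect_equal(w$scheduled_hours_mean, rep(8, 3))
})

test_that("WFH and absence days are counted; absence blanks work features", {
  p <- make_participant(weeks = 2, wfh_days = 2)
  w <- build_weekly_features(p, n_weeks = 2, start_date = MON)
  expect_equal(w$wfh_days[1], 2)
  expect_equal(w$worked_days, c(5, 5))
  expect_equal(w$telework_rate_week, c(2 / 5, 0))

  p2 <- make_participant(weeks = 2)
  p2$shifts$absent[1:5] <- TRUE  # whole first week absent
  p2$shifts$actual_start[1:5] <- NA
  p2$shifts$actual_end[1:5] <- NA
  w2 <- build_weekly_features(p2, n_weeks = 2, start_date = MON)
  expect_true(is.na(w2$working_hours_mean[1]))
  expect_equal(w2$absence_days[1], 5)
  expect_equal(w2$worked_days[1], 0)
})

test_that("instances pair week t-1 features with week t labels", {
  co <- small_cohort()
  parts <- assemble_participants(co$wearable, co$shifts, co$questionnaires)
  reg <- default_feature_registry()
  weekly <- build_cohort_features(parts, reg, 12, MON)
  inst <- build_instances(weekly, reg)
  # lag structure: label week t uses features of week t - 1, so <= 11 per id
  expect_true(all(table(inst$participant_id) <= 11))
  expect_true(all(inst$label_week >= 2))
  # cross-check one row against the weekly table
  r <- inst[17, ]
  wrow <- weekly[weekly$participant_id == r$participant_id &
                   weekly$week_index == r$label_week - 1, ]
  expect_equal(r$sleep_duration_mean, wrow$sleep_duration_mean)
  lrow <- weekly[weekly$participant_id == r$participant_id &
                   weekly$week_index == r$label_week, ]
  expect_equal(r$label, as.integer(lrow$k6_total >= 5))
})

test_that("weeks with a missing label are dropped but still lend features", {
  p <- make_participant(weeks = 6, k6 = c(3, 6, 2, 8, 1, 7))
  reg <- default_feature_registry()
  w <- build_weekly_features(p, reg, n_weeks = 6, start_date = MON)
  # drop the week-5 questionnaire: label week 5 vanishes, week 6 survives
  # (its features come from week 5, whose wearable data are intact)
  w$k6_total[w$week_index == 5] <- NA
  inst <- build_instances(w, reg)
  expect_false(5 %in% inst$label_week)
  expect_true(6 %in% inst$label_week)
  expect_equal(attr(inst, "dropped"), 1L)
  expect_equal(nrow(inst), 4L)

  one_week <- build_weekly_features(make_participant(weeks = 1), reg,
                                    n_weeks = 1, start_date = MON)
  expect_equal(nrow(build_instances(one_week, reg)), 0L)
})

test_that("delta features are week-over-week changes of the base feature", {
  p <- make_participant(weeks = 3)
  p$wearable$sleep_duration <- rep(c(400, 410, 430), each = 7)
  w <- build_weekly_features(p, n_weeks = 3, start_date = MON)
  expect_true(is.na(w$delta_sleep_duration_mean[1]))
  expect_equal(w$delta_sleep_duration_mean[2:3], c(10, 20))
})
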