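# Instances with controllable labels over a signal feature; all other
# registry features are noise.
toy_instances <- function(n, seed = 1, signal = TRUE) {
  reg <- default_feature_registry()
  set.seed(seed)
  m <- matrix(rnorm(n * nrow(reg)), n, nrow(reg),
              dimnames = list(NULL, reg$name))
  df <- data.frame(participant_id = sprintf("P%03d", rep(1:10, length.out = n)),
                   label_week = rep(2:12, length.out = n),
                   stringsAsFactors = FALSE)
  df <- cbind(df, as.data.frame(m))
  df$label <- if (signal) as.integer(df$steps_sum > 0) else
    rbinom(n, 1, 0.4)
  attr(df, "feature_names") <- reg$name
  df
}

test_that("per-target splits follow the label-week convention", {
  co <- small_cohort()
  prep <- list(
    instances = build_instances(build_cohort_features(
      assemble_participants(co$wearable, co$shifts, co$questionnaires),
      n_weeks = 12, start_date = MON)),
    profiles = telework_profiles(co$shifts))
  inst <- prep$instances
  cfg <- experiment_config()
  id <- "P0001"
  members <- setdiff(unique(inst$participant_id), id)[1:20]

  sp1 <- make_splits("proposed1", id, inst, members, cfg)
  # cluster members contribute all their instances; target only weeks 2-7
  expect_true(all(sp1$train$label_week[sp1$train$participant_id == id] %in% 2:7))
  member_rows <- inst[inst$participant_id %in% members, ]
  expect_equal(sum(sp1$train$participant_id %in% members), nrow(member_rows))
  expect_true(all(sp1$test$participant_id == id &
                    sp1$test$label_week %in% 8:12))

  sp2 <- make_splits("proposed2", id, inst, members, cfg)
  expect_true(all(sp2$train$label_week %in% 2:7))
  expect_true(all(sp2$adaptation$participant_id %in% members))
  expect_true(all(sp2$adaptation$label_week %in% 8:12))
  # with complete 12-week members the adaptation set is 5 x cluster size
  expect_lte(nrow(sp2$adaptation), 5L * length(members))

  # no test instance ever appears in training
  for (sp in list(sp1, sp2)) {
    keys <- function(df) paste(df$participant_id, df$label_week)
    expect_length(intersect(keys(sp$test), keys(sp$train)), 0L)
  }
})

test_that("a complete 12-week cohort yields 6 train + 5 test target instances", {
  co <- simulate_cohort(cohort_spec(n_participants = 22, seed = 13,
                                    wearable_missing_prob = 0,
                                    questionnaire_missing_prob = 0))
  prep <- telestress:::prepare_experiment_data(co,
                                               default_feature_registry())
  cfg <- experiment_config()
  id <- prep$profiles$participant_id[1]
  members <- setdiff(prep$profiles$participant_id, id)[1:20]
  sp <- make_splits("proposed1", id, prep$instances, members, cfg)
  expect_equal(sum(sp$train$participant_id == id), 6L)
  expect_equal(nrow(sp$test), 5L)
  expect_equal(sum(sp$train$participant_id %in% members), 20L * 11L)
  sp2 <- make_splits("proposed2", id, prep$instances, members, cfg)
  expect_equal(nrow(sp2$adaptation), 5L * 20L)
})

test_that("training is deterministic and rejects one-class sets", {
  inst <- toy_instances(120, seed = 2)
  cfg <- experiment_config(seed = 5)
  m1 <- train_model(inst, attr(inst, "feature_names"), cfg)
  m2 <- train_model(inst, attr(inst, "feature_names"), cfg)
  expect_identical(predict_instances(m1, inst)$score,
                   predict_instances(m2, inst)$score)
  one_class <- inst[inst$label == 1, ]
  expect_error(train_model(one_class, attr(inst, "feature_names"), cfg),
               "degenerate training set")
})

test_that("a separable signal is learned to training accuracy 1", {
  inst <- toy_instances(150, seed = 3)
  m <- train_model(inst, attr(inst, "feature_names"), experiment_config())
  pr <- predict_instances(m, inst)
  expect_equal(mean(pr$predicted == pr$actual), 1)
})

test_that("score >= threshold predicts positive, below predicts negative", {
  inst <- toy_instances(60, seed = 4)
  m <- train_model(inst, attr(inst, "feature_names"), experiment_config())
  m$threshold <- 0.5
  pr <- predict_instances(m, inst)
  expect_equal(pr$predicted, as.integer(pr$score >= 0.5))
  empty <- inst[0, ]
  expect_equal(nrow(predict_instances(m, empty)), 0L)
})

test_that("threshold adaptation returns the minimal-FP threshold with TP above target", {
  # cleanly separated scores
  res <- adapt_threshold(c(0.9, 0.9, 0.1, 0.1), c(1, 1, 0, 0))
  expect_equal(res$threshold, 0.9)
  expect_equal(res$achieved_tp, 1)
  expect_equal(res$achieved_fp, 0)
  expect_true(res$constraint_met)

  # worked mixed case: TP > 0.8 requires all 5 positives, so threshold 0.4
  scores <- c(0.9, 0.8, 0.7, 0.6, 0.4, 0.55, 0.3, 0.2)
  labels <- c(1, 1, 1, 1, 1, 0, 0, 0)
  res <- adapt_threshold(scores, labels)
  expect_equal(res$threshold, 0.4)
  expect_equal(res$achieved_tp, 1)
  expect_equal(res$achieved_fp, 1 / 3)

  # degenerate: all scores identical
  res <- adapt_threshold(rep(0.5, 6), c(1, 0, 1, 0, 1, 0))
  expect_equal(res$threshold, 0.5)
  expect_equal(res$achieved_tp, 1)
  expect_equal(res$achieved_fp, 1)
  expect_true(res$constraint_met)

  # badly ranked scores: the TP floor is still attainable by a low
  # threshold, at the cost of FP = 1 (TP = 1 is always reachable at the
  # minimum score, so the constraint cannot fail outright)
  res <- adapt_threshold(c(0.2, 0.9), c(1, 0), tp_target = 0.8)
  expect_true(res$constraint_met)
  expect_equal(res$threshold, 0.2)
  expect_equal(res$achieved_fp, 1)
  expect_error(adapt_threshold(c(0.5, 0.6), c(0, 0)), "positive")
})

test_that("raising the threshold never raises TP or FP rates", {
  set.seed(10)
  scores <- runif(40)
  labels <- rbinom(40, 1, 0.4)
  ths <- sort(unique(scores))
  tp <- vapply(ths, function(t) mean(scores[labels == 1] >= t), 0)
  fp <- vapply(ths, function(t) mean(scores[labels == 0] >= t), 0)
  expect_true(all(diff(tp) <= 0))
  expect_true(all(diff(fp) <= 0))
})

test_that("the single method fits one pooled model; fits are seed-reproducible", {
  co <- small_cohort()
  cfg <- experiment_config(seed = 21)
  fs <- suppressMessages(telestress(co, "single", cfg))
  expect_length(fs$models, 1L)
  expect_true(all(fs$predictions$label_week %in% 8:12))
  expect_equal(unique(vapply(fs$models, function(m) m$model$threshold, 0)),
               0.5)
  fs2 <- suppressMessages(telestress(co, "single", cfg))
  expect_identical(fs$predictions, fs2$predictions)
})

test_that("personalized fits train one model per eligible target", {
  co <- small_cohort()
  cfg <- experiment_config(seed = 21)
  f1 <- suppressMessages(telestress(co, "proposed1", cfg))
  n_targets <- nrow(f1$profiles)
  expect_equal(length(f1$models) + length(f1$skipped), n_targets)
  # per-target cluster sizes are min(20, pool)
  pool <- n_targets - 1L
  sizes <- vapply(f1$models, function(m) length(m$member_ids), 0L)
  expect_true(all(sizes == min(20L, pool)))
  # proposed2 thresholds come from adaptation
  f2 <- suppressMessages(telestress(co, "proposed2", cfg))
  ths <- vapply(f2$models, function(m) m$model$threshold, 0)
  ads <- lapply(f2$models, `[[`, "adaptation")
  expect_equal(unname(ths),
               unname(vapply(ads, `[[`, numeric(1), "threshold")))
})

test_that("targets without test-period data are skipped but keep donating", {
  co <- simulate_cohort(cohort_spec(n_participants = 23, seed = 31,
                                    questionnaire_missing_prob = 0))
  # erase one participant's questionnaires for label weeks 8-12
  drop_id <- "P0005"
  q <- co$questionnaires
  co$questionnaires <- q[!(q$participant_id == drop_id &
                             q$week_index >= 8), ]
  f1 <- suppressMessages(telestress(co, "proposed1",
                                    experiment_config(seed = 31)))
  expect_true(drop_id %in% names(f1$skipped))
  expect_false(drop_id %in% names(f1$models))
  # its training-period instances still appear in someone's training pool
  donors <- vapply(f1$models, function(m)
    drop_id %in% m$member_ids, logical(1))
  expect_true(any(donors))
})
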