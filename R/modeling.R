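#' Experiment configuration
#'
#' Fixed learner hyperparameters shared by all three methods: gradient
#' boosted trees with `max_depth = 6`, `learning_rate = 0.3`, 100 boosting
#' rounds, no hyperparameter search. `single` and `proposed1` classify at a
#' fixed 0.5 probability threshold; `proposed2` adapts the threshold on
#' held-out neighborhood weeks to push the true-positive rate above
#' `tp_target` at the lowest attainable false-positive rate.
#'
#' @param max_depth,learning_rate,nrounds learner hyperparameters.
#' @param fixed_threshold classification threshold for the non-adapted
#'   methods (default 0.5).
#' @param tp_target true-positive-rate floor for threshold adaptation, in
#'   (0, 1) (default 0.8).
#' @param cluster_size neighborhood cluster size (default 20).
#' @param train_weeks label weeks of the training period (default 2:7, the
#'   "first 7 weeks" under a one-week lag).
#' @param test_weeks label weeks of the test period (default 8:12).
#' @param seed experiment seed; per-target learner seeds are derived from
#'   it.
#' @return An `experiment_config` list.
#' @export
experiment_config <- function(max_depth = 6L, learning_rate = 0.3,
                              nrounds = 100L, fixed_threshold = 0.5,
                              tp_target = 0.8, cluster_size = 20L,
                              train_weeks = 2:7, test_weeks = 8:12,
                              seed = 1L) {
  if (!(tp_target > 0 && tp_target < 1)) stopf("tp_target must be in (0, 1)")
  if (length(intersect(train_weeks, test_weeks))) {
    stopf("train_weeks and test_weeks must not overlap")
  }
  structure(list(max_depth = as.integer(max_depth),
                 learning_rate = learning_rate,
                 nrounds = as.integer(nrounds),
                 fixed_threshold = fixed_threshold, tp_target = tp_target,
                 cluster_size = as.integer(cluster_size),
                 train_weeks = as.integer(train_weeks),
                 test_weeks = as.integer(test_weeks),
                 seed = as.integer(seed)),
            class = "experiment_config")
}

instance_key <- function(df) paste(df$participant_id, df$label_week)

take <- function(instances, ids, weeks) {
  instances[instances$participant_id %in% ids &
              instances$label_week %in% weeks, , drop = FALSE]
}

#' Build the train / adaptation / test split for one prediction target
#'
#' Splits are by label calendar week: the "first 7 weeks" of a 12-week
#' study contribute label weeks 2-7 (six lagged instances; week 1 has no
#' predictor week before it) and the "latter 5 weeks" label weeks 8-12.
#' \describe{
#'   \item{proposed1}{train = all 11 instances of every cluster member plus
#'     the target's label weeks 2-7; test = target's label weeks 8-12.}
#'   \item{proposed2}{train = cluster members' and target's label weeks
#'     2-7; adaptation = cluster members' label weeks 8-12; test =
#'     target's label weeks 8-12.}
#' }
#' The single model is split globally (everyone's weeks 2-7 vs 8-12), not
#' per target.
#'
#' @param method `"proposed1"` or `"proposed2"`.
#' @param target_id the prediction target.
#' @param instances supervised instances from [build_instances()].
#' @param member_ids cluster member ids from [extract_neighborhood()].
#' @param config an [experiment_config()].
#' @return List with data frames `train`, `adaptation` (`NULL` for
#'   proposed1), `test`.
#' @export
make_splits <- function(method, target_id, instances, member_ids,
                        config = experiment_config()) {
  tw <- config$train_weeks; sw <- config$test_weeks
  all_weeks <- c(tw, sw)
  if (method == "proposed1") {
    train <- rbind(take(instances, member_ids, all_weeks),
                   take(instances, target_id, tw))
    adaptation <- NULL
  } else if (method == "proposed2") {
    train <- take(instances, c(member_ids, target_id), tw)
    adaptation <- take(instances, member_ids, sw)
  } else {
    stopf("make_splits handles proposed1/proposed2; the single model is split globally")
  }
  test <- take(instances, target_id, sw)
  stopifnot(length(intersect(instance_key(test), instance_key(train))) == 0L)
  list(train = train, adaptation = adaptation, test = test)
}

instance_matrix <- function(instances, feature_names) {
  m <- as.matrix(instances[, feature_names, drop = FALSE])
  storage.mode(m) <- "double"
  m
}

#' Train a gradient-boosted stress classifier
#'
#' Fits a binary logistic gradient-boosted tree ensemble on lagged weekly
#' features. Missing feature values are handled natively by the learner's
#' sparsity-aware splits; no imputation is performed. Training is
#' single-threaded and seeded, so identical inputs give identical models.
#'
#' @param train training instances (must contain both classes).
#' @param feature_names feature columns, in registry order.
#' @param config an [experiment_config()].
#' @param seed learner seed (defaults to `config$seed`).
#' @return A `telestress_model`: list with the fitted booster, the feature
#'   names, and the decision `threshold` (initialized to the fixed one).
#' @export
train_model <- function(train, feature_names, config = experiment_config(),
                        seed = config$seed) {
  y <- train$label
  if (length(unique(y)) < 2L) {
    stopf("degenerate training set: only class %s present (%d instances)",
          unique(y), nrow(train))
  }
  dtrain <- xgboost::xgb.DMatrix(instance_matrix(train, feature_names),
                                 label = y, missing = NA)
  params <- xgboost::xgb.params(
    objective = "binary:logistic",
    max_depth = config$max_depth,
    eta = config$learning_rate,
    nthread = 1L,
    seed = as.integer(seed %% .Machine$integer.max)
  )
  booster <- xgboost::xgb.train(params, dtrain, nrounds = config$nrounds,
                                verbose = 0)
  structure(list(booster = booster, feature_names = feature_names,
                 threshold = config$fixed_threshold, n_train = nrow(train),
                 seed = as.integer(seed)),
            class = "telestress_model")
}

model_scores <- function(model, instances, type = c("prob", "margin")) {
  type <- match.arg(type)
  if (!all(model$feature_names %in% names(instances))) {
    stopf("instances lack the model's feature columns")
  }
  if (nrow(instances) == 0L) return(numeric(0))
  m <- instance_matrix(instances, model$feature_names)
  predict(model$booster, m, outputmargin = (type == "margin"))
}

#' Adapt the decision threshold under a true-positive-rate constraint
#'
#' Scans candidate thresholds (the distinct observed scores, plus one above
#' the maximum) and returns, among candidates whose true-positive rate on
#' the adaptation data exceeds `tp_target`, the one with the lowest
#' false-positive rate, breaking remaining ties by the highest threshold.
#' The FP-minimizing solution is always attained at an observed score, so
#' the scan is exact. If no candidate clears the TP floor, the threshold
#' maximizing the TP rate (then minimal FP, then highest threshold) is
#' returned with `constraint_met = FALSE` and a warning.
#'
#' A prediction is positive when its score is greater than or equal to the
#' threshold.
#'
#' @param scores predicted positive-class probabilities.
#' @param labels 0/1 actual labels (at least one positive required).
#' @param tp_target TP-rate floor (default 0.8).
#' @return A `threshold_adaptation` list: `threshold`, `achieved_tp`,
#'   `achieved_fp`, `constraint_met`.
#' @export
adapt_threshold <- function(scores, labels, tp_target = 0.8) {
  if (length(scores) != length(labels)) stopf("scores/labels length mismatch")
  labels <- as.integer(labels)
  n_pos <- sum(labels == 1L); n_neg <- sum(labels == 0L)
  if (n_pos == 0L) stopf("threshold adaptation needs at least one positive label")
  cand <- sort(unique(c(scores, max(scores) + 1)), decreasing = TRUE)
  tp <- vapply(cand, function(th) sum(scores >= th & labels == 1L), 0) / n_pos
  fp <- if (n_neg == 0L) rep(0, length(cand)) else
    vapply(cand, function(th) sum(scores >= th & labels == 0L), 0) / n_neg
  ok <- tp > tp_target
  pick <- function(idx) {
    # minimal FP, then maximal threshold (cand is sorted decreasing)
    idx[order(fp[idx], -cand[idx])][1]
  }
  if (any(ok)) {
    i <- pick(which(ok))
    met <- TRUE
  } else {
    best_tp <- max(tp)
    i <- pick(which(tp == best_tp))
    met <- FALSE
    warnf("TP rate > %g not attainable on the adaptation data (best %.3f)",
          tp_target, best_tp)
  }
  structure(list(threshold = cand[i], achieved_tp = tp[i],
                 achieved_fp = fp[i], constraint_met = met),
            class = "threshold_adaptation")
}

#' Score instances into prediction records
#'
#' @param model a `telestress_model`.
#' @param instances instances sharing the training feature schema.
#' @return Data frame with `participant_id`, `label_week`, `score`,
#'   `predicted` (1 when `score >= threshold`), `actual`.
#' @export
predict_instances <- function(model, instances) {
  if (nrow(instances) == 0L) {
    return(data.frame(participant_id = character(0), label_week = integer(0),
                      score = numeric(0), predicted = integer(0),
                      actual = integer(0)))
  }
  score <- model_scores(model, instances)
  data.frame(participant_id = instances$participant_id,
             label_week = instances$label_week,
             score = score,
             predicted = as.integer(score >= model$threshold),
             actual = instances$label,
             stringsAsFactors = FALSE)
}

#' Fit personalized next-week stress prediction models
#'
#' The main fitting function. For `method = "single"` one pooled classifier
#' is trained on every participant's training-period instances and applied
#' to all test-period instances at the fixed 0.5 threshold. For the
#' personalized methods, participants are taken in ascending
#' teleworking-rate order and one classifier is trained per prediction
#' target on the instances of the target's neighborhood cluster (the
#' `cluster_size` participants with nearest teleworking rates):
#' `"proposed1"` uses the cluster's full 11 lagged weeks plus the target's
#' training weeks at the fixed threshold; `"proposed2"` trains on
#' training-period weeks only and adapts the threshold on the cluster's
#' held-out test-period weeks so the true-positive rate exceeds
#' `config$tp_target` with the lowest false-positive rate.
#'
#' Targets with no test-period instances, a single-class training set, or
#' (for proposed2) no positive adaptation labels are skipped with their
#' reason recorded; their instances still serve in other targets' training
#' pools.
#'
#' @param data a `telestress_cohort` from [simulate_cohort()], a cohort
#'   list from [read_cohort()], or a list with precomputed `instances`
#'   (from [build_instances()]) and `profiles` (from
#'   [telework_profiles()]).
#' @param method `"single"`, `"proposed1"` or `"proposed2"`.
#' @param config an [experiment_config()].
#' @param registry feature registry used when `data` is a raw cohort.
#' @param rate_weeks optional week restriction for teleworking-rate
#'   computation (e.g. `1:7` to avoid using test-period attendance).
#' @return A `telestress` object: per-target models and thresholds, pooled
#'   test-set `predictions`, the pooled `evaluation`, and bookkeeping for
#'   interpretation (`instances`, `profiles`, `skipped`).
#' @seealso [pool_and_evaluate()], [stratify_contributions()],
#'   [predict.telestress()]
#' @export
#' @examples
#' \donttest{
#' cohort <- simulate_cohort(cohort_spec(n_participants = 25, seed = 7))
#' fit <- telestress(cohort, method = "proposed2",
#'                   config = experiment_config(seed = 7))
#' fit
#' summary(fit)
#' }
telestress <- function(data, method = c("single", "proposed1", "proposed2"),
                       config = experiment_config(),
                       registry = default_feature_registry(),
                       rate_weeks = NULL) {
  method <- match.arg(method)
  prep <- prepare_experiment_data(data, registry, rate_weeks)
  instances <- prep$instances
  profiles <- prep$profiles
  feature_names <- attr(instances, "feature_names")
  profiles <- profiles[order(profiles$rate, profiles$participant_id), ,
                       drop = FALSE]
  targets <- profiles$participant_id

  skipped <- character(0)
  note_skip <- function(id, why) {
    skipped[[id]] <<- why
    message(sprintf("skipping target %s: %s", id, why))
  }

  models <- list()
  preds <- list()

  if (method == "single") {
    train <- instances[instances$label_week %in% config$train_weeks, ,
                       drop = FALSE]
    test <- instances[instances$label_week %in% config$test_weeks, ,
                      drop = FALSE]
    model <- train_model(train, feature_names, config)
    models[["(single)"]] <- list(model = model, member_ids = targets,
                                 adaptation = NULL,
                                 train_keys = instance_key(train))
    preds[["(single)"]] <- predict_instances(model, test)
  } else {
    for (id in targets) {
      test <- take(instances, id, config$test_weeks)
      if (nrow(test) == 0L) { note_skip(id, "no test-period instances"); next }
      nb <- extract_neighborhood(id, profiles, n = config$cluster_size,
                                 seed = config$seed + id_hash(id))
      sp <- make_splits(method, id, instances, nb$member_ids, config)
      model <- tryCatch(
        train_model(sp$train, feature_names, config,
                    seed = config$seed + id_hash(id)),
        error = function(e) conditionMessage(e)
      )
      if (is.character(model)) { note_skip(id, model); next }
      adaptation <- NULL
      if (method == "proposed2") {
        ad_scores <- model_scores(model, sp$adaptation)
        adaptation <- tryCatch(
          adapt_threshold(ad_scores, sp$adaptation$label, config$tp_target),
          error = function(e) conditionMessage(e)
        )
        if (is.character(adaptation)) { note_skip(id, adaptation); next }
        model$threshold <- adaptation$threshold
      }
      models[[id]] <- list(model = model, member_ids = nb$member_ids,
                           adaptation = adaptation,
                           train_keys = instance_key(sp$train),
                           adaptation_keys = if (is.null(sp$adaptation)) NULL
                                             else instance_key(sp$adaptation))
      preds[[id]] <- predict_instances(model, test)
    }
  }

  predictions <- do.call(rbind, unname(preds))
  if (is.null(predictions)) {
    stopf("no target produced test predictions; nothing to evaluate")
  }
  rownames(predictions) <- NULL
  evaluation <- pool_and_evaluate(predictions, method = method)

  structure(list(method = method, config = config, registry = registry,
                 feature_names = feature_names, models = models,
                 predictions = predictions, evaluation = evaluation,
                 instances = instances, profiles = profiles,
                 skipped = skipped, call = match.call()),
            class = "telestress")
}

# Normalize the accepted input forms of telestress() to instances+profiles.
prepare_experiment_data <- function(data, registry, rate_weeks = NULL) {
  if (is.list(data) && !is.null(data$instances) && !is.null(data$profiles)) {
    return(list(instances = data$instances, profiles = data$profiles))
  }
  if (inherits(data, "telestress_cohort") ||
      (is.list(data) && all(c("wearable", "shifts", "questionnaires") %in%
                              names(data)))) {
    participants <- data$participants %||%
      assemble_participants(data$wearable, data$shifts, data$questionnaires)
    n_weeks <- if (inherits(data, "telestress_cohort")) data$spec$n_weeks
               else NULL
    start_date <- if (inherits(data, "telestress_cohort")) {
      data$spec$start_date
    } else {
      week_origin(c(data$wearable$date, data$shifts$date))
    }
    if (is.null(n_weeks)) {
      all_dates <- c(data$wearable$date, data$shifts$date)
      n_weeks <- max(week_of(all_dates, start_date))
    }
    weekly <- build_cohort_features(participants, registry, n_weeks,
                                    start_date)
    instances <- build_instances(weekly, registry)
    profiles <- telework_profiles(data$shifts, weeks = rate_weeks,
                                  start_date = start_date)
    return(list(instances = instances, profiles = profiles))
  }
  stopf("data must be a cohort or a list with $instances and $profiles")
}
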