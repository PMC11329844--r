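signal_model <- function(n = 500, seed = 1) {
  reg <- default_feature_registry()
  set.seed(seed)
  m <- matrix(rnorm(n * nrow(reg)), n, nrow(reg),
              dimnames = list(NULL, reg$name))
  df <- cbind(data.frame(participant_id = "P1", label_week = 2),
              as.data.frame(m))
  df$label <- as.integer(df$hr_sd_mean + 0.2 * rnorm(n) > 0)
  list(model = train_model(df, reg$name, experiment_config(seed = seed)),
       data = df)
}

test_that("the informative feature ranks first by gain", {
  sm <- signal_model()
  ri <- rank_importance(sm$model)
  expect_equal(ri$top[1], "hr_sd_mean")
  expect_true(all(diff(ri$ranking$gain) <= 0))
  expect_length(ri$top, 10L)
  # unused features are padded in at zero gain, in stable name order
  zero <- ri$ranking[ri$ranking$gain == 0, "feature"]
  expect_equal(zero, sort(zero))
})

test_that("SHAP values are additive to the model margin", {
  sm <- signal_model(n = 200, seed = 3)
  sh <- compute_shap(sm$model, sm$data[1:50, ])
  expect_lt(max(abs(sh$base + rowSums(sh$phi) - sh$margin)), 1e-4)
  expect_equal(dim(sh$phi), c(50L, 50L))
})

test_that("stump SHAP equals the closed-form two-group decomposition", {
  # depth-1, single-tree model: phi_j(x) = leaf(x) - cover-weighted mean leaf
  reg <- default_feature_registry()
  set.seed(4)
  n <- 400
  m <- matrix(rnorm(n * nrow(reg)), n, nrow(reg),
              dimnames = list(NULL, reg$name))
  df <- cbind(data.frame(participant_id = "P1", label_week = 2),
              as.data.frame(m))
  df$label <- as.integer(df$steps_sum > 0)
  cfg <- experiment_config(max_depth = 1L, nrounds = 1L)
  model <- train_model(df, reg$name, cfg)
  tree <- xgboost::xgb.model.dt.tree(model = model$booster)
  leaves <- tree[tree$Feature == "Leaf", ]
  split_feat <- tree$Feature[1]
  expect_equal(split_feat, "steps_sum")
  base_exp <- sum(leaves$Gain * leaves$Cover) / sum(leaves$Cover)
  sh <- compute_shap(model, df[1:20, ])
  leaf_of <- ifelse(df$steps_sum[1:20] < tree$Split[1],
                    leaves$Gain[1], leaves$Gain[2])
  expect_equal(unname(sh$phi[, split_feat]), leaf_of - base_exp,
               tolerance = 1e-6)
  other <- setdiff(colnames(sh$phi), split_feat)
  expect_equal(max(abs(sh$phi[, other])), 0)
})

test_that("a constant model yields all-zero SHAP", {
  reg <- default_feature_registry()
  set.seed(5)
  df <- cbind(data.frame(participant_id = "P1", label_week = 2),
              as.data.frame(matrix(0, 50, nrow(reg),
                                   dimnames = list(NULL, reg$name))))
  df$label <- rep(c(0L, 1L), 25)  # constant features: nothing to split on
  model <- train_model(df, reg$name, experiment_config())
  sh <- compute_shap(model, df[1:5, ])
  expect_equal(max(abs(sh$phi)), 0)
})

test_that("direction statistic matches the two-pass formula and its invariances", {
  # phi == x: cov(x, x)/sd(x) = sd(x)
  expect_equal(direction_statistic(1:3, 1:3)$value, 1)
  expect_false(direction_statistic(rep(2, 5), rnorm(5))$defined)
  expect_error(direction_statistic(1, 1), "at least 2")
  set.seed(6)
  for (i in 1:20) {
    x <- rnorm(10); phi <- rnorm(10)
    two_pass <- cov(x, phi) / sd(x)
    got <- direction_statistic(x, phi)
    expect_true(got$defined)
    expect_equal(got$value, two_pass, tolerance = 1e-10)
    # shift invariance in x; linear scaling in phi
    expect_equal(direction_statistic(x + 100, phi)$value, got$value,
                 tolerance = 1e-10)
    expect_equal(direction_statistic(x, 3 * phi)$value, 3 * got$value,
                 tolerance = 1e-10)
  }
})

test_that("stratification partitions models and conserves top-10 counts", {
  co <- small_cohort()
  f1 <- suppressMessages(telestress(co, "proposed1",
                                    experiment_config(seed = 11)))
  sc <- stratify_contributions(f1)
  # partition: every fitted model in exactly one level
  expect_setequal(unlist(sc$levels), names(f1$models))
  # conservation: each level's category counts sum to 10 x models there
  for (lv in names(sc$levels)) {
    expect_equal(sum(sc$category_counts[lv, ]),
                 10L * length(sc$levels[[lv]]))
  }
  # mean ranks are averages of within-model ranks, sorted ascending
  for (lv in names(sc$mean_ranks)) {
    expect_true(all(diff(sc$mean_ranks[[lv]]$mean_rank) >= 0))
  }
  expect_error(stratify_contributions(
    suppressMessages(telestress(co, "single", experiment_config(seed = 11)))),
    "per-target")
})

test_that("an all-office cohort lands every model in the low stratum", {
  co <- simulate_cohort(cohort_spec(n_participants = 22, seed = 17,
                                    telework_distribution = 0))
  f1 <- suppressMessages(telestress(co, "proposed1",
                                    experiment_config(seed = 17)))
  sc <- stratify_contributions(f1)
  expect_equal(names(sc$levels), "low")
  expect_equal(sum(sc$category_counts["middle", ]), 0L)
  expect_equal(sum(sc$category_counts["high", ]), 0L)
})
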