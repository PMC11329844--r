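#' Rank features by gain importance
#'
#' Gain importance is the total reduction of the training objective
#' achieved by splits on each feature, summed over all trees. Features the
#' ensemble never split on receive zero importance; the ranking is made
#' total and deterministic by breaking ties (including the zero-importance
#' tail) in feature-name order. The top 10 are padded with zero-importance
#' names when fewer than 10 features were used.
#'
#' @param model a `telestress_model` from [train_model()].
#' @param n_top how many leading features to report (default 10).
#' @return A list with `ranking` (data frame `feature`, `gain`, `rank`) and
#'   `top` (the first `n_top` feature names).
#' @export
rank_importance <- function(model, n_top = 10L) {
  if (!inherits(model, "telestress_model")) {
    stopf("rank_importance expects a fitted telestress_model")
  }
  imp <- xgboost::xgb.importance(model = model$booster)
  gain <- stats::setNames(rep(0, length(model$feature_names)),
                          model$feature_names)
  if (!is.null(imp) && nrow(imp)) gain[imp$Feature] <- imp$Gain
  ord <- order(-gain, names(gain))
  ranking <- data.frame(feature = names(gain)[ord], gain = unname(gain[ord]),
                        rank = seq_along(gain), stringsAsFactors = FALSE)
  list(ranking = ranking, top = ranking$feature[seq_len(min(n_top,
                                                            nrow(ranking)))])
}

#' Compute exact TreeSHAP values
#'
#' Per-instance, per-feature signed contributions on the margin (log-odds)
#' scale, computed by the exact TreeSHAP path algorithm. For every row,
#' `base + sum(phi)` reproduces the model's margin output.
#'
#' @param model a `telestress_model`.
#' @param instances instances sharing the training schema.
#' @return A list with `phi` (matrix rows x features), `base` (per-row base
#'   value) and `margin` (the model's margin predictions).
#' @export
compute_shap <- function(model, instances) {
  if (nrow(instances) == 0L) stopf("no instances to explain")
  m <- instance_matrix(instances, model$feature_names)
  contrib <- predict(model$booster, m, predcontrib = TRUE)
  k <- ncol(contrib)
  list(phi = contrib[, -k, drop = FALSE], base = contrib[, k],
       margin = predict(model$booster, m, outputmargin = TRUE))
}

#' Contribution-direction statistic
#'
#' The covariance between a feature and its SHAP values divided by the
#' feature's standard deviation (both in unbiased n - 1 form). Its sign
#' gives the direction in which the feature pushes the predicted stress
#' probability; its magnitude is in SHAP (log-odds) units. Undefined
#' (reported as 0 with `defined = FALSE`) when the feature is constant
#' over the evaluated instances.
#'
#' @param x feature values over the evaluated instances (length >= 2).
#' @param phi matching SHAP values.
#' @return A list: `value`, `defined`.
#' @export
direction_statistic <- function(x, phi) {
  if (length(x) != length(phi)) stopf("x and phi lengths differ")
  if (length(x) < 2L) stopf("direction statistic needs at least 2 instances")
  keep <- !is.na(x) & !is.na(phi)
  if (sum(keep) < 2L) return(list(value = 0, defined = FALSE))
  x <- x[keep]; phi <- phi[keep]
  sdx <- stats::sd(x)
  if (sdx == 0) return(list(value = 0, defined = FALSE))
  list(value = stats::cov(x, phi) / sdx, defined = TRUE)
}

#' Stratified feature-contribution analysis
#'
#' For every per-target model of a personalized fit: ranks features by gain
#' importance, computes SHAP values on the target's evaluated (test-period)
#' instances, and derives per-feature direction statistics. Models are then
#' stratified by their target's teleworking level (low / middle / high);
#' per level the analysis tallies top-10 feature occurrences by registry
#' category and orders features by mean within-model importance rank.
#'
#' @param fit a `telestress` fit with per-target models (`proposed1` or
#'   `proposed2`).
#' @param n_top how many leading features per model (default 10).
#' @return A `telestress_contrib` list: `levels` (targets per level),
#'   `category_counts` (level x category top-10 tallies), `mean_ranks`
#'   (per-level data frames ordered by mean importance rank), `directions`
#'   (long data frame: level, target, feature, direction value, defined,
#'   whether the feature was in that model's top 10).
#' @export
stratify_contributions <- function(fit, n_top = 10L) {
  if (!inherits(fit, "telestress")) stopf("expected a telestress fit")
  if (fit$method == "single") {
    stopf("stratified contribution analysis needs per-target models")
  }
  target_ids <- names(fit$models)
  lev <- assign_telework_level(
    fit$profiles$rate[match(target_ids, fit$profiles$participant_id)])
  names(lev) <- target_ids

  cats <- stats::setNames(fit$registry$category, fit$registry$name)
  cat_levels <- c("sleep", "activity", "work", "questionnaire")
  counts <- matrix(0L, 3, length(cat_levels),
                   dimnames = list(c("low", "middle", "high"), cat_levels))
  rank_rows <- list(); dir_rows <- list()

  for (id in target_ids) {
    entry <- fit$models[[id]]
    ri <- rank_importance(entry$model, n_top)
    test <- take(fit$instances, id, fit$config$test_weeks)
    sh <- compute_shap(entry$model, test)
    for (f in ri$top) {
      counts[lev[[id]], cats[[f]]] <- counts[lev[[id]], cats[[f]]] + 1L
    }
    rank_rows[[id]] <- data.frame(level = lev[[id]], target_id = id,
                                  feature = ri$ranking$feature,
                                  rank = ri$ranking$rank,
                                  stringsAsFactors = FALSE)
    ds <- lapply(fit$feature_names, function(f)
      direction_statistic(test[[f]], sh$phi[, f]))
    dir_rows[[id]] <- data.frame(
      level = lev[[id]], target_id = id, feature = fit$feature_names,
      direction = vapply(ds, `[[`, numeric(1), "value"),
      defined = vapply(ds, `[[`, logical(1), "defined"),
      in_top = fit$feature_names %in% ri$top,
      stringsAsFactors = FALSE)
  }

  ranks <- do.call(rbind, unname(rank_rows))
  mean_ranks <- lapply(split(ranks, ranks$level), function(df) {
    agg <- stats::aggregate(rank ~ feature, df, mean)
    names(agg)[2] <- "mean_rank"
    agg <- agg[order(agg$mean_rank, agg$feature), , drop = FALSE]
    rownames(agg) <- NULL
    agg
  })

  structure(list(
    levels = split(target_ids, lev[target_ids]),
    category_counts = counts,
    mean_ranks = mean_ranks,
    directions = do.call(rbind, unname(dir_rows)),
    n_top = as.integer(n_top)
  ), class = "telestress_contrib")
}

#' @export
print.telestress_contrib <- function(x, ...) {
  cat("Stratified feature contributions\n")
  cat(sprintf("  models per level: %s\n",
              paste(sprintf("%s=%d", names(x$levels),
                            lengths(x$levels)), collapse = ", ")))
  cat(sprintf("  top-%d category tallies:\n", x$n_top))
  print(x$category_counts)
  invisible(x)
}
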