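#' @export
print.telestress <- function(x, ...) {
  cat(sprintf("Personalized stress prediction fit (method: %s)\n", x$method))
  n_models <- length(x$models)
  cat(sprintf("  %d model(s), %d pooled test predictions, %d target(s) skipped\n",
              n_models, nrow(x$predictions), length(x$skipped)))
  print(x$evaluation)
  invisible(x)
}

#' Summarize a personalized stress prediction fit
#'
#' @param object a `telestress` fit.
#' @param ... unused.
#' @return A `summary.telestress` list with the pooled evaluation,
#'   per-level target counts, adapted-threshold summaries (proposed2), and
#'   skip reasons.
#' @export
summary.telestress <- function(object, ...) {
  ids <- setdiff(names(object$models), "(single)")
  lev_tab <- if (length(ids)) {
    table(assign_telework_level(
      object$profiles$rate[match(ids, object$profiles$participant_id)]))
  } else NULL
  thresholds <- vapply(object$models, function(m) m$model$threshold,
                       numeric(1))
  adapt <- Filter(Negate(is.null),
                  lapply(object$models, `[[`, "adaptation"))
  structure(list(
    method = object$method,
    evaluation = object$evaluation,
    n_models = length(object$models),
    level_counts = lev_tab,
    thresholds = thresholds,
    n_constraint_met = sum(vapply(adapt, `[[`, logical(1), "constraint_met")),
    n_adapted = length(adapt),
    skipped = object$skipped
  ), class = "summary.telestress")
}

#' @export
print.summary.telestress <- function(x, ...) {
  cat(sprintf("Method: %s (%d model(s))\n", x$method, x$n_models))
  print(x$evaluation)
  if (!is.null(x$level_counts)) {
    cat("  targets by teleworking level: ",
        paste(sprintf("%s=%d", names(x$level_counts), x$level_counts),
              collapse = ", "), "\n", sep = "")
  }
  if (x$n_adapted > 0) {
    cat(sprintf("  adapted thresholds: median %.3f (TP floor met for %d/%d targets)\n",
                stats::median(x$thresholds), x$n_constraint_met, x$n_adapted))
  }
  if (length(x$skipped)) {
    cat(sprintf("  skipped: %s\n",
                paste(sprintf("%s (%s)", names(x$skipped), x$skipped),
                      collapse = "; ")))
  }
  invisible(x)
}

#' Predict stress for new participant-weeks
#'
#' Scores new supervised instances with the fitted model(s): the pooled
#' model for `single` fits, or each row's own target model for the
#' personalized methods (rows whose `participant_id` has no fitted model
#' are rejected).
#'
#' @param object a `telestress` fit.
#' @param newdata an instance data frame with the fit's feature columns
#'   (and `participant_id`/`label_week`); defaults to the fit's test-period
#'   instances.
#' @param ... unused.
#' @return A prediction-record data frame (`score`, `predicted`, `actual`).
#' @export
predict.telestress <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) {
    return(object$predictions)
  }
  if (object$method == "single") {
    return(predict_instances(object$models[["(single)"]]$model, newdata))
  }
  ids <- unique(newdata$participant_id)
  missing_ids <- setdiff(ids, names(object$models))
  if (length(missing_ids)) {
    stopf("no fitted model for participant(s): %s",
          paste(missing_ids, collapse = ", "))
  }
  out <- lapply(ids, function(id) {
    predict_instances(object$models[[id]]$model,
                      newdata[newdata$participant_id == id, , drop = FALSE])
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Plot the pooled ROC curve of a fit
#'
#' Draws the empirical ROC curve of the pooled test-set scores and marks
#' the operating point of the thresholded predictions.
#'
#' @param x a `telestress` fit.
#' @param ... passed to [plot.default()].
#' @return Invisibly, a data frame of ROC points (`fpr`, `tpr`).
#' @export
plot.telestress <- function(x, ...) {
  p <- x$predictions
  th <- sort(unique(c(p$score, max(p$score) + 1)), decreasing = TRUE)
  n_pos <- sum(p$actual == 1L); n_neg <- sum(p$actual == 0L)
  roc <- data.frame(
    fpr = vapply(th, function(t) sum(p$score >= t & p$actual == 0L), 0) /
      max(n_neg, 1L),
    tpr = vapply(th, function(t) sum(p$score >= t & p$actual == 1L), 0) /
      max(n_pos, 1L)
  )
  plot(roc$fpr, roc$tpr, type = "s", xlim = c(0, 1), ylim = c(0, 1),
       xlab = "False positive rate", ylab = "True positive rate",
       main = sprintf("Pooled ROC (%s), AUROC = %.3f", x$method,
                      x$evaluation$auroc), ...)
  graphics::abline(0, 1, lty = 3, col = "grey50")
  graphics::points(x$evaluation$fp_rate, x$evaluation$tp_rate, pch = 19,
                   col = "red3")
  invisible(roc)
}
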