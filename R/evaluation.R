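#' Area under the ROC curve (rank formulation)
#'
#' Computed via the Mann-Whitney statistic on midranks: the proportion of
#' (positive, negative) pairs in which the positive scores higher, with
#' ties counted one half. Invariant to strictly monotone transforms of the
#' scores.
#'
#' @param scores numeric scores (higher = more positive).
#' @param labels 0/1 labels.
#' @return AUROC in [0, 1], or `NA` when only one class is present.
#' @export
auroc <- function(scores, labels) {
  labels <- as.integer(labels)
  n_pos <- sum(labels == 1L); n_neg <- sum(labels == 0L)
  if (n_pos == 0L || n_neg == 0L) return(NA_real_)
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Pool prediction records and evaluate
#'
#' Micro (pooled) evaluation over all targets and weeks: confusion counts
#' from the thresholded predictions, TP rate = TP / (TP + FN), FP rate =
#' FP / (FP + TN), and AUROC from the raw scores. With one-class actuals
#' the AUROC is undefined (`NA`) but the rates are still computed.
#'
#' @param records a prediction data frame with columns `score`, `predicted`,
#'   `actual` (e.g. `fit$predictions`).
#' @param method optional method tag carried into the report.
#' @return A `telestress_eval` list: `tp_rate`, `fp_rate`, `auroc`,
#'   `confusion` (named TP/FP/TN/FN counts), `n_records`, `method`.
#' @export
pool_and_evaluate <- function(records, method = NA_character_) {
  if (nrow(records) == 0L) stopf("no prediction records to evaluate")
  a <- as.integer(records$actual); p <- as.integer(records$predicted)
  conf <- c(TP = sum(p == 1L & a == 1L), FP = sum(p == 1L & a == 0L),
            TN = sum(p == 0L & a == 0L), FN = sum(p == 0L & a == 1L))
  tp_rate <- if (conf[["TP"]] + conf[["FN"]] == 0L) NA_real_ else
    conf[["TP"]] / (conf[["TP"]] + conf[["FN"]])
  fp_rate <- if (conf[["FP"]] + conf[["TN"]] == 0L) NA_real_ else
    conf[["FP"]] / (conf[["FP"]] + conf[["TN"]])
  structure(list(tp_rate = tp_rate, fp_rate = fp_rate,
                 auroc = auroc(records$score, a), confusion = conf,
                 n_records = nrow(records), method = method),
            class = "telestress_eval")
}

#' @export
print.telestress_eval <- function(x, ...) {
  cat(sprintf("Pooled evaluation%s (n = %d)\n",
              if (is.na(x$method)) "" else paste0(" [", x$method, "]"),
              x$n_records))
  cat(sprintf("  TP rate: %.3f  FP rate: %.3f  AUROC: %.3f\n",
              x$tp_rate, x$fp_rate, x$auroc))
  cat(sprintf("  confusion: TP=%d FP=%d TN=%d FN=%d\n",
              x$confusion[["TP"]], x$confusion[["FP"]],
              x$confusion[["TN"]], x$confusion[["FN"]]))
  invisible(x)
}

#' Compare evaluation reports side by side
#'
#' @param reports a list of `telestress_eval` objects (at least 2).
#' @return A data frame with one row per method and columns `method`,
#'   `tp_rate`, `fp_rate`, `auroc`, `n_records`.
#' @export
compare_methods <- function(reports) {
  if (length(reports) < 2L) stopf("compare_methods needs at least 2 reports")
  do.call(rbind, lapply(reports, function(r) {
    data.frame(method = r$method, tp_rate = r$tp_rate, fp_rate = r$fp_rate,
               auroc = r$auroc, n_records = r$n_records,
               stringsAsFactors = FALSE)
  }))
}
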