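#' Confusion counts over sample verdicts
#'
#' Tallies predicted against original labels for a binary cohort. True
#' positives are samples whose predicted and original labels both equal the
#' positive class; swapping `positive_class` swaps (TP, TN) and (FP, FN).
#'
#' @param predictions A binary `CohortResult`, a list of
#'   `SamplePrediction`, or a data.frame with columns `original_label` and
#'   `predicted_label`.
#' @param positive_class Integer label treated as positive (default: the
#'   larger of the two labels, i.e. tumor = 1 in the 0/1 coding).
#' @return A `ConfusionCounts` list with `TP`, `FP`, `FN`, `TN` and
#'   `positive_class`.
#' @export
confusion_counts <- function(predictions, positive_class = NULL) {
  df <- as_verdict_frame(predictions)
  classes <- sort(unique(c(df$original_label, df$predicted_label)))
  if (length(classes) > 2L)
    stop("confusion_counts is binary-only (labels ",
         paste(classes, collapse = ", "),
         "); use multiclass_metrics() for one-vs-rest metrics")
  if (is.null(positive_class)) positive_class <- max(classes)
  pos <- df$original_label == positive_class
  hit <- df$predicted_label == positive_class
  structure(list(TP = sum(pos & hit), FP = sum(!pos & hit),
                 FN = sum(pos & !hit), TN = sum(!pos & !hit),
                 positive_class = as.integer(positive_class)),
            class = "ConfusionCounts")
}

as_verdict_frame <- function(predictions) {
  if (inherits(predictions, "CohortResult"))
    predictions <- predictions$predictions
  if (is.data.frame(predictions)) {
    stopifnot(all(c("original_label", "predicted_label") %in% names(predictions)))
    return(predictions)
  }
  do.call(rbind, lapply(predictions, function(p)
    data.frame(original_label = p$original_label,
               predicted_label = p$predicted_label)))
}

#' Precision, recall and F1 from confusion counts
#'
#' `precision = TP / (TP + FP)`, `recall = TP / (TP + FN)`, and F1 is their
#' harmonic mean `2 * P * R / (P + R)`. A zero denominator yields 0 with a
#' warning rather than NaN.
#'
#' @param counts A `ConfusionCounts`.
#' @return Named list `precision`, `recall`, `f1`.
#' @export
precision_recall_f1 <- function(counts) {
  stopifnot(inherits(counts, "ConfusionCounts"))
  safe_div <- function(num, den, what) {
    if (den == 0) {
      warning(what, " undefined (zero denominator); reporting 0")
      return(0)
    }
    num / den
  }
  precision <- safe_div(counts$TP, counts$TP + counts$FP, "precision")
  recall <- safe_div(counts$TP, counts$TP + counts$FN, "recall")
  f1 <- if (precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  list(precision = precision, recall = recall, f1 = f1)
}

#' F1 score from a precision/recall pair
#'
#' @param precision,recall Values in `[0, 1]`.
#' @return The harmonic mean `2 * P * R / (P + R)` (0 when both are 0).
#' @export
f1_score <- function(precision, recall) {
  if (precision + recall == 0) return(0)
  2 * precision * recall / (precision + recall)
}

#' Cohort accuracy
#'
#' The fraction of samples whose majority-vote verdict is correct:
#' `n_predicted / n_total`.
#'
#' @param result A `CohortResult`.
#' @return Accuracy in `[0, 1]`.
#' @export
cohort_accuracy <- function(result) {
  stopifnot(inherits(result, "CohortResult"))
  if (result$n_total < 1L) stop("empty cohort")
  result$n_predicted / result$n_total
}

#' ROC curve and AUC by threshold sweep
#'
#' Sweeps every distinct score as a decision threshold (ties grouped into a
#' single step), accumulating true/false positive rates from (0, 0) to
#' (1, 1), and integrates the curve with the trapezoid rule. This equals
#' the rank-statistic (concordant-pair) formulation of the AUC with ties
#' counted one half.
#'
#' @param labels True binary labels, one per scored item.
#' @param scores Positive-class scores/probabilities (finite).
#' @param positive_class Label counted as positive (default: larger label).
#' @return List with `roc_points` (data.frame `threshold`, `fpr`, `tpr`,
#'   starting at the (Inf, 0, 0) anchor) and `auc`.
#' @export
roc_auc <- function(labels, scores, positive_class = NULL) {
  stopifnot(length(labels) == length(scores), all(is.finite(scores)))
  classes <- sort(unique(labels))
  if (length(classes) < 2L)
    stop("ROC needs both classes present; got only class ", classes)
  if (length(classes) > 2L) stop("ROC is binary-only")
  if (is.null(positive_class)) positive_class <- max(classes)
  y <- labels == positive_class
  nP <- sum(y); nN <- sum(!y)
  ord <- order(scores, decreasing = TRUE)
  y <- y[ord]; s <- scores[ord]
  # group tied scores into one threshold step
  last_of_group <- c(diff(s) != 0, TRUE)
  cum_tp <- cumsum(y)[last_of_group]
  cum_fp <- cumsum(!y)[last_of_group]
  roc <- data.frame(threshold = c(Inf, s[last_of_group]),
                    fpr = c(0, cum_fp / nN), tpr = c(0, cum_tp / nP))
  auc <- sum(diff(roc$fpr) * (utils::head(roc$tpr, -1) + utils::tail(roc$tpr, -1)) / 2)
  list(roc_points = roc, auc = auc)
}

#' Full metrics report for a cohort result
#'
#' Sample-level precision/recall/F1 and accuracy are computed over the
#' majority-vote verdict labels (the granularity at which published
#' comparisons report them), while ROC/AUC is computed over the pooled
#' per-scan positive-class probabilities (spectrum granularity). Multiclass
#' cohorts get one-vs-rest precision/recall/F1 per class plus their macro
#' averages, and no pooled ROC.
#'
#' @param result A `CohortResult`.
#' @param positive_class Positive label for the binary metrics.
#' @return A `MetricsReport` list: `precision`, `recall`, `f1`, `accuracy`,
#'   `auc`, `roc_points`, and for multiclass a `per_class` data.frame.
#' @export
metrics_report <- function(result, positive_class = NULL) {
  stopifnot(inherits(result, "CohortResult"))
  acc <- cohort_accuracy(result)
  if (result$mode == "binary") {
    cc <- confusion_counts(result, positive_class)
    prf <- precision_recall_f1(cc)
    roc <- if (!is.null(result$pooled_scan_scores) &&
               length(unique(result$pooled_scan_scores$label)) == 2L)
      roc_auc(result$pooled_scan_scores$label, result$pooled_scan_scores$prob)
    else list(roc_points = NULL, auc = NA_real_)
    rpt <- list(precision = prf$precision, recall = prf$recall, f1 = prf$f1,
                accuracy = acc, auc = roc$auc, roc_points = roc$roc_points,
                counts = cc, per_class = NULL)
  } else {
    per <- multiclass_metrics(result)
    rpt <- list(precision = mean(per$precision), recall = mean(per$recall),
                f1 = mean(per$f1), accuracy = acc, auc = NA_real_,
                roc_points = NULL, counts = NULL, per_class = per)
  }
  structure(rpt, class = "MetricsReport")
}

#' One-vs-rest precision/recall/F1 per class
#'
#' @param result A `CohortResult` (any class count).
#' @return data.frame with one row per class: `class`, `precision`,
#'   `recall`, `f1`.
#' @export
multiclass_metrics <- function(result) {
  df <- as_verdict_frame(result)
  classes <- sort(unique(df$original_label))
  rows <- lapply(classes, function(cl) {
    bin <- data.frame(original_label = as.integer(df$original_label == cl),
                      predicted_label = as.integer(df$predicted_label == cl))
    prf <- suppressWarnings(precision_recall_f1(confusion_counts(bin, 1L)))
    data.frame(class = cl, precision = prf$precision, recall = prf$recall,
               f1 = prf$f1)
  })
  do.call(rbind, rows)
}

#' @export
print.MetricsReport <- function(x, ...) {
  cat(sprintf("MetricsReport: accuracy %.3f, precision %.3f, recall %.3f, F1 %.3f",
              x$accuracy, x$precision, x$recall, x$f1))
  if (!is.na(x$auc)) cat(sprintf(", scan-level AUC %.3f", x$auc))
  cat("\n")
  invisible(x)
}
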