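# Confusion-matrix metrics: accuracy, sensitivity, specificity and the
# Matthews correlation coefficient, with the rounding conventions used in
# the tabular reports (percentages to 2 decimals, MCC to 4, per-test mean
# accuracies to 1). Raw full-precision values are always retained.

#' Confusion counts of a binary prediction
#'
#' Positive class is 1 (PD): `TP` counts (truth 1, prediction 1), `TN`
#' (0, 0), `FP` (0, 1) and `FN` (1, 0).
#'
#' @param truth,pred binary 0/1 vectors of equal length.
#' @return object of class `confusion_counts` with fields `TP`, `TN`, `FP`,
#'   `FN`.
#' @export
confusion <- function(truth, pred) {
  if (length(truth) != length(pred)) {
    stop("value error: truth and pred lengths differ")
  }
  truth <- as.integer(truth)
  pred <- as.integer(pred)
  if (!all(truth %in% c(0L, 1L)) || !all(pred %in% c(0L, 1L))) {
    stop("value error: labels must be 0/1")
  }
  confusion_counts(TP = sum(truth == 1L & pred == 1L),
                   TN = sum(truth == 0L & pred == 0L),
                   FP = sum(truth == 0L & pred == 1L),
                   FN = sum(truth == 1L & pred == 0L))
}

#' Construct confusion counts directly
#'
#' @param TP,TN,FP,FN non-negative integer counts.
#' @return object of class `confusion_counts`.
#' @export
confusion_counts <- function(TP, TN, FP, FN) {
  counts <- c(TP = TP, TN = TN, FP = FP, FN = FN)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("value error: counts must be non-negative integers")
  }
  structure(lapply(as.list(counts), as.integer),
            class = "confusion_counts")
}

#' Metrics of a confusion matrix
#'
#' * accuracy = (TP + TN) / (TP + TN + FP + FN), as a percentage;
#' * sensitivity = TP / (TP + FN), specificity = TN / (TN + FP), as
#'   percentages;
#' * MCC = (TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN)), in
#'   `[-1, 1]`.
#'
#' A zero factor in the MCC denominator makes the coefficient undefined; the
#' no-information convention MCC = 0 is returned with a warning. An empty
#' sensitivity/specificity denominator likewise yields `NA` for that metric.
#'
#' @param counts a [confusion_counts()] with a positive total.
#' @return object of class `metrics_report`: `counts`, `accuracy`,
#'   `sensitivity`, `specificity` (percentages, full precision) and `mcc`.
#' @export
compute_metrics <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  TP <- counts$TP; TN <- counts$TN; FP <- counts$FP; FN <- counts$FN
  total <- TP + TN + FP + FN
  if (total == 0L) stop("value error: empty confusion matrix")
  acc <- 100 * (TP + TN) / total
  sens <- if (TP + FN > 0L) 100 * TP / (TP + FN) else NA_real_
  spec <- if (TN + FP > 0L) 100 * TN / (TN + FP) else NA_real_
  denom2 <- as.double(TP + FP) * (TP + FN) * (TN + FP) * (TN + FN)
  if (denom2 == 0) {
    warning("MCC denominator has a zero factor; returning 0 (no information)",
            call. = FALSE)
    mcc <- 0
  } else {
    mcc <- (as.double(TP) * TN - as.double(FP) * FN) / sqrt(denom2)
  }
  structure(list(counts = counts, accuracy = acc, sensitivity = sens,
                 specificity = spec, mcc = mcc),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  c_ <- x$counts
  cat(sprintf("TP=%d FN=%d TN=%d FP=%d\n", c_$TP, c_$FN, c_$TN, c_$FP))
  cat(sprintf("accuracy %.2f%%  sensitivity %.2f%%  specificity %.2f%%  MCC %.4f\n",
              x$accuracy, x$sensitivity, x$specificity, x$mcc))
  invisible(x)
}

#' One-row data frame view of a metrics report
#'
#' @param x a `metrics_report`.
#' @param ... unused.
#' @return data frame with counts and metrics at full precision.
#' @export
as.data.frame.metrics_report <- function(x, ...) {
  data.frame(TP = x$counts$TP, FN = x$counts$FN, TN = x$counts$TN,
             FP = x$counts$FP, accuracy = x$accuracy,
             sensitivity = x$sensitivity, specificity = x$specificity,
             mcc = x$mcc)
}

#' Per-vocal-test accuracy table with row summaries
#'
#' Given per-test LOO accuracies of one or more classifiers (percent scale),
#' appends each test's mean accuracy across classifiers (rounded to 1
#' decimal) and the n-1 sample standard deviation. With a single classifier
#' column the SD is undefined and reported as 0 with a `degenerate_sd` flag.
#'
#' @param acc numeric matrix or data frame, rows = vocal tests, columns =
#'   classifiers (percent accuracies).
#' @param test_ids integer test ids (default: row sequence).
#' @return data frame `test_id`, one column per classifier, `mean_accuracy`
#'   (1 decimal), `sd_accuracy`; attribute `degenerate_sd` marks the
#'   single-column case.
#' @export
per_test_accuracy_table <- function(acc, test_ids = seq_len(nrow(acc))) {
  acc <- as.matrix(acc)
  stopifnot(ncol(acc) >= 1L)
  degenerate <- ncol(acc) == 1L
  mean_acc <- rowMeans(acc)
  sd_acc <- if (degenerate) rep(0, nrow(acc)) else apply(acc, 1L, stats::sd)
  out <- data.frame(test_id = as.integer(test_ids),
                    as.data.frame(acc, row.names = NULL),
                    mean_accuracy = round(mean_acc, 1L),
                    sd_accuracy = sd_acc)
  attr(out, "degenerate_sd") <- degenerate
  out
}
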