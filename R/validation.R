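# The framework proper — per-vocal-test leave-one-out classifiers fused by
# majority vote — plus the two baselines it is compared against: pooled
# leave-one-subject-out (LOSO, evaluated per recording) and summarized
# leave-one-out (s-LOO, one summary vector per subject).

#' Leave-one-out predictions on one vocal-test subset
#'
#' For every subject, the classifier is trained on all other subjects of the
#' subset (restricted to `features`) and predicts the held-out subject. In
#' the default (faithful) mode the subset is used as given — normalize it
#' beforehand with [zscore_normalize()]. With `fold_safe = TRUE` z-scoring is
#' re-estimated inside each training fold and applied to the held-out row,
#' which removes the preprocessing leakage of the faithful protocol.
#'
#' @param subset a `vocal_test_subset` with >= 3 subjects and both classes.
#' @param features integer feature indices to use (>= 1 of them).
#' @param spec a [classifier_spec()].
#' @param fold_safe logical; re-fit scaling per fold.
#' @return integer vector of 0/1 predictions, one per subject, named by
#'   subject id.
#' @export
loo_predict_subset <- function(subset, features, spec, fold_safe = FALSE) {
  stopifnot(inherits(subset, "vocal_test_subset"), length(features) >= 1L)
  n <- nrow(subset$x)
  if (n < 3L) stop("value error: need >= 3 subjects for leave-one-out")
  x <- subset$x[, features, drop = FALSE]
  y <- subset$labels
  preds <- vapply(seq_len(n), function(i) {
    train_y <- y[-i]
    if (length(unique(train_y)) < 2L) {
      stop("value error: training fold contains a single class")
    }
    if (fold_safe) {
      sc <- fit_apply_zscore(x[-i, , drop = FALSE], x[i, , drop = FALSE])
      fit_predict(spec, sc$train, train_y, sc$test)
    } else {
      fit_predict(spec, x[-i, , drop = FALSE], train_y, x[i, , drop = FALSE])
    }
  }, integer(1))
  stats::setNames(preds, subset$subject_ids)
}

#' Majority vote over per-test predictions
#'
#' Each included vocal test casts one 0/1 vote per subject; `NA` entries
#' (tests omitted under A-MCFS) cast no vote. A subject is labelled 1 (PD)
#' iff at least half of its votes are 1 — i.e. strict majorities decide, and
#' an exact tie is resolved towards PD, the costlier class to miss in a
#' screening setting.
#'
#' @param pred_matrix integer matrix, rows = vocal tests, columns =
#'   subjects; entries 0/1 or `NA` for absent votes.
#' @return integer vector of fused 0/1 labels, one per column.
#' @export
majority_vote <- function(pred_matrix) {
  pred_matrix <- as.matrix(pred_matrix)
  n_votes <- colSums(!is.na(pred_matrix))
  if (any(n_votes == 0L)) {
    stop("value error: subject(s) with zero votes: ",
         paste(colnames(pred_matrix)[n_votes == 0L], collapse = ", "))
  }
  share <- colMeans(pred_matrix == 1L, na.rm = TRUE)
  stats::setNames(as.integer(share >= 0.5), colnames(pred_matrix))
}

#' Run the multiple-classifier framework on a recording table
#'
#' Executes the four stages: (1) separation into per-vocal-test subsets,
#' (2) per-subset z-scoring and correlation-filter feature selection with
#' the chosen policy for unsuccessful tests (MCFS fallback features or
#' A-MCFS omission), (3) a leave-one-out classifier per included subset, and
#' (4) majority-vote fusion of the per-test predictions.
#'
#' In the default faithful protocol, normalization and selection are
#' computed once on the full table before cross-validation. With
#' `fold_safe = TRUE`, scaling and selection (including the MCFS fallback
#' ranking) are re-estimated inside every leave-one-out fold; a test whose
#' fold-level selection fails under A-MCFS simply casts no vote for that
#' fold's subject. The returned `plan` is always the full-table plan, which
#' in fold-safe mode is a descriptive summary rather than the per-fold plans
#' actually used.
#'
#' @param table a `recording_table`.
#' @param mode `"A_MCFS"` (omit unsuccessful tests) or `"MCFS"` (fallback
#'   features).
#' @param spec a [classifier_spec()].
#' @param alpha selection significance level (default 0.05).
#' @param fallback_k number of MCFS fallback features (default 4).
#' @param fold_safe logical; leakage-free re-fitting per fold.
#' @return object of class `framework_result`: `metrics`
#'   (a `metrics_report` on the fused labels), `per_test_accuracy` (data
#'   frame `test_id`, `accuracy` — each included test's standalone LOO
#'   accuracy in percent, prior to voting), `plan`, `predictions` (the
#'   test x subject vote matrix, `NA` = no vote), `final` (fused labels),
#'   `truth`, `subject_ids`.
#' @export
run_framework <- function(table, mode = c("A_MCFS", "MCFS"), spec,
                          alpha = 0.05, fallback_k = 4L,
                          fold_safe = FALSE) {
  mode <- match.arg(mode)
  stopifnot(inherits(spec, "classifier_spec"))
  subsets <- separate_by_test(table)
  n_tests <- length(subsets)
  subj <- subsets[[1L]]$subject_ids
  truth <- subsets[[1L]]$labels
  norm <- lapply(subsets, zscore_normalize)
  results <- lapply(norm, select_features, alpha = alpha)
  plan <- build_selection_plan(results, mode = mode,
                               fallback_k = fallback_k, alpha = alpha)
  pm <- matrix(NA_integer_, nrow = n_tests, ncol = length(subj),
               dimnames = list(as.character(seq_len(n_tests)), subj))
  if (!fold_safe) {
    for (tid in names(plan$per_test_features)) {
      t <- as.integer(tid)
      pm[tid, ] <- loo_predict_subset(norm[[t]],
                                      plan$per_test_features[[tid]], spec)
    }
  } else {
    for (i in seq_along(subj)) {
      fold_results <- lapply(subsets, function(s) {
        train <- vocal_test_subset(s$test_id, s$x[-i, , drop = FALSE],
                                   s$labels[-i], s$subject_ids[-i])
        select_features(train, alpha = alpha)
      })
      fold_plan <- build_selection_plan(fold_results, mode = mode,
                                        fallback_k = fallback_k,
                                        alpha = alpha)
      for (tid in names(fold_plan$per_test_features)) {
        t <- as.integer(tid)
        feats <- fold_plan$per_test_features[[tid]]
        s <- subsets[[t]]
        sc <- fit_apply_zscore(s$x[-i, feats, drop = FALSE],
                               s$x[i, feats, drop = FALSE])
        pm[tid, i] <- fit_predict(spec, sc$train, s$labels[-i], sc$test)
      }
    }
  }
  final <- majority_vote(pm)
  included <- which(rowSums(!is.na(pm)) > 0L)
  per_test <- data.frame(
    test_id = included,
    accuracy = vapply(included, function(t) {
      ok <- !is.na(pm[t, ])
      100 * mean(pm[t, ok] == truth[ok])
    }, double(1)))
  structure(list(metrics = compute_metrics(confusion(truth, final)),
                 per_test_accuracy = per_test, plan = plan,
                 selection_results = results,
                 predictions = pm, final = final, truth = truth,
                 subject_ids = subj, mode = mode, spec = spec,
                 alpha = alpha, fold_safe = fold_safe),
            class = "framework_result")
}

#' @export
print.framework_result <- function(x, ...) {
  cat(sprintf("%s framework, %s%s\n", gsub("_", "-", x$mode),
              format(x$spec), if (x$fold_safe) " (fold-safe)" else ""))
  cat(sprintf("included vocal tests: %d of %d\n",
              length(x$plan$per_test_features), nrow(x$predictions)))
  print(x$metrics)
  invisible(x)
}

#' Leave-one-subject-out baseline
#'
#' Pools all recordings into one matrix (after per-subset z-scoring, the
#' same preprocessing the framework uses; no feature selection). For each
#' subject, the classifier is trained on every recording of the other
#' subjects and predicts each of the held-out subject's recordings. Metrics
#' are per recording (`n_subjects * n_tests` predictions), which is why LOSO
#' accuracies need not be multiples of `1/n_subjects`.
#'
#' @param table a `recording_table` with >= 3 subjects.
#' @param spec a [classifier_spec()].
#' @param normalize z-score each subset first (default `TRUE`).
#' @return list: `metrics` (per-recording `metrics_report`), `pred`,
#'   `truth`, `rec_subject` (subject of each pooled recording).
#' @export
loso_cv <- function(table, spec, normalize = TRUE) {
  subsets <- separate_by_test(table)
  subj <- subsets[[1L]]$subject_ids
  if (length(subj) < 3L) stop("value error: need >= 3 subjects")
  if (normalize) subsets <- lapply(subsets, zscore_normalize)
  x <- do.call(rbind, lapply(subsets, function(s) s$x))
  rec_subject <- rep(subj, times = length(subsets))
  rec_truth <- rep(subsets[[1L]]$labels, times = length(subsets))
  pred <- rep(NA_integer_, length(rec_truth))
  for (s in subj) {
    test_rows <- rec_subject == s
    train_y <- rec_truth[!test_rows]
    if (length(unique(train_y)) < 2L) {
      stop("value error: training fold contains a single class")
    }
    pred[test_rows] <- fit_predict(spec, x[!test_rows, , drop = FALSE],
                                   train_y, x[test_rows, , drop = FALSE])
  }
  list(metrics = compute_metrics(confusion(rec_truth, pred)),
       pred = pred, truth = rec_truth, rec_subject = rec_subject)
}

# Summary statistics available to s-LOO. "trimmed_mean25" removes 25% of the
# values in total (12.5% from each tail); "mad" is the mean absolute
# deviation about the mean; "iqr" is stats::IQR (quantile type 7).
sloo_stat_funs <- list(
  mean = function(v) mean(v),
  median = function(v) stats::median(v),
  trimmed_mean25 = function(v) mean(v, trim = 0.125),
  sd = function(v) stats::sd(v),
  mad = function(v) mean(abs(v - mean(v))),
  iqr = function(v) stats::IQR(v)
)

#' Summary-statistic codes used in s-LOO configurations
#'
#' The numbered central-tendency metrics are 1 = mean, 2 = median,
#' 3 = trimmed mean (25% removed); the dispersion metrics are 4 = standard
#' deviation, 5 = mean absolute deviation, 6 = interquartile range. The
#' conventional pairings are `"1-4"` (mean + sd), `"2-5"` (median + mad),
#' `"3-6"` (trimmed mean + iqr) and `"all"` (all six).
#'
#' @param code one of `"1-4"`, `"2-5"`, `"3-6"`, `"all"`.
#' @return character vector of statistic names for [sloo_summarize()].
#' @export
sloo_stat_codes <- function(code = c("1-4", "2-5", "3-6", "all")) {
  code <- match.arg(code)
  switch(code,
         "1-4" = c("mean", "sd"),
         "2-5" = c("median", "mad"),
         "3-6" = c("trimmed_mean25", "iqr"),
         all = names(sloo_stat_funs))
}

#' Summarize each subject's recordings into one vector
#'
#' For every subject and feature, each chosen statistic is computed across
#' the subject's `n_tests` recordings; the per-statistic blocks are
#' concatenated statistic-major, feature-minor, giving vectors of length
#' `n_features * length(stats)`.
#'
#' @param table a `recording_table`.
#' @param stats character vector of statistic names, a nonempty subset of
#'   `names(sloo_stat_funs)`: mean, median, trimmed_mean25, sd, mad, iqr.
#' @return list: `x` (subject x summary matrix with `<stat>_f<j>` columns),
#'   `labels`, `subject_ids`, `stats`.
#' @export
sloo_summarize <- function(table, stats = c("mean", "sd")) {
  validate_recording_table(table)
  stopifnot(length(stats) >= 1L, all(stats %in% names(sloo_stat_funs)))
  n_features <- attr(table, "n_features")
  subj <- table_subjects(table)
  labs <- subject_labels(table)
  fm <- as.matrix(table[feature_names(n_features)])
  blocks <- lapply(stats, function(st) {
    f <- sloo_stat_funs[[st]]
    vals <- vapply(subj, function(s) {
      apply(fm[table$subject_id == s, , drop = FALSE], 2L, f)
    }, double(n_features))
    block <- t(matrix(vals, nrow = n_features))
    colnames(block) <- paste0(st, "_", feature_names(n_features))
    block
  })
  x <- do.call(cbind, blocks)
  rownames(x) <- subj
  list(x = x, labels = unname(labs), subject_ids = subj, stats = stats)
}

#' Summarized leave-one-out baseline
#'
#' Collapses each subject's recordings to summary statistics
#' ([sloo_summarize()]), z-scores the summary matrix, then runs a
#' leave-one-out over the subjects — one prediction per subject.
#'
#' @param table a `recording_table` with >= 3 subjects.
#' @param stats statistic names (see [sloo_stat_codes()]).
#' @param spec a [classifier_spec()].
#' @return list: `metrics` (per-subject `metrics_report`), `pred`, `truth`,
#'   `subject_ids`.
#' @export
sloo_cv <- function(table, stats, spec) {
  sm <- sloo_summarize(table, stats)
  if (length(sm$subject_ids) < 3L) stop("value error: need >= 3 subjects")
  x <- zscore_matrix(sm$x)
  subset <- vocal_test_subset(0L, x, sm$labels, sm$subject_ids)
  pred <- loo_predict_subset(subset, seq_len(ncol(x)), spec)
  list(metrics = compute_metrics(confusion(sm$labels, pred)),
       pred = unname(pred), truth = sm$labels,
       subject_ids = sm$subject_ids)
}
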