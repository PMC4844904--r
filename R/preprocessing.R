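# Per-vocal-test subsets and z-score normalization.

#' Construct a vocal-test subset
#'
#' One vocal test's data: an `n_subjects x n_features` matrix (one row per
#' subject, row order shared across all subsets of a table), the subject
#' labels and ids.
#'
#' @param test_id integer vocal-test id.
#' @param x numeric matrix, rows = subjects.
#' @param labels binary integer vector aligned to rows.
#' @param subject_ids character vector aligned to rows.
#' @return an object of class `vocal_test_subset`.
#' @export
vocal_test_subset <- function(test_id, x, labels, subject_ids) {
  x <- as.matrix(x)
  stopifnot(nrow(x) == length(labels), nrow(x) == length(subject_ids),
            all(labels %in% c(0L, 1L)))
  rownames(x) <- subject_ids
  structure(list(test_id = as.integer(test_id), x = x,
                 labels = as.integer(labels),
                 subject_ids = as.character(subject_ids)),
            class = "vocal_test_subset")
}

#' Split a recording table into per-vocal-test subsets
#'
#' Recordings of the same vocal test form one subset (all vowel-"a"
#' recordings, all vowel-"o" recordings, ...), so a 40-subject, 26-test table
#' yields 26 subsets of 40 samples. Subject order is the order of first
#' appearance in the table and is identical in every subset.
#'
#' @param table a `recording_table`.
#' @return list of [vocal_test_subset()]s, one per test id, in test order.
#' @export
separate_by_test <- function(table) {
  validate_recording_table(table)
  n_tests <- attr(table, "n_tests")
  n_features <- attr(table, "n_features")
  subj <- table_subjects(table)
  labs <- subject_labels(table)
  fm <- as.matrix(table[feature_names(n_features)])
  lapply(seq_len(n_tests), function(t) {
    rows <- table$test_id == t
    idx <- match(subj, table$subject_id[rows])
    vocal_test_subset(t, fm[rows, , drop = FALSE][idx, , drop = FALSE],
                      unname(labs), subj)
  })
}

#' Z-score normalize a vocal-test subset
#'
#' Centers every feature column to mean zero and scales it to unit sample
#' standard deviation (n - 1 denominator). Constant columns cannot be scaled
#' and are mapped to all-zeros with a warning. The transform is idempotent.
#'
#' @param subset a `vocal_test_subset` with at least two rows.
#' @return the normalized `vocal_test_subset`.
#' @export
zscore_normalize <- function(subset) {
  stopifnot(inherits(subset, "vocal_test_subset"))
  if (nrow(subset$x) < 2L) {
    stop("value error: z-scoring needs at least 2 rows")
  }
  subset$x <- zscore_matrix(subset$x,
                            warn_tag = paste0("test ", subset$test_id))
  subset
}

# Column-wise z-scoring with constant-column handling; used by the subset
# normalizer and by the fold-safe / s-LOO paths.
zscore_matrix <- function(x, warn_tag = NULL) {
  mu <- colMeans(x)
  s <- apply(x, 2L, stats::sd)
  const <- s == 0 | !is.finite(s)
  if (any(const) && !is.null(warn_tag)) {
    warning("constant feature column(s) mapped to zeros (", warn_tag, "): ",
            paste(colnames(x)[const], collapse = ", "), call. = FALSE)
  }
  s[const] <- 1
  out <- sweep(sweep(x, 2L, mu, "-"), 2L, s, "/")
  out[, const] <- 0
  out
}

# Scaling parameters estimated on training rows, applied to held-out rows.
# Constant training columns map both train and test values to zero.
fit_apply_zscore <- function(train_x, test_x) {
  mu <- colMeans(train_x)
  s <- apply(train_x, 2L, stats::sd)
  const <- s == 0 | !is.finite(s)
  s[const] <- 1
  scale_one <- function(m) {
    out <- sweep(sweep(m, 2L, mu, "-"), 2L, s, "/")
    out[, const] <- 0
    out
  }
  list(train = scale_one(train_x), test = scale_one(test_x))
}

#' Reassemble a recording table from vocal-test subsets
#'
#' Inverse of [separate_by_test()]; used for round-trip checks.
#'
#' @param subsets list of `vocal_test_subset`s from one table.
#' @return a `recording_table`.
#' @export
flatten_subsets <- function(subsets) {
  stopifnot(length(subsets) >= 1L)
  n_features <- ncol(subsets[[1L]]$x)
  dfs <- lapply(subsets, function(s) {
    data.frame(subject_id = s$subject_ids, test_id = s$test_id,
               as.data.frame(s$x, row.names = NULL), label = s$labels,
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, dfs)
  # restore subject-major, test-minor ordering
  df <- df[order(match(df$subject_id, subsets[[1L]]$subject_ids),
                 df$test_id), ]
  rownames(df) <- NULL
  recording_table(df, n_tests = length(subsets), n_features = n_features)
}
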