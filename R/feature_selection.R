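# Correlation-filter feature selection.
#
# For each vocal test, every feature is correlated with the binary class
# label (a point-biserial correlation, i.e. Pearson's r against a 0/1
# vector). The r is transformed to a two-sided p-value through Student's t
# with n - 2 degrees of freedom, and features with p < alpha are selected.
# Vocal tests where no feature passes are "unsuccessful"; the MCFS policy
# substitutes the globally most frequent selected features for them, the
# A-MCFS policy omits them from the ensemble altogether.

#' Pearson correlation between a feature and a vector
#'
#' Plain Pearson product-moment correlation; with a 0/1 `y` this is the
#' point-biserial correlation used by the selection filter. A constant input
#' vector has no defined correlation and yields `NA` (the degenerate-
#' correlation signal: callers treat such a feature as not selected).
#'
#' @param x,y numeric vectors of equal length `>= 3`.
#' @return correlation in `[-1, 1]`, or `NA` for degenerate input.
#' @export
pearson_r <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3L)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y)
}

#' Two-sided p-value of a correlation coefficient
#'
#' Uses the exact-null transformation `t = r * sqrt((n - 2) / (1 - r^2))`,
#' referred to Student's t with `n - 2` degrees of freedom. `|r| = 1` maps to
#' p = 0. Vectorized over `r`; monotone decreasing in `|r|` for fixed `n`.
#'
#' @param r correlation coefficient(s) in `[-1, 1]` (`NA` passes through).
#' @param n sample size, `>= 3`.
#' @return two-sided p-value(s) in `[0, 1]`.
#' @export
r_to_pvalue <- function(r, n) {
  if (n < 3L) stop("value error: n must be >= 3")
  if (any(abs(r) > 1 + 1e-12, na.rm = TRUE)) {
    stop("value error: |r| must be <= 1")
  }
  r <- pmin(pmax(r, -1), 1)
  p <- rep(NA_real_, length(r))
  exact <- !is.na(r) & abs(r) == 1
  p[exact] <- 0
  ok <- !is.na(r) & !exact
  t_stat <- r[ok] * sqrt((n - 2) / (1 - r[ok]^2))
  p[ok] <- 2 * stats::pt(abs(t_stat), df = n - 2, lower.tail = FALSE)
  p
}

#' Correlation-filter selection on one vocal-test subset
#'
#' Feature `j` is selected iff the two-sided p-value of its label correlation
#' is strictly below `alpha`. Constant features are never selected (their r
#' is degenerate). Selection is invariant to positive affine rescaling of
#' feature columns, so it behaves identically on raw and z-scored subsets.
#'
#' @param subset a [vocal_test_subset()].
#' @param alpha significance level (default 0.05).
#' @return object of class `feature_selection_result`: the per-feature
#'   `correlations` data frame (`feature`, `r`, `p_value`, `selected`),
#'   `selected_features` (increasing indices) and the `successful` flag
#'   (`TRUE` iff at least one feature was selected).
#' @export
select_features <- function(subset, alpha = 0.05) {
  stopifnot(inherits(subset, "vocal_test_subset"), alpha >= 0, alpha <= 1)
  r <- suppressWarnings(as.vector(stats::cor(subset$x, subset$labels)))
  if (stats::sd(subset$labels) == 0) r <- rep(NA_real_, ncol(subset$x))
  p <- r_to_pvalue(r, nrow(subset$x))
  selected <- !is.na(p) & p < alpha
  new_selection_result(subset$test_id,
                       data.frame(feature = seq_len(ncol(subset$x)),
                                  r = r, p_value = p, selected = selected),
                       which(selected))
}

new_selection_result <- function(test_id, correlations, selected_features) {
  structure(list(test_id = as.integer(test_id),
                 correlations = correlations,
                 selected_features = as.integer(selected_features),
                 successful = length(selected_features) > 0L),
            class = "feature_selection_result")
}

#' Cross-test selection frequency of each feature
#'
#' Counts, for every feature index, in how many vocal tests it was selected.
#'
#' @param results list of `feature_selection_result`s (one per test).
#' @param n_features total number of features.
#' @return named integer vector of length `n_features` (names `f1`, ...).
#' @export
feature_frequencies <- function(results, n_features) {
  all_sel <- as.integer(unlist(lapply(results, function(r) r$selected_features)))
  counts <- tabulate(all_sel, nbins = n_features)
  stats::setNames(as.integer(counts), feature_names(n_features))
}

#' Build the per-test feature plan under MCFS or A-MCFS
#'
#' Successful vocal tests always keep their own selected features. For
#' unsuccessful tests:
#' * `"MCFS"` substitutes the `fallback_k` most frequently selected features
#'   across all tests (ties broken towards the lower feature index; fewer
#'   than `fallback_k` are used if fewer features were ever selected);
#' * `"A_MCFS"` omits the test from the ensemble.
#'
#' @param results list of `feature_selection_result`s, one per test.
#' @param mode `"MCFS"` or `"A_MCFS"`.
#' @param fallback_k number of fallback features for MCFS (default 4).
#' @param alpha the significance level used (recorded in the plan).
#' @return object of class `selection_plan`: `mode`, `per_test_features`
#'   (named list, test id -> integer feature indices; omitted tests absent),
#'   `fallback_features`, `successful_tests`, `omitted_tests`, `alpha`,
#'   `fallback_k`.
#' @export
build_selection_plan <- function(results, mode = c("MCFS", "A_MCFS"),
                                 fallback_k = 4L, alpha = 0.05) {
  mode <- match.arg(mode)
  stopifnot(fallback_k >= 1L)
  test_ids <- vapply(results, function(r) r$test_id, integer(1))
  successful <- vapply(results, function(r) r$successful, logical(1))
  n_features <- max(vapply(results, function(r) nrow(r$correlations),
                           integer(1)))
  per_test <- lapply(results, function(r) r$selected_features)
  names(per_test) <- as.character(test_ids)

  fallback <- integer(0)
  if (mode == "MCFS") {
    if (!any(successful)) {
      stop("MCFS impossible: every vocal test is unsuccessful, ",
           "no feature frequencies to rank")
    }
    freq <- feature_frequencies(results, n_features)
    ranked <- order(-freq, seq_along(freq))   # ties -> lower feature index
    ranked <- ranked[freq[ranked] > 0L]
    fallback <- sort(ranked[seq_len(min(fallback_k, length(ranked)))])
    per_test[!successful] <- list(fallback)
  } else {
    per_test <- per_test[successful]
  }
  structure(list(mode = mode, per_test_features = per_test,
                 fallback_features = fallback,
                 successful_tests = test_ids[successful],
                 omitted_tests = if (mode == "A_MCFS")
                   test_ids[!successful] else integer(0),
                 alpha = alpha, fallback_k = as.integer(fallback_k)),
            class = "selection_plan")
}

#' Selection results from a published per-test feature table
#'
#' Converts a table of pre-computed selections — e.g. the published reference
#' selections for the UCI Parkinson speech dataset shipped in
#' `system.file("extdata", "reference_selected_features.csv", package =
#' "vocalvote")` — into `feature_selection_result` objects so that
#' [feature_frequencies()] and [build_selection_plan()] apply to them.
#' r/p values are not part of such tables and are recorded as `NA`.
#'
#' @param df data frame with columns `test_id` and `features` (feature
#'   indices separated by semicolons; empty string = unsuccessful test).
#' @param n_features total number of features (default 26).
#' @return list of `feature_selection_result`s.
#' @export
selection_results_from_table <- function(df, n_features = 26L) {
  stopifnot(all(c("test_id", "features") %in% names(df)))
  lapply(seq_len(nrow(df)), function(i) {
    feats <- df$features[i]
    sel <- if (is.na(feats) || !nzchar(trimws(feats))) integer(0) else
      sort(as.integer(strsplit(trimws(feats), ";", fixed = TRUE)[[1]]))
    corr <- data.frame(feature = seq_len(n_features), r = NA_real_,
                       p_value = NA_real_,
                       selected = seq_len(n_features) %in% sel)
    new_selection_result(df$test_id[i], corr, sel)
  })
}

#' Write a per-test selection report
#'
#' One row per (test, feature): `test_id`, `feature_index`, `r`, `p_value`,
#' `selected`.
#'
#' @param results list of `feature_selection_result`s.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_selection_report <- function(results, path) {
  rows <- do.call(rbind, lapply(results, function(r) {
    data.frame(test_id = r$test_id,
               feature_index = r$correlations$feature,
               r = r$correlations$r, p_value = r$correlations$p_value,
               selected = r$correlations$selected)
  }))
  write.csv(rows, path, row.names = FALSE)
  invisible(path)
}
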