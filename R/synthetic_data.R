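# Seeded generator of synthetic recording tables.
#
# Emulates the structure of the multi-recording voice dataset: balanced PD /
# control subjects, n_tests recordings per subject, n_features features per
# recording. Features of a recording are multivariate Gaussian with an
# exchangeable (compound-symmetry) correlation, mimicking the strong
# within-family correlation of jitter/shimmer measures. In a configurable
# subset of "informative" vocal tests, PD subjects' means are shifted on a
# configurable subset of features; all other (test, feature) pairs are pure
# noise, identically distributed in both classes.

#' Specification of a synthetic recording table
#'
#' The defaults reproduce the study conditions the package is designed
#' around: 40 subjects (20 PD / 20 control), 26 vocal tests with 26 features
#' each, disease signal confined to three vocal tests (4, 6 and 7) as a
#' 1.5-SD class-mean shift on features 1-4, and an exchangeable within-test
#' feature correlation of 0.3.
#'
#' For smaller tables the default informative sets scale down automatically:
#' only the test ids / feature indices that exist are kept.
#'
#' @param n_subjects even integer; classes are always balanced
#'   (`n_subjects/2` PD, `n_subjects/2` control).
#' @param n_tests number of vocal tests per subject.
#' @param n_features number of features per recording.
#' @param informative_tests integer vector of test ids carrying class signal
#'   (subset of `1..n_tests`); empty vector = pure-noise table.
#' @param informative_features integer vector of feature indices shifted in
#'   informative tests.
#' @param effect class-mean shift in units of `noise_sd`.
#' @param noise_sd marginal feature standard deviation (> 0).
#' @param feature_corr exchangeable correlation between features of one
#'   recording, in `[0, 1)`.
#' @param seed integer seed; identical seeds give bit-identical tables.
#' @return an object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_subjects = 40L, n_tests = 26L, n_features = 26L,
                           informative_tests = c(4L, 6L, 7L),
                           informative_features = 1:4,
                           effect = 1.5, noise_sd = 1,
                           feature_corr = 0.3, seed = 1L) {
  if (n_subjects %% 2L != 0L || n_subjects < 2L) {
    stop("value error: n_subjects must be even and >= 2 (balanced classes)")
  }
  stopifnot(n_tests >= 1L, n_features >= 1L, noise_sd > 0,
            feature_corr >= 0, feature_corr < 1)
  tests_given <- !missing(informative_tests)
  feats_given <- !missing(informative_features)
  informative_tests <- as.integer(informative_tests)
  informative_features <- as.integer(informative_features)
  if (!tests_given) {
    informative_tests <- intersect(informative_tests, seq_len(n_tests))
  }
  if (!feats_given) {
    informative_features <- intersect(informative_features,
                                      seq_len(n_features))
  }
  if (!all(informative_tests %in% seq_len(n_tests))) {
    stop("value error: informative_tests must lie in 1..n_tests")
  }
  if (!all(informative_features %in% seq_len(n_features))) {
    stop("value error: informative_features must lie in 1..n_features")
  }
  structure(list(n_subjects = as.integer(n_subjects),
                 n_tests = as.integer(n_tests),
                 n_features = as.integer(n_features),
                 informative_tests = informative_tests,
                 informative_features = informative_features,
                 effect = effect, noise_sd = noise_sd,
                 feature_corr = feature_corr, seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Generate a synthetic recording table
#'
#' Draws, for every (subject, test) recording, a feature vector
#' `noise_sd * (sqrt(rho) z0 + sqrt(1 - rho) z)` where `z0` is a scalar
#' shared by the recording's features and `z` is i.i.d. standard normal —
#' i.e. a multivariate Gaussian with exchangeable correlation `rho =
#' feature_corr`. PD subjects additionally receive `effect * noise_sd` on
#' `informative_features` of `informative_tests`. The generator runs under
#' its own seed and leaves the session's RNG state untouched.
#'
#' @param spec a [synthetic_spec()].
#' @return a validated [recording_table()]; subjects `pd01..` then `hc01..`.
#' @export
generate_table <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  n_half <- spec$n_subjects %/% 2L
  subj <- c(sprintf("pd%03d", seq_len(n_half)),
            sprintf("hc%03d", seq_len(n_half)))
  labels <- c(rep(1L, n_half), rep(0L, n_half))
  n_rows <- spec$n_subjects * spec$n_tests
  rho <- spec$feature_corr
  withr::with_seed(spec$seed, {
    z0 <- stats::rnorm(n_rows)
    z <- matrix(stats::rnorm(n_rows * spec$n_features), nrow = n_rows)
    x <- spec$noise_sd * (sqrt(rho) * z0 + sqrt(1 - rho) * z)
  })
  row_test <- rep(seq_len(spec$n_tests), times = spec$n_subjects)
  row_label <- rep(labels, each = spec$n_tests)
  shift_rows <- row_label == 1L & row_test %in% spec$informative_tests
  if (any(shift_rows) && length(spec$informative_features) > 0L) {
    x[shift_rows, spec$informative_features] <-
      x[shift_rows, spec$informative_features] +
      spec$effect * spec$noise_sd
  }
  colnames(x) <- feature_names(spec$n_features)
  df <- data.frame(subject_id = rep(subj, each = spec$n_tests),
                   test_id = row_test, x, label = row_label,
                   stringsAsFactors = FALSE)
  recording_table(df, n_tests = spec$n_tests, n_features = spec$n_features)
}
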