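# Shared fixtures: reference tables shipped with the package and small
# hand-built recording tables / subsets.

ref_file <- function(name) {
  path <- system.file("extdata", name, package = "vocalvote")
  stopifnot(nzchar(path))
  path
}

load_reference_selections <- function() {
  df <- read.csv(ref_file("reference_selected_features.csv"),
                 stringsAsFactors = FALSE)
  selection_results_from_table(df, n_features = 26L)
}

load_reference_per_test_accuracy <- function() {
  read.csv(ref_file("reference_per_test_accuracy.csv"))
}

load_reference_confusion <- function() {
  read.csv(ref_file("reference_confusion_amcfs.csv"),
           stringsAsFactors = FALSE)
}

# A tiny tidy table: values filled deterministically from a function of
# (subject index, test, feature).
make_table <- function(n_subjects = 4L, n_tests = 3L, n_features = 2L,
                       value_fun = function(s, t, f) s + 10 * t + 100 * f) {
  subj <- sprintf("s%02d", seq_len(n_subjects))
  labels <- rep(c(1L, 0L), length.out = n_subjects)
  rows <- expand.grid(t = seq_len(n_tests), s = seq_len(n_subjects))
  feats <- sapply(seq_len(n_features), function(f) {
    mapply(value_fun, rows$s, rows$t, f)
  })
  feats <- matrix(feats, ncol = n_features)
  colnames(feats) <- paste0("f", seq_len(n_features))
  df <- data.frame(subject_id = subj[rows$s], test_id = rows$t, feats,
                   label = labels[rows$s], stringsAsFactors = FALSE)
  recording_table(df, n_tests = n_tests, n_features = n_features)
}

make_subset <- function(x, labels, test_id = 1L) {
  x <- as.matrix(x)
  vocal_test_subset(test_id, x, labels,
                    sprintf("s%02d", seq_len(nrow(x))))
}

# Well-separated two-cluster training data used for sanity checks.
separated_fixture <- function() {
  train_x <- cbind(c(-5, -5.5, -4.5, 5, 5.5, 4.5),
                   c(0.1, -0.2, 0.3, 0.2, -0.1, 0.3))
  list(train_x = train_x,
       train_y = c(0L, 0L, 0L, 1L, 1L, 1L),
       test_x = cbind(c(-5.2, 5.2), c(0, 0)),
       test_y = c(0L, 1L))
}

all_classifier_specs <- function() {
  list(classifier_spec("knn", k = 1),
       classifier_spec("knn", k = 3),
       classifier_spec("svm_linear"),
       classifier_spec("svm_rbf"),
       classifier_spec("naive_bayes"),
       classifier_spec("discriminant"))
}
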