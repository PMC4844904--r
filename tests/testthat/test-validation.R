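test_that("a perfect feature gives a perfect per-test LOO accuracy", {
  set.seed(31)
  labels <- rep(c(1L, 0L), each = 20L)
  x <- cbind(labels + 0, rnorm(40))
  s <- zscore_normalize(make_subset(x, labels))
  for (spec in all_classifier_specs()) {
    pred <- loo_predict_subset(s, 1L, spec)
    expect_identical(unname(pred), labels, info = format(spec))
  }
})

test_that("LOO predictions equal the exhaustive per-fold oracle on small subsets", {
  set.seed(17)
  for (n in c(4L, 6L)) {
    labels <- rep(c(1L, 0L), length.out = n)
    s <- make_subset(matrix(rnorm(n * 3L), ncol = 3L), labels)
    for (spec in list(classifier_spec("knn", k = 1),
                      classifier_spec("svm_linear"),
                      classifier_spec("discriminant"))) {
      expect_identical(unname(loo_predict_subset(s, 1:3, spec)),
                       oracle_loo(s, 1:3, spec), info = format(spec))
    }
  }
})

test_that("small fixture matches the hand-enumerated folds", {
  # 1-NN, x = [0, 0.5, 3, 3.2], labels [1, 1, 0, 0]; per fold the nearest
  # remaining point is 0.5, 0, 3.2, 3 -> predictions [1, 1, 0, 0]
  s <- make_subset(matrix(c(0, 0.5, 3, 3.2), ncol = 1L),
                   c(1L, 1L, 0L, 0L))
  pred <- loo_predict_subset(s, 1L, classifier_spec("knn", k = 1))
  expect_identical(unname(pred), c(1L, 1L, 0L, 0L))
  # a 2/1 class split always produces a single-class training fold
  s3 <- make_subset(matrix(c(0, 0.5, 3), ncol = 1L), c(1L, 1L, 0L))
  expect_error(loo_predict_subset(s3, 1L, classifier_spec("knn", k = 1)),
               "single class")
})

test_that("pure-noise subsets classify at chance on average", {
  accs <- sapply(1:50, function(seed) {
    spec <- synthetic_spec(n_subjects = 40L, n_tests = 1L, n_features = 3L,
                           informative_tests = integer(0), seed = seed)
    s <- zscore_normalize(separate_by_test(generate_table(spec))[[1L]])
    mean(loo_predict_subset(s, 1:3, classifier_spec("knn", k = 1)) ==
           s$labels)
  })
  expect_gt(mean(accs), 0.45)
  expect_lt(mean(accs), 0.55)
})

test_that("fold-safe and faithful LOO agree on strongly separated data", {
  spec <- synthetic_spec(n_subjects = 20L, n_tests = 1L, n_features = 3L,
                         informative_tests = 1L, informative_features = 1:3,
                         effect = 6, seed = 3)
  s_raw <- separate_by_test(generate_table(spec))[[1L]]
  k1 <- classifier_spec("knn", k = 3)
  faithful <- loo_predict_subset(zscore_normalize(s_raw), 1:3, k1)
  safe <- loo_predict_subset(s_raw, 1:3, k1, fold_safe = TRUE)
  expect_identical(faithful, safe)
})

test_that("majority vote follows strict majorities and resolves ties to PD", {
  pm <- rbind(c(1L, 0L, 1L), c(1L, 0L, 0L), c(0L, 0L, 1L))
  colnames(pm) <- c("a", "b", "c")
  expect_identical(unname(majority_vote(pm)), c(1L, 0L, 1L))
  # 13-13 tie over 26 voters -> 1
  tie <- matrix(rep(c(1L, 0L), each = 13L), ncol = 1L)
  expect_identical(unname(majority_vote(tie)), 1L)
  # absent votes are ignored; zero votes is an error
  pm_na <- rbind(c(1L, NA), c(NA, NA), c(0L, NA))
  colnames(pm_na) <- c("a", "b")
  expect_error(majority_vote(pm_na), "zero votes")
  expect_identical(unname(majority_vote(pm_na[, 1L, drop = FALSE])), 1L)
})

test_that("vote conservation: votes for 1 and 0 sum to the included tests", {
  tab <- generate_table(synthetic_spec(n_subjects = 12L, n_tests = 6L,
                                       n_features = 5L, seed = 21,
                                       informative_tests = c(2L, 3L),
                                       effect = 3))
  res <- run_framework(tab, mode = "A_MCFS",
                       spec = classifier_spec("knn", k = 3))
  votes <- colSums(!is.na(res$predictions))
  expect_true(all(votes == length(res$plan$per_test_features)))
  expect_equal(colSums(res$predictions == 1L, na.rm = TRUE) +
                 colSums(res$predictions == 0L, na.rm = TRUE),
               votes)
})

test_that("with a single successful test the framework output is that test's LOO", {
  set.seed(8)
  n <- 20L
  labels <- rep(c(1L, 0L), each = 10L)
  # test 2 carries a perfect feature; tests 1 and 3 are noise
  df <- do.call(rbind, lapply(1:3, function(t) {
    data.frame(subject_id = sprintf("s%02d", 1:n), test_id = t,
               f1 = if (t == 2L) labels + rnorm(n, sd = 0.01) else rnorm(n),
               f2 = rnorm(n), label = labels)
  }))
  tab <- recording_table(df, n_tests = 3L, n_features = 2L)
  res <- run_framework(tab, mode = "A_MCFS",
                       spec = classifier_spec("svm_linear"), alpha = 1e-8)
  expect_identical(names(res$plan$per_test_features), "2")
  expect_identical(unname(res$final), unname(res$predictions["2", ]))
  expect_equal(res$metrics$accuracy, 100)
})

test_that("alpha = 1 under MCFS selects every feature for every test", {
  tab <- generate_table(synthetic_spec(n_subjects = 10L, n_tests = 4L,
                                       n_features = 3L, seed = 14))
  res <- run_framework(tab, mode = "MCFS",
                       spec = classifier_spec("knn", k = 1), alpha = 1)
  expect_length(res$plan$per_test_features, 4L)
  for (f in res$plan$per_test_features) expect_identical(f, 1:3)
})

test_that("informative tests dominate: fused accuracy beats every noise test", {
  tab <- generate_table(synthetic_spec(seed = 77, effect = 2.5))
  res <- run_framework(tab, mode = "A_MCFS",
                       spec = classifier_spec("svm_linear"))
  per_test <- res$per_test_accuracy
  noise <- per_test[!per_test$test_id %in% c(4L, 6L, 7L), ]
  expect_gte(res$metrics$accuracy, max(noise$accuracy))
})

test_that("faithful full-table selection is optimistically biased on pure noise", {
  # the known leakage of selecting features on all subjects before LOO:
  # on null data the framework then scores systematically above chance,
  # which is why the fold_safe flag exists
  accs <- sapply(1:10, function(seed) {
    tab <- generate_table(synthetic_spec(n_subjects = 30L, n_tests = 8L,
                                         n_features = 10L,
                                         informative_tests = integer(0),
                                         seed = 4000L + seed))
    run_framework(tab, mode = "A_MCFS",
                  spec = classifier_spec("knn", k = 1))$metrics$accuracy
  })
  expect_gt(mean(accs), 55)
})

test_that("LOSO matches the explicit per-subject oracle and scores a perfect feature", {
  tab <- make_table(n_subjects = 4L, n_tests = 2L, n_features = 2L,
                    value_fun = function(s, t, f) s * 0.9 + t * f + (s %% 2))
  for (spec in list(classifier_spec("knn", k = 1),
                    classifier_spec("svm_linear"))) {
    res <- loso_cv(tab, spec)
    oracle <- oracle_loso(tab, spec)
    expect_identical(res$pred, oracle$pred, info = format(spec))
    expect_identical(res$truth, oracle$truth)
  }
  # feature 1 equals the subject label in every recording -> 100%
  set.seed(2)
  n <- 6L
  labels <- rep(c(1L, 0L), each = 3L)
  df <- do.call(rbind, lapply(1:2, function(t) {
    data.frame(subject_id = sprintf("s%02d", 1:n), test_id = t,
               f1 = labels + 0, f2 = rnorm(n), label = labels)
  }))
  perfect <- recording_table(df, n_tests = 2L, n_features = 2L)
  expect_equal(loso_cv(perfect, classifier_spec("knn", k = 1))$metrics$accuracy,
               100)
})

test_that("LOSO metrics are per recording and near chance on noise", {
  accs <- sapply(1:20, function(seed) {
    tab <- generate_table(synthetic_spec(n_subjects = 20L, n_tests = 4L,
                                         n_features = 4L,
                                         informative_tests = integer(0),
                                         seed = seed))
    res <- loso_cv(tab, classifier_spec("knn", k = 1))
    expect_length(res$pred, 80L)   # n_subjects * n_tests predictions
    res$metrics$accuracy
  })
  expect_gt(mean(accs), 42)
  expect_lt(mean(accs), 58)
})

test_that("s-LOO summaries reproduce direct statistic evaluations", {
  df <- data.frame(subject_id = rep(c("a", "b"), each = 3L),
                   test_id = rep(1:3, 2L),
                   f1 = c(1, 2, 3, 5, 5, 5),
                   f2 = c(2, 4, 9, 1, 1, 4),
                   label = rep(c(1L, 0L), each = 3L))
  tab <- recording_table(df, n_tests = 3L, n_features = 2L)
  sm <- sloo_summarize(tab, c("mean", "sd"))
  expect_identical(colnames(sm$x), c("mean_f1", "mean_f2", "sd_f1", "sd_f2"))
  expect_equal(unname(sm$x["a", ]), c(2, 5, 1, sd(c(2, 4, 9))))
  expect_equal(unname(sm$x["b", "sd_f1"]), 0)   # constant -> zero dispersion
  # trimmed mean, 25% removed in total: one value off each tail of 8
  df8 <- data.frame(subject_id = rep(c("a", "b"), each = 8L),
                    test_id = rep(1:8, 2L),
                    f1 = c(1:8, 8:1), label = rep(c(1L, 0L), each = 8L))
  tab8 <- recording_table(df8, n_tests = 8L, n_features = 1L)
  sm8 <- sloo_summarize(tab8, "trimmed_mean25")
  expect_equal(unname(sm8$x[, 1L]), c(mean(2:7), mean(2:7)))
  # mad is the mean absolute deviation about the mean
  sm_mad <- sloo_summarize(tab, "mad")
  expect_equal(unname(sm_mad$x["a", "mad_f2"]),
               mean(abs(c(2, 4, 9) - 5)))
  expect_length(sloo_summarize(tab, sloo_stat_codes("all"))$x["a", ],
                2L * 6L)
})

test_that("s-LOO scores a perfect summary and runs all four stat configurations", {
  set.seed(12)
  n <- 8L
  labels <- rep(c(1L, 0L), each = 4L)
  df <- do.call(rbind, lapply(1:4, function(t) {
    data.frame(subject_id = sprintf("s%02d", 1:n), test_id = t,
               f1 = labels + rnorm(n, sd = 0.01), f2 = rnorm(n),
               label = labels)
  }))
  tab <- recording_table(df, n_tests = 4L, n_features = 2L)
  res <- sloo_cv(tab, "mean", classifier_spec("knn", k = 1))
  expect_equal(res$metrics$accuracy, 100)
  for (code in c("1-4", "2-5", "3-6", "all")) {
    r <- sloo_cv(tab, sloo_stat_codes(code), classifier_spec("svm_linear"))
    expect_s3_class(r$metrics, "metrics_report")
  }
})

test_that("s-LOO is near chance on pure-noise tables", {
  accs <- sapply(1:20, function(seed) {
    tab <- generate_table(synthetic_spec(n_subjects = 20L, n_tests = 6L,
                                         n_features = 4L,
                                         informative_tests = integer(0),
                                         seed = 600L + seed))
    sloo_cv(tab, c("mean", "sd"),
            classifier_spec("knn", k = 3))$metrics$accuracy
  })
  expect_gt(mean(accs), 38)
  expect_lt(mean(accs), 62)
})

test_that("fold-safe framework runs and omits votes where fold selection fails", {
  tab <- generate_table(synthetic_spec(n_subjects = 16L, n_tests = 5L,
                                       n_features = 6L,
                                       informative_tests = c(1L, 2L),
                                       effect = 2.5, seed = 5))
  res <- run_framework(tab, mode = "A_MCFS",
                       spec = classifier_spec("knn", k = 3),
                       fold_safe = TRUE)
  expect_s3_class(res$metrics, "metrics_report")
  # every subject still gets at least one vote from the informative tests
  expect_true(all(colSums(!is.na(res$predictions)) >= 1L))
  expect_gte(res$metrics$accuracy, 50)
})
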