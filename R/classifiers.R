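# Uniform train/predict contract over the four classifier families used in
# the framework: k-NN (Euclidean, k in {1,3,5,7}), SVM (linear and RBF with
# scaling factor sigma = 3, C = 1), Gaussian naive Bayes and linear
# discriminant analysis. All are deterministic given the inputs.

#' Classifier specification
#'
#' @param family one of `"knn"`, `"svm_linear"`, `"svm_rbf"`,
#'   `"naive_bayes"`, `"discriminant"`.
#' @param k number of neighbours (knn only); odd, so that a binary vote
#'   cannot tie. Default 7.
#' @param sigma RBF scaling factor (svm_rbf only); the kernel is
#'   `K(u, v) = exp(-||u - v||^2 / (2 sigma^2))`, i.e. `gamma = 1/(2 sigma^2)`
#'   in libsvm terms. Default 3.
#' @param C SVM cost parameter. Default 1.
#' @return an object of class `classifier_spec`.
#' @export
classifier_spec <- function(family = c("knn", "svm_linear", "svm_rbf",
                                       "naive_bayes", "discriminant"),
                            k = 7L, sigma = 3, C = 1) {
  family <- match.arg(family)
  if (family == "knn") {
    k <- as.integer(k)
    if (k < 1L || k %% 2L == 0L) stop("value error: knn needs odd k >= 1")
  }
  if (family == "svm_rbf" && sigma <= 0) stop("value error: sigma must be > 0")
  if (family %in% c("svm_linear", "svm_rbf") && C <= 0) {
    stop("value error: C must be > 0")
  }
  structure(list(family = family, k = k, sigma = sigma, C = C),
            class = "classifier_spec")
}

#' @export
format.classifier_spec <- function(x, ...) {
  switch(x$family,
         knn = sprintf("k-NN (k = %d)", x$k),
         svm_linear = sprintf("SVM (linear kernel, C = %g)", x$C),
         svm_rbf = sprintf("SVM (RBF kernel, sigma = %g, C = %g)",
                           x$sigma, x$C),
         naive_bayes = "Naive Bayes",
         discriminant = "Discriminant analysis")
}

#' @export
print.classifier_spec <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' Train a classifier and predict test labels
#'
#' Deterministic train-and-predict for each family:
#' * `knn`: Euclidean k-nearest neighbours; neighbour-distance ties are
#'   broken by training-row order, and odd `k` with binary labels rules out
#'   vote ties.
#' * `svm_linear` / `svm_rbf`: [e1071::svm()] with `scale = FALSE`.
#' * `naive_bayes`: Gaussian per-feature ([e1071::naiveBayes()]); a
#'   zero-variance feature has its standard deviation floored at 1e-9.
#' * `discriminant`: linear discriminant with pooled covariance (see
#'   [lda_pooled()]).
#'
#' @param spec a [classifier_spec()].
#' @param train_x,train_y training matrix and 0/1 labels; both classes must
#'   be present.
#' @param test_x matrix of test rows (same columns as `train_x`).
#' @return integer vector of predicted 0/1 labels, one per test row.
#' @export
fit_predict <- function(spec, train_x, train_y, test_x) {
  stopifnot(inherits(spec, "classifier_spec"))
  train_x <- as.matrix(train_x)
  test_x <- as.matrix(test_x)
  train_y <- as.integer(train_y)
  if (ncol(train_x) != ncol(test_x)) {
    stop("value error: train and test feature dimensions differ")
  }
  if (length(unique(train_y)) < 2L) {
    stop("value error: training set contains a single class")
  }
  colnames(train_x) <- colnames(test_x) <- paste0("v", seq_len(ncol(train_x)))
  switch(spec$family,
         knn = knn_predict(train_x, train_y, test_x, spec$k),
         svm_linear = svm_predict(train_x, train_y, test_x,
                                  kernel = "linear", cost = spec$C),
         svm_rbf = svm_predict(train_x, train_y, test_x, kernel = "radial",
                               cost = spec$C,
                               gamma = 1 / (2 * spec$sigma^2)),
         naive_bayes = nb_predict(train_x, train_y, test_x),
         discriminant = lda_pooled(train_x, train_y, test_x))
}

knn_predict <- function(train_x, train_y, test_x, k) {
  k <- min(k, nrow(train_x))
  d2 <- outer(rowSums(test_x^2), rowSums(train_x^2), "+") -
    2 * tcrossprod(test_x, train_x)
  vapply(seq_len(nrow(test_x)), function(i) {
    ord <- order(d2[i, ], seq_len(ncol(d2)))   # stable: ties by row order
    as.integer(mean(train_y[ord[seq_len(k)]]) > 0.5)
  }, integer(1))
}

svm_predict <- function(train_x, train_y, test_x, kernel, cost, gamma = NULL) {
  args <- list(x = train_x, y = factor(train_y, levels = c(0L, 1L)),
               kernel = kernel, cost = cost, scale = FALSE)
  if (!is.null(gamma)) args$gamma <- gamma
  fit <- do.call(e1071::svm, args)
  as.integer(as.character(predict(fit, test_x)))
}

nb_predict <- function(train_x, train_y, test_x) {
  fit <- e1071::naiveBayes(x = as.data.frame(train_x),
                           y = factor(train_y, levels = c(0L, 1L)))
  # floor zero within-class SDs so degenerate features stay usable
  fit$tables <- lapply(fit$tables, function(tab) {
    tab[, 2L] <- pmax(tab[, 2L], 1e-9)
    tab
  })
  as.integer(as.character(predict(fit, as.data.frame(test_x))))
}

#' Pooled-covariance linear discriminant classifier
#'
#' Classic two-class LDA: class means `m0`, `m1`, pooled within-class
#' covariance `S`, discriminant direction `w = S^-1 (m1 - m0)` and decision
#' `w'x > w'(m0 + m1)/2 - log(p1/p0)` with proportional priors. A small
#' ridge (`1e-8 * mean(diag(S))`, floored at 1e-12) stabilizes `S` so that
#' collinear or within-class-constant features — a perfectly separating
#' feature has zero within-class variance — are handled rather than refused.
#' Agrees with [MASS::lda()] on non-degenerate data.
#'
#' @param train_x,train_y training matrix and 0/1 labels.
#' @param test_x test matrix.
#' @return integer vector of predicted 0/1 labels.
#' @export
lda_pooled <- function(train_x, train_y, test_x) {
  train_x <- as.matrix(train_x)
  test_x <- as.matrix(test_x)
  i0 <- train_y == 0L
  i1 <- train_y == 1L
  m0 <- colMeans(train_x[i0, , drop = FALSE])
  m1 <- colMeans(train_x[i1, , drop = FALSE])
  c0 <- sweep(train_x[i0, , drop = FALSE], 2L, m0)
  c1 <- sweep(train_x[i1, , drop = FALSE], 2L, m1)
  s_pool <- (crossprod(c0) + crossprod(c1)) / (nrow(train_x) - 2L)
  ridge <- max(1e-8 * mean(diag(s_pool)), 1e-12)
  s_pool <- s_pool + diag(ridge, ncol(train_x))
  w <- solve(s_pool, m1 - m0)
  thresh <- sum(w * (m0 + m1)) / 2 - log(sum(i1) / sum(i0))
  as.integer(drop(test_x %*% w) > thresh)
}
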