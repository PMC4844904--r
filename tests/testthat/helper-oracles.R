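# Independent oracles used by the unit and acceptance tests. They
# deliberately re-derive results through a different code path (explicit
# loops, exhaustive enumeration, permutation resampling) than the
# implementation under test.

# Majority vote by explicit counting.
oracle_vote <- function(votes) {
  votes <- votes[!is.na(votes)]
  stopifnot(length(votes) > 0L)
  ones <- sum(votes == 1L)
  zeros <- sum(votes == 0L)
  if (ones > zeros) 1L else if (zeros > ones) 0L else 1L  # tie -> PD
}

# Leave-one-out by an explicit per-fold loop: build each training fold by
# hand and call the classifier on it.
oracle_loo <- function(subset, features, spec) {
  n <- nrow(subset$x)
  out <- integer(n)
  for (i in seq_len(n)) {
    tr_x <- subset$x[setdiff(seq_len(n), i), features, drop = FALSE]
    tr_y <- subset$labels[setdiff(seq_len(n), i)]
    te_x <- subset$x[i, features, drop = FALSE]
    out[i] <- fit_predict(spec, tr_x, tr_y, te_x)
  }
  out
}

# Leave-one-subject-out by an explicit loop over subjects on the pooled,
# per-subset z-scored recording matrix.
oracle_loso <- function(table, spec) {
  subsets <- lapply(separate_by_test(table), zscore_normalize)
  subj <- subsets[[1L]]$subject_ids
  x <- do.call(rbind, lapply(subsets, function(s) s$x))
  rec_subject <- rep(subj, times = length(subsets))
  rec_truth <- rep(subsets[[1L]]$labels, times = length(subsets))
  pred <- integer(length(rec_truth))
  for (s in subj) {
    te <- which(rec_subject == s)
    tr <- which(rec_subject != s)
    pred[te] <- fit_predict(spec, x[tr, , drop = FALSE], rec_truth[tr],
                            x[te, , drop = FALSE])
  }
  list(pred = pred, truth = rec_truth)
}

# Permutation null of the feature/label correlation: fraction of B label
# permutations with |r| at least r0.
oracle_permutation_pvalue <- function(x, y, r0, B) {
  r_null <- vapply(seq_len(B), function(b) cor(x, sample(y)), double(1))
  mean(abs(r_null) >= r0)
}
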