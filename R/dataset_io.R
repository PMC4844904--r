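# Recording-level data model and CSV dialects.
#
# A recording table holds one row per (subject, vocal test): an opaque subject
# id, a test id in 1..n_tests, n_features acoustic features and a binary class
# label (1 = Parkinson's disease, 0 = control). Two on-disk dialects are
# supported: the headerless UCI train-file layout (subject id first, label
# last, optional UPDRS column) and a self-describing "tidy" CSV.

#' Feature column names
#'
#' @param n_features number of features.
#' @return character vector `f1`, ..., `f<n_features>`.
#' @keywords internal
feature_names <- function(n_features) paste0("f", seq_len(n_features))

#' Construct a recording table
#'
#' Builds and validates the package's central container: a data frame with one
#' row per (subject, vocal test), columns `subject_id`, `test_id`,
#' `f1..f<n_features>` and `label`, carrying `n_tests`/`n_features` as
#' attributes.
#'
#' @param df data frame with the columns above. `subject_id` is coerced to
#'   character, `test_id` and `label` to integer.
#' @param n_tests number of vocal tests per subject (default: max `test_id`).
#' @param n_features number of feature columns (default: count of `f*`
#'   columns).
#' @return an object of class `recording_table` (a data frame).
#' @examples
#' df <- data.frame(subject_id = rep(c("a", "b"), each = 2),
#'                  test_id = c(1, 2, 1, 2),
#'                  f1 = rnorm(4), f2 = rnorm(4),
#'                  label = c(1, 1, 0, 0))
#' tab <- recording_table(df)
#' @export
recording_table <- function(df, n_tests = NULL, n_features = NULL) {
  stopifnot(is.data.frame(df))
  if (is.null(n_features)) {
    n_features <- sum(grepl("^f[0-9]+$", names(df)))
  }
  if (is.null(n_tests)) {
    if (nrow(df) == 0L) stop("cannot infer n_tests from an empty table")
    n_tests <- max(as.integer(df$test_id))
  }
  cols <- c("subject_id", "test_id", feature_names(n_features), "label")
  missing_cols <- setdiff(cols, names(df))
  if (length(missing_cols) > 0L) {
    stop("missing columns: ", paste(missing_cols, collapse = ", "))
  }
  df <- df[cols]
  df$subject_id <- as.character(df$subject_id)
  df$test_id <- as.integer(df$test_id)
  df$label <- as.integer(df$label)
  for (fc in feature_names(n_features)) df[[fc]] <- as.double(df[[fc]])
  structure(df,
            n_tests = as.integer(n_tests),
            n_features = as.integer(n_features),
            class = c("recording_table", "data.frame")) |>
    validate_recording_table()
}

#' Validate a recording table
#'
#' Checks the structural invariants: every subject has exactly one row per
#' test id in `1..n_tests`, all rows of a subject carry the same label, labels
#' are binary with both classes represented, and features are finite numbers.
#'
#' @param x a `recording_table`.
#' @return `x`, invisibly unchanged, or an error.
#' @export
validate_recording_table <- function(x) {
  stopifnot(inherits(x, "recording_table"))
  n_tests <- attr(x, "n_tests")
  n_features <- attr(x, "n_features")
  if (nrow(x) == 0L) stop("structural error: recording table has no rows")
  if (!all(x$label %in% c(0L, 1L))) {
    stop("value error: labels must be 0 (control) or 1 (PD); found: ",
         paste(unique(x$label[!x$label %in% c(0L, 1L)]), collapse = ", "))
  }
  if (!all(x$test_id >= 1L & x$test_id <= n_tests)) {
    stop("structural error: test_id outside 1..", n_tests)
  }
  fm <- as.matrix(x[feature_names(n_features)])
  if (!all(is.finite(fm))) {
    stop("value error: non-finite feature values present")
  }
  split_tests <- split(x$test_id, x$subject_id)
  bad <- names(split_tests)[vapply(split_tests, function(t) {
    length(t) != n_tests || !setequal(t, seq_len(n_tests))
  }, logical(1))]
  if (length(bad) > 0L) {
    stop("structural error: subject(s) without exactly one row per test 1..",
         n_tests, ": ", paste(bad, collapse = ", "))
  }
  lab_per_subj <- vapply(split(x$label, x$subject_id),
                         function(l) length(unique(l)), integer(1))
  if (any(lab_per_subj != 1L)) {
    stop("structural error: subject with inconsistent labels")
  }
  subj_labels <- vapply(split(x$label, x$subject_id), `[`, integer(1), 1L)
  if (sum(subj_labels == 1L) < 1L || sum(subj_labels == 0L) < 1L) {
    stop("structural error: both classes must have at least one subject")
  }
  invisible(x)
}

#' Subjects of a recording table, in first-appearance order
#'
#' @param table a `recording_table`.
#' @return character vector of subject ids.
#' @export
table_subjects <- function(table) unique(table$subject_id)

#' Per-subject labels, in first-appearance subject order
#'
#' @param table a `recording_table`.
#' @return named integer vector (names = subject ids).
#' @export
subject_labels <- function(table) {
  subj <- table_subjects(table)
  lab <- table$label[match(subj, table$subject_id)]
  stats::setNames(as.integer(lab), subj)
}

#' Read a recording table from CSV
#'
#' Two dialects:
#' * `"tidy"`: header `subject_id,test_id,f1,...,f<K>,label`; `n_features` is
#'   inferred from the header.
#' * `"uci_train"`: headerless, one row per recording, subject id first and
#'   class label last, `n_tests` consecutive rows per subject in vocal-test
#'   order (row order assigns `test_id` 1..n_tests within each subject block —
#'   the file format itself does not name the tests). A penultimate UPDRS
#'   column is detected by column count (`n_features + 3` columns instead of
#'   `n_features + 2`) and discarded.
#'
#' Labels must be 0/1; other encodings are remapped only through an explicit
#' `label_map`, never silently.
#'
#' @param path file path.
#' @param dialect `"tidy"` or `"uci_train"`.
#' @param n_tests,n_features expected table shape (`uci_train` only; the tidy
#'   dialect is self-describing).
#' @param label_map optional named vector mapping raw label strings to 0/1,
#'   e.g. `c("1" = 0, "2" = 1)`.
#' @return a validated [recording_table()].
#' @export
read_recording_table <- function(path, dialect = c("tidy", "uci_train"),
                                 n_tests = 26L, n_features = 26L,
                                 label_map = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("I/O error: file not found: ", path)
  if (dialect == "tidy") {
    header <- strsplit(readLines(path, n = 1L), ",", fixed = TRUE)[[1]]
    k <- length(header) - 3L
    expected <- c("subject_id", "test_id", feature_names(max(k, 0L)), "label")
    if (k < 1L || !identical(header, expected)) {
      stop("parse error: tidy header must be subject_id,test_id,f1,...,label")
    }
    df <- read_delim_checked(path, expected_width = length(header), skip = 1L)
    names(df) <- header
    df$label <- remap_labels(df$label, label_map)
    return(recording_table(df, n_features = k))
  }
  # uci_train: headerless, sniff UPDRS by column count
  raw <- read_delim_checked(path, expected_width = c(n_features + 2L,
                                                     n_features + 3L))
  width <- ncol(raw)
  has_updrs <- width == n_features + 3L
  features <- raw[, 2L:(n_features + 1L), drop = FALSE]
  names(features) <- feature_names(n_features)
  df <- data.frame(subject_id = as.character(raw[[1L]]),
                   features,
                   label = remap_labels(raw[[width]], label_map),
                   stringsAsFactors = FALSE)
  counts <- table(df$subject_id)
  if (any(counts != n_tests)) {
    stop("structural error: subject(s) with != ", n_tests, " rows: ",
         paste(names(counts)[counts != n_tests], collapse = ", "))
  }
  df$test_id <- stats::ave(seq_len(nrow(df)), df$subject_id,
                           FUN = seq_along)
  if (has_updrs) {
    message("uci_train: ", width, "-column file, UPDRS column discarded")
  }
  recording_table(df, n_tests = n_tests, n_features = n_features)
}

# Reads a comma-separated numeric-ish file, enforcing a uniform row width and
# reporting the first offending line number on failure.
read_delim_checked <- function(path, expected_width, skip = 0L) {
  lines <- readLines(path)
  if (skip > 0L) lines <- lines[-seq_len(skip)]
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("parse error: no data lines in ", path)
  fields <- strsplit(lines, ",", fixed = TRUE)
  widths <- lengths(fields)
  width <- widths[1L]
  if (!width %in% expected_width) {
    stop("parse error: line ", skip + 1L, " has ", width,
         " fields; expected ", paste(expected_width, collapse = " or "))
  }
  bad <- which(widths != width)
  if (length(bad) > 0L) {
    stop("parse error: line ", skip + bad[1L], " has ", widths[bad[1L]],
         " fields; expected ", width)
  }
  mat <- do.call(rbind, fields)
  df <- as.data.frame(mat, stringsAsFactors = FALSE)
  for (j in seq_len(ncol(df))[-1L]) {
    v <- suppressWarnings(as.numeric(df[[j]]))
    if (anyNA(v)) {
      bad_line <- which(is.na(v))[1L]
      stop("parse error: non-numeric value in line ", skip + bad_line,
           ", column ", j)
    }
    df[[j]] <- v
  }
  df
}

remap_labels <- function(label, label_map) {
  if (is.null(label_map)) return(label)
  mapped <- label_map[as.character(label)]
  if (anyNA(mapped)) {
    stop("value error: label(s) not covered by label_map: ",
         paste(unique(label[is.na(mapped)]), collapse = ", "))
  }
  as.integer(unname(mapped))
}

#' Write a recording table as tidy CSV
#'
#' Feature values are printed with 17 significant digits so that
#' `read_recording_table(write_recording_table(x))` is the identity on
#' doubles.
#'
#' @param table a valid `recording_table`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_recording_table <- function(table, path) {
  validate_recording_table(table)
  n_features <- attr(table, "n_features")
  out <- table
  for (fc in feature_names(n_features)) {
    out[[fc]] <- sprintf("%.17g", out[[fc]])
  }
  lines <- c(paste(names(out), collapse = ","),
             do.call(paste, c(unname(as.list(out)), sep = ",")))
  ok <- tryCatch({
    writeLines(lines, path)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop("I/O error: cannot write ", path)
  invisible(path)
}

#' @export
print.recording_table <- function(x, ...) {
  subj <- table_subjects(x)
  lab <- subject_labels(x)
  cat(sprintf("recording_table: %d subjects (%d PD / %d control), %d tests x %d features\n",
              length(subj), sum(lab == 1L), sum(lab == 0L),
              attr(x, "n_tests"), attr(x, "n_features")))
  invisible(x)
}
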