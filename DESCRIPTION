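Package: vocalvote
Title: Per-Vocal-Test Majority-Vote Classification for Parkinson's Disease Voice Data
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Multiple-classifier framework for detecting Parkinson's disease
    from feature tables of repeated voice recordings. Each vocal test
    (sustained vowels, numbers, words, short sentences) gets its own
    correlation-filtered feature subset and leave-one-out classifier; the
    per-test predictions are fused by majority vote. Includes the MCFS and
    A-MCFS policies for vocal tests where no feature passes the filter, the
    leave-one-subject-out (LOSO) and summarized leave-one-out (s-LOO)
    baselines, confusion-matrix metrics (accuracy, sensitivity, specificity,
    Matthews correlation coefficient), a seeded synthetic-data generator that
    emulates the multi-recording dataset structure, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    e1071,
    MASS,
    optparse,
    stats,
    utils,
    withr
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
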