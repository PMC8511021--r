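Package: rngprint
Title: Cognitive Fingerprints in Human Random Number Generation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis of human-generated pseudorandom digit sequences.
    Implements variation-tolerant pattern prevalence scoring based on the
    Damerau-Levenshtein edit distance, a robustified high-dimensional
    sequence distance, same-author identification with ROC/AUC and
    leave-one-subject-out jackknife inference, classical random number
    generation task indices (redundancy, ascending runs), a pattern
    preference/inhibition individuality analysis with familiar-number
    tests, and a synthetic cohort generator with subject-specific,
    session-stable pattern preferences for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    tibble,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
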