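# Small cohort fixtures for unit tests.  Unit tests use reduced sizes;
# the acceptance suite uses the cohort sizes of the study design.

tiny_spec <- function(n_subjects = 10L, sequence_length = 150L, ...) {
  cohort_spec(n_subjects = n_subjects, sequence_length = sequence_length, ...)
}

# corpus of uniform-random sequences (no generator structure at all)
uniform_corpus <- function(n_subjects, length = 150L, sessions = 1:2,
                           seed = 1L) {
  set.seed(seed)
  seqs <- list()
  for (i in seq_len(n_subjects)) {
    for (s in sessions) {
      seqs[[length(seqs) + 1L]] <- digit_sequence(
        sprintf("U%02d", i), s, sample(1:9, length, replace = TRUE))
    }
  }
  as_corpus(seqs)
}
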