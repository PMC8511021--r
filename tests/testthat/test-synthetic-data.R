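test_that("cohort generation is fully reproducible from the master seed", {
  spec <- tiny_spec(n_subjects = 5, master_seed = 91)
  c1 <- generate_corpus(spec)
  c2 <- generate_corpus(spec)
  expect_identical(c1$sequences, c2$sequences)
  f1 <- withr::local_tempfile()
  f2 <- withr::local_tempfile()
  write_corpus(c1, f1)
  write_corpus(c2, f2)
  expect_identical(readLines(f1), readLines(f2))  # byte-identical TSV
})

test_that("adding subjects never perturbs existing subjects' sequences", {
  small <- generate_corpus(tiny_spec(n_subjects = 4, master_seed = 92))
  large <- generate_corpus(tiny_spec(n_subjects = 6, master_seed = 92))
  keep <- large$sequences$subject_id %in% small$sequences$subject_id
  expect_identical(large$sequences[keep, ], small$sequences)
})

test_that("kappa = 0 collapses every subject onto the shared profile", {
  spec <- tiny_spec(n_subjects = 5, kappa = 0, master_seed = 93)
  p1 <- sample_profile(spec, 1)
  p4 <- sample_profile(spec, 4)
  expect_identical(p1$preferred, p4$preferred)
  expect_identical(p1$pref_weights, p4$pref_weights)
  expect_identical(p1$inhibited, p4$inhibited)
  # and profiles are deterministic per (seed, index)
  spec1 <- tiny_spec(n_subjects = 5, master_seed = 94)
  expect_identical(sample_profile(spec1, 3)$preferred,
                   sample_profile(spec1, 3)$preferred)
  # distinct subjects under kappa > 0 get distinct preferred sets
  labs <- function(p) vapply(p$preferred, paste0, character(1), collapse = "")
  expect_false(setequal(labs(sample_profile(spec1, 1)),
                        labs(sample_profile(spec1, 2))))
})

test_that("the deterministic template limit tiles the preferred pattern verbatim", {
  spec <- cohort_spec(n_subjects = 1, sequence_length = 60, kappa = 0,
                      n_shared_preferred = 1, n_shared_inhibited = 0,
                      template_rate = 1, edit_noise = 0, session_drift = 0,
                      master_seed = 95)
  prof <- sample_profile(spec, 1)
  pat <- prof$preferred[[1]]
  z <- generate_sequence(prof, spec, 1)$digits
  expect_identical(z, rep(pat, length.out = 60))
})

test_that("full repetition suppression with no templates forbids immediate repeats", {
  spec <- cohort_spec(n_subjects = 2, sequence_length = 300,
                      template_rate = 0, repetition_suppression = 1,
                      master_seed = 96)
  for (i in 1:2) {
    z <- generate_sequence(sample_profile(spec, i), spec, 1)$digits
    expect_identical(length(z), 300L)
    expect_true(all(z %in% 1:9))
    expect_true(all(diff(z) != 0))
  }
})

test_that("sequences have the specified length and digit domain", {
  spec <- tiny_spec(n_subjects = 3, sequence_length = 123, master_seed = 97)
  corp <- generate_corpus(spec)
  expect_true(all(vapply(corp$sequences$digits, length, integer(1)) == 123L))
  expect_true(all(unlist(corp$sequences$digits) %in% 1:9))
})

test_that("pooled digit marginals stay near uniform at the default design", {
  for (seed in c(201, 202)) {
    corp <- generate_corpus(cohort_spec(master_seed = seed))
    freq <- tabulate(unlist(corp$sequences$digits), 9) /
      length(unlist(corp$sequences$digits))
    expect_true(all(abs(freq - 1 / 9) < 0.03))
  }
})

test_that("same-subject sessions are closer than cross-subject pairs when kappa > 0", {
  corp <- generate_corpus(cohort_spec(n_subjects = 20, master_seed = 98))
  sc <- score_corpus(corp, pattern_space(3, exclude_repeats = TRUE))
  pairs <- pairwise_distances(standardize_scores(sc))
  wt <- stats::wilcox.test(pairs$distance[pairs$label == "match"],
                           pairs$distance[pairs$label == "non_match"],
                           alternative = "less")
  expect_lt(wt$p.value, 0.01)
})

test_that("the optional third session extends only the requested subjects", {
  spec <- tiny_spec(n_subjects = 5, third_session_subjects = 2,
                    master_seed = 99)
  corp <- generate_corpus(spec)
  tb <- corp$sequences
  expect_identical(sort(unique(tb$subject_id[tb$session == 3])),
                   c("S001", "S002"))
  expect_identical(nrow(tb), 12L)  # 5 x 2 + 2
})

test_that("familiar tables are deterministic and planted familiarity reaches the sequences", {
  spec <- tiny_spec(n_subjects = 6, master_seed = 100, familiar_boost = 3)
  fam <- generate_familiar(spec)
  expect_identical(fam, generate_familiar(spec))
  expect_setequal(unique(fam$kind), c("birthdate", "phone", "postal"))
  expect_true(all(grepl("^[0-9]+$", fam$digits)))
  corp <- generate_corpus(spec, familiar = fam)
  # planted patterns should be visibly over-represented in the subject's
  # own sequence relative to a corpus generated without planting
  spec0 <- tiny_spec(n_subjects = 6, master_seed = 100)
  corp0 <- generate_corpus(spec0, familiar = fam)  # boost 0: no planting
  sc <- score_corpus(corp, pattern_space(3))
  sc0 <- score_corpus(corp0, pattern_space(3))
  gain <- numeric(0)
  for (i in 1:6) {
    sid <- sprintf("S%03d", i)
    pats <- unique(unlist(lapply(fam$digits[fam$subject_id == sid],
                                 extract_familiar_patterns)))
    ci <- match(pats, sc$space$labels)
    row <- which(sc$subject_id == sid & sc$session == 1)
    gain <- c(gain, mean(sc$scores[row, ci]) - mean(sc0$scores[row, ci]))
  }
  expect_gt(mean(gain), 0)
})
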