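score_set_from_matrix <- function(S, subj, sess, n = 1L) {
  sp <- pattern_space(n)
  structure(list(scores = S, subject_id = subj, session = sess,
                 space = sp, scoring = "dls"),
            class = "score_set")
}

test_that("ordinal ranks sort ascending with lexicographic tie-breaks", {
  sp <- pattern_space(1)
  expect_identical(ordinal_ranks(seq(0.1, 0.9, by = 0.1), sp), 1:9)
  v <- c(0.5, 0.2, 0.2, 0.9, 0.1, 0.3, 0.3, 0.3, 0.4)
  r <- ordinal_ranks(v, sp)
  expect_identical(r[2], 2L)  # tie at 0.2: pattern "2" before "3"
  expect_identical(r[3], 3L)
  set.seed(15)
  for (rep in 1:20) {
    v <- runif(9)
    expect_identical(ordinal_ranks(v, sp), rank(v, ties.method = "first"))
  }
  expect_error(ordinal_ranks(runif(9), pattern_space(1, TRUE)), "full pattern")
})

test_that("a fully degenerate cohort yields an identically zero curve", {
  z <- c(1, 5, 3, 8, 2, 9, 4, 7, 6, 1, 5, 3)
  seqs <- list()
  for (s in c("A", "B", "C")) {
    for (k in 1:2) seqs[[length(seqs) + 1]] <- digit_sequence(s, k, z)
  }
  sc <- score_corpus(as_corpus(seqs), pattern_space(2))
  cur <- individuality_curve(sc)
  expect_equal(cur$within, rep(0, 81))
  expect_equal(cur$between, rep(0, 81))
  expect_equal(cur$delta, rep(0, 81))
})

test_that("the curve equals a hand-rolled double loop on a toy corpus", {
  set.seed(23)
  seqs <- list()
  for (s in c("A", "B", "C", "D")) {
    for (k in 1:2) {
      seqs[[length(seqs) + 1]] <- digit_sequence(s, k, sample(1:9, 25, TRUE))
    }
  }
  sc <- score_corpus(as_corpus(seqs), pattern_space(1))
  cur <- individuality_curve(sc)

  S <- sc$scores
  subj <- sc$subject_id
  sess <- sc$session
  subjects <- unique(subj)
  within <- between <- matrix(NA_real_, 4, 9)
  for (i in seq_along(subjects)) {
    s1 <- S[subj == subjects[i] & sess == 1, ]
    s2 <- S[subj == subjects[i] & sess == 2, ]
    ord <- order(s1)
    for (k in 1:9) {
      pat <- ord[k]
      within[i, k] <- abs(s1[pat] - s2[pat])
      others <- subjects[-i]
      between[i, k] <- mean(vapply(others, function(o)
        abs(s1[pat] - S[subj == o & sess == 1, pat]), numeric(1)))
    }
  }
  expect_equal(cur$within, colMeans(within), tolerance = 1e-12)
  expect_equal(cur$between, colMeans(between), tolerance = 1e-12)
  expect_equal(cur$delta, colMeans(between - within), tolerance = 1e-12)
})

test_that("the curve is invariant to subject order and labels", {
  corp <- generate_corpus(tiny_spec(n_subjects = 6, master_seed = 77))
  sc <- score_corpus(corp, pattern_space(2))
  cur <- individuality_curve(sc)
  perm <- sample(nrow(sc$scores))
  sc2 <- sc
  sc2$scores <- sc$scores[perm, ]
  sc2$subject_id <- paste0("Z", sc$subject_id[perm])
  sc2$session <- sc$session[perm]
  cur2 <- individuality_curve(sc2)
  expect_equal(cur2$within, cur$within, tolerance = 1e-12)
  expect_equal(cur2$delta, cur$delta, tolerance = 1e-12)
})

test_that("band reports count rank membership with deterministic ties", {
  # three identical subjects: ranks are shared, so counts are 0 or 3
  z <- c(2, 4, 6, 8, 1, 3, 5, 7, 9, 2, 4, 6)
  seqs <- list()
  for (s in c("A", "B", "C")) {
    for (k in 1:2) seqs[[length(seqs) + 1]] <- digit_sequence(s, k, z)
  }
  sc <- score_corpus(as_corpus(seqs), pattern_space(1))
  bands <- tibble::tibble(band = c("low", "high"), lo = c(1L, 5L), hi = c(4L, 9L))
  bt <- band_top_patterns(sc, bands, top_k = 10)
  expect_identical(sort(unique(bt$count)), 3L)
  expect_identical(sum(bt$band == "low"), 4L)   # whole band returned
  expect_identical(sum(bt$band == "high"), 5L)
  bt2 <- band_top_patterns(sc, bands, top_k = 2)
  expect_identical(nrow(bt2), 4L)
  expect_error(band_top_patterns(sc, tibble::tibble(band = "x", lo = 5L, hi = 2L)),
               "empty band")
  expect_error(band_top_patterns(sc, tibble::tibble(band = "x", lo = 1L, hi = 99L)),
               "within")
})

test_that("default bands reproduce the printed length-3 ranges", {
  b <- default_bands()
  expect_identical(b$lo, c(1L, 11L, 201L, 230L, 700L))
  expect_identical(b$hi, c(10L, 200L, 230L, 300L, 729L))
})

test_that("familiar strings lose zeros and yield deduplicated length-3 patterns", {
  expect_identical(extract_familiar_patterns("12041990"),
                   c("124", "241", "419", "199"))  # "1241 99 0" -> windows
  expect_identical(extract_familiar_patterns("110"), character(0))
  expect_identical(extract_familiar_patterns("121212"),
                   c("121", "212"))
  expect_error(extract_familiar_patterns("12a"), "non-digit")
})

test_that("familiar-pattern test needs enough usable subjects and warns on unusable ones", {
  corp <- generate_corpus(tiny_spec(n_subjects = 6, master_seed = 55))
  sc <- score_corpus(corp, pattern_space(3))
  fam <- tibble::tibble(
    subject_id = c("S001", "S002", "S003", "S004"),
    kind = "birthdate",
    digits = c("15081991", "03021987", "27111975", "100")
  )
  expect_warning(res <- familiar_pattern_test(sc, fam), "skipping")
  expect_identical(res$n_subjects, 3L)
  expect_identical(res$df, 2)
  fam2 <- fam[1:2, ]
  expect_error(suppressWarnings(familiar_pattern_test(sc, fam2)), "fewer than 3")
})

test_that("familiar table I/O round-trips and validates kinds", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("subject_id\tkind\tdigits",
               "S001\tbirthdate\t01011990",
               "S001\tphone\t0123456789"), f)
  fam <- read_familiar(f)
  expect_identical(nrow(fam), 2L)
  writeLines(c("subject_id\tkind\tdigits", "S001\tlottery\t123"), f)
  expect_error(read_familiar(f), "unknown familiar kind")
})
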