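test_that("edit distance handles the canonical cases", {
  expect_identical(dl_distance("123", "123"), 0L)
  expect_identical(dl_distance("2169", "2196"), 1L)  # adjacent transposition
  expect_identical(dl_distance("1234", "5678"), 4L)  # four substitutions
  # OSA forbids editing across a transposition: 3, not the unrestricted 2
  expect_identical(dl_distance("31", "123"), 3L)
  expect_identical(dl_distance("", "123"), 3L)
  expect_identical(dl_distance("12", ""), 2L)
})

test_that("edit distance matches the recursive oracle on random pairs", {
  set.seed(42)
  for (rep in 1:200) {
    a <- sample(1:9, sample(0:6, 1), replace = TRUE)
    b <- sample(1:9, sample(0:6, 1), replace = TRUE)
    expect_identical(dl_distance(a, b), osa_oracle(a, b))
  }
})

test_that("edit distance is symmetric with identity of indiscernibles; triangle violations are rare OSA corner cases", {
  strings <- all_digit_strings(1:3, 3)
  k <- length(strings)
  D <- matrix(0L, k, k)
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      D[i, j] <- dl_distance(strings[[i]], strings[[j]])
    }
  }
  expect_true(all(D == t(D)))
  expect_true(all((D == 0L) == outer(seq_len(k), seq_len(k), function(i, j)
    mapply(function(a, b) identical(strings[[a]], strings[[b]]), i, j))))
  # the optimal-string-alignment variant can violate the triangle
  # inequality when a transposition is followed by an insertion between
  # the transposed characters (e.g. 31 -> 13 -> 123); such corner cases
  # exist but are a vanishing fraction of all triples
  viol <- 0L
  for (j in seq_len(k)) {
    excess <- D - outer(D[, j], D[j, ], "+")
    viol <- viol + sum(excess > 0L)
  }
  expect_gt(viol, 0L)            # the known corner cases are present
  expect_lt(viol / (k^3), 0.01)  # but vanishingly rare
})

test_that("pattern space enumeration is lexicographic with the expected sizes", {
  expect_identical(nrow(pattern_space(1)$patterns), 9L)
  expect_identical(nrow(pattern_space(3)$patterns), 729L)
  expect_identical(nrow(pattern_space(3, exclude_repeats = TRUE)$patterns),
                   576L)  # 9 * 8 * 8
  sp <- pattern_space(2)
  expect_identical(sp$labels[1:10],
                   c("11", "12", "13", "14", "15", "16", "17", "18", "19", "21"))
  expect_identical(sp$labels, pattern_space(2)$labels)  # deterministic
  spx <- pattern_space(3, exclude_repeats = TRUE)
  adj <- apply(spx$patterns, 1, function(p) any(p[-1] == p[-3]))
  expect_false(any(adj))
  expect_error(pattern_space(0), "1\\.\\.6")
  expect_error(pattern_space(7), "1\\.\\.6")
})

test_that("pattern scores match the analytic and oracle values", {
  expect_equal(pattern_score("1", c(1, 1, 1)), 1.0)
  expect_equal(pattern_score("2", c(1, 1, 1)), 0.5)
  # windows of (1,2,1,2): (1,2)->1, (2,1)->1/2, (1,2)->1; sum 2.5 / 4
  expect_equal(pattern_score("12", c(1, 2, 1, 2)), 0.625)
  expect_error(pattern_score("1234", c(1, 2)), "longer than")
  set.seed(7)
  for (rep in 1:20) {
    z <- sample(1:9, 30, TRUE)
    m <- sample(1:9, sample(1:4, 1), TRUE)
    expect_equal(pattern_score(m, z), pattern_score_oracle(m, z),
                 tolerance = 1e-14)
  }
})

test_that("score vectors align with the space, stay in [0,1] and match the naive path", {
  set.seed(13)
  z <- sample(1:9, 300, TRUE)
  for (n in 1:3) {
    for (excl in c(FALSE, TRUE)) {
      sp <- pattern_space(n, exclude_repeats = excl)
      v <- score_vector(z, sp)
      expect_length(v, nrow(sp$patterns))
      expect_true(all(v >= 0 & v <= 1))
    }
  }
  sp2 <- pattern_space(2)
  expect_equal(score_vector(z, sp2), score_vector(z, sp2, method = "naive"),
               tolerance = 1e-12)
  # length-1 entries: every window is at distance 0 or 1
  v1 <- score_vector(z, pattern_space(1))
  expect_true(all(v1 >= 0.5 * 300 / 300 - 1e-12 & v1 <= 1))
})

test_that("exact counts are exact and affinely related to length-1 scores", {
  sp2 <- pattern_space(2)
  cnt <- exact_count_vector(c(1, 2, 1, 2), sp2)
  expect_equal(cnt[sp2$labels == "12"], 0.5)  # two exact windows / L = 4
  expect_equal(cnt[sp2$labels == "21"], 0.25)
  expect_equal(cnt[sp2$labels == "34"], 0)
  set.seed(21)
  sp1 <- pattern_space(1)
  for (rep in 1:10) {
    z <- sample(1:9, 120, TRUE)
    s <- score_vector(z, sp1)
    cexp <- exact_count_vector(z, sp1)
    # each length-1 window contributes 1 on a hit, 1/2 on a miss:
    # s_i = 1/2 + c_i / 2 with L windows
    expect_equal(s, 0.5 + 0.5 * cexp, tolerance = 1e-12)
  }
})

test_that("corpus scoring is a pure function of the digits", {
  corp1 <- uniform_corpus(4, length = 60, seed = 9)
  corp2 <- corp1
  corp2$sequences$subject_id <- paste0("X", corp2$sequences$subject_id)
  sp <- pattern_space(2, exclude_repeats = TRUE)
  s1 <- score_corpus(corp1, sp)
  s2 <- score_corpus(corp2, sp)
  expect_equal(unname(s1$scores), unname(s2$scores))
})
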