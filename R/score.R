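# The mathematical core: optimal-string-alignment Damerau-Levenshtein
# distance, the per-pattern prevalence score, and the exact-match
# (edit-intolerant) baseline.

#' Damerau-Levenshtein distance (optimal string alignment)
#'
#' Minimum number of unit-cost insertions, deletions, substitutions and
#' transpositions of adjacent characters converting one digit string
#' into the other, in the optimal-string-alignment (OSA) variant: each
#' element participates in at most one transposition, i.e. no substring
#' is edited again after being transposed.  For the short patterns used
#' here (length <= 6) the distinction from the unrestricted distance is
#' immaterial in practice.
#'
#' @param a,b Digit strings (e.g. `"2169"`) or integer vectors.
#' @return A non-negative integer; 0 iff `a == b`, symmetric, at most
#'   `max(length(a), length(b))`.
#' @examples
#' dl_distance("2169", "2196")  # one adjacent transposition -> 1
#' dl_distance("1234", "5678")  # four substitutions -> 4
#' @export
dl_distance <- function(a, b) {
  .cpp_osa_distance(as_digits(a), as_digits(b))
}

#' Prevalence score of one pattern in one sequence
#'
#' Slides a window of the pattern's length over every position of the
#' sequence where a full window fits, computes the edit distance of the
#' pattern to each window, and returns the sum of `1/(distance + 1)`
#' divided by the sequence length.  A pattern occurring often, exactly
#' or in slightly edited variations, receives a high score.
#'
#' This is the naive reference computation (one edit-distance evaluation
#' per window); [score_vector()] computes all patterns of a space at
#' once and agrees with it to within additive 1e-12.
#'
#' @param pattern Digit string or integer vector, not longer than `z`.
#' @param z Digit sequence (integer vector or digit string).
#' @return A real in `[1/(n+1), 1]` scaled by `(L - n + 1)/L`.
#' @examples
#' pattern_score("1", c(1, 1, 1))     # 1.0
#' pattern_score("12", c(1, 2, 1, 2)) # 0.625
#' @export
pattern_score <- function(pattern, z) {
  m <- as_digits(pattern)
  z <- as_digits(z)
  n <- length(m)
  L <- length(z)
  if (n > L) stop("pattern longer than sequence")
  s <- 0
  for (start in 1:(L - n + 1L)) {
    s <- s + 1 / (.cpp_osa_distance(m, z[start:(start + n - 1L)]) + 1)
  }
  s / L
}

#' Score a sequence against every pattern of a space
#'
#' @param z Digit sequence (integer vector or digit string).
#' @param space A [pattern_space()].
#' @param method `"trie"` (default) shares the dynamic-programming
#'   prefix rows across patterns; `"naive"` loops [pattern_score()] over
#'   patterns.  Both agree to within additive 1e-12.
#' @return Numeric vector aligned with `space$patterns`, each entry in
#'   `[0, 1]`.
#' @export
score_vector <- function(z, space, method = c("trie", "naive")) {
  method <- match.arg(method)
  stopifnot(inherits(space, "pattern_space"))
  z <- as_digits(z)
  if (space$n > length(z)) stop("pattern length exceeds sequence length")
  if (method == "trie") {
    .cpp_score_space(z, space$n, space$exclude_repeats)
  } else {
    apply(space$patterns, 1L, pattern_score, z = z)
  }
}

#' Exact-match pattern counts (edit-intolerant baseline)
#'
#' The non-edit-tolerant analogue of [score_vector()]: the number of
#' windows exactly equal to each pattern, divided by the sequence
#' length.  For length-1 patterns this is an exact affine image of the
#' edit-tolerant score (a length-1 window is either equal to the
#' pattern, term 1, or one substitution away, term 1/2), so both carry
#' identical ranking information; for longer patterns the two diverge.
#'
#' @inheritParams score_vector
#' @return Numeric vector of counts divided by sequence length, aligned
#'   with `space$patterns`.
#' @export
exact_count_vector <- function(z, space) {
  stopifnot(inherits(space, "pattern_space"))
  z <- as_digits(z)
  n <- space$n
  L <- length(z)
  if (n > L) stop("pattern length exceeds sequence length")
  W <- if (n == 1L) matrix(z, ncol = 1L) else stats::embed(z, n)[, n:1, drop = FALSE]
  idx <- as.integer((W - 1) %*% 9^((n - 1):0)) + 1L
  counts <- tabulate(idx, nbins = 9L^n)[space$full_index]
  counts / L
}

#' Score every sequence of a corpus
#'
#' @param corpus An `rng_corpus`.
#' @param space A [pattern_space()].
#' @param scoring `"dls"` for the edit-tolerant prevalence score,
#'   `"exact"` for the exact-match baseline.
#' @param method Passed to [score_vector()] when `scoring = "dls"`.
#' @return An object of class `score_set`: a list with `scores` (matrix,
#'   sequences x patterns, rows named `subject.session`), `subject_id`,
#'   `session`, `space` and `scoring`.
#' @export
score_corpus <- function(corpus, space, scoring = c("dls", "exact"),
                         method = "trie") {
  scoring <- match.arg(scoring)
  stopifnot(inherits(corpus, "rng_corpus"), inherits(space, "pattern_space"))
  tb <- corpus$sequences
  if (nrow(tb) == 0L) stop("empty corpus")
  f <- if (scoring == "dls") {
    function(z) score_vector(z, space, method = method)
  } else {
    function(z) exact_count_vector(z, space)
  }
  S <- t(vapply(tb$digits, f, numeric(nrow(space$patterns))))
  rownames(S) <- paste(tb$subject_id, tb$session, sep = ".")
  colnames(S) <- space$labels
  structure(list(scores = S, subject_id = tb$subject_id,
                 session = tb$session, space = space, scoring = scoring),
            class = "score_set")
}

#' @export
print.score_set <- function(x, ...) {
  cat("<score_set> ", nrow(x$scores), " sequence(s) x ", ncol(x$scores),
      " pattern(s), n = ", x$space$n, ", scoring = ", x$scoring, "\n", sep = "")
  invisible(x)
}

#' Write a score matrix as TSV
#'
#' One row per (subject, session), one column per pattern; column
#' headers are the concatenated pattern digits in lexicographic order.
#'
#' @param scores A `score_set` from [score_corpus()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_scores <- function(scores, path) {
  stopifnot(inherits(scores, "score_set"))
  df <- data.frame(subject_id = scores$subject_id, session = scores$session,
                   scores$scores, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, eol = "\n", fileEncoding = "UTF-8")
  invisible(path)
}
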