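# Corpus-level standardization of pattern scores and the robustified
# between-sequence distance.
#
# Raw prevalence scores are z-scored per pattern (column) over all
# sequences entering the analysis, then pattern-wise differences between
# two sequences are damped with tanh before taking the Euclidean norm.
# The damping bounds each coordinate's contribution below 1, so a few
# strategy changes between sessions cannot dominate the distance.

#' Standardize a score matrix per pattern
#'
#' Column-wise z-scoring using the population (divide by N) mean and
#' standard deviation over all sequences in the set.  Columns with zero
#' raw standard deviation become all-zero.
#'
#' @param scores A `score_set` from [score_corpus()], or a plain numeric
#'   matrix (sequences x patterns).
#' @return The input with a standardized matrix in `$z` and the
#'   per-column `$center` and `$scale`; class `std_score_set` is added.
#'   For a plain matrix input, a `std_score_set` without sequence keys.
#' @export
standardize_scores <- function(scores) {
  if (is.matrix(scores)) {
    scores <- structure(list(scores = scores,
                             subject_id = rep(NA_character_, nrow(scores)),
                             session = rep(NA_integer_, nrow(scores)),
                             space = NULL, scoring = "unknown"),
                        class = "score_set")
  }
  stopifnot(inherits(scores, "score_set"))
  S <- scores$scores
  if (nrow(S) < 2L) stop("standardization needs at least 2 sequences")
  mu <- colMeans(S)
  centered <- sweep(S, 2L, mu)
  sigma <- sqrt(colMeans(centered^2))
  Z <- sweep(centered, 2L, ifelse(sigma > 0, sigma, 1), "/")
  Z[, sigma == 0] <- 0
  out <- scores
  out$z <- Z
  out$center <- mu
  out$scale <- sigma
  class(out) <- c("std_score_set", class(scores))
  out
}

#' Distance between two standardized score vectors
#'
#' Robust form: `sqrt(sum(tanh(u - v)^2))`, which down-weights outlying
#' pattern-wise differences (each coordinate contributes < 1, so the
#' distance is bounded by `sqrt(P)`).  Native form: the plain Euclidean
#' norm `sqrt(sum((u - v)^2))`.
#'
#' @param u,v Numeric vectors of equal length.
#' @param robust Use the tanh-damped form (default `TRUE`).
#' @return A non-negative real, 0 iff `u == v`; symmetric in `u`, `v`.
#' @examples
#' dls_distance(c(2, 0), c(0, 0))                  # tanh(2) ~ 0.96403
#' dls_distance(c(2, 0), c(0, 0), robust = FALSE)  # 2
#' @export
dls_distance <- function(u, v, robust = TRUE) {
  if (length(u) != length(v)) stop("dimension mismatch")
  d <- u - v
  if (robust) sqrt(sum(tanh(d)^2)) else sqrt(sum(d^2))
}

scheme_sessions <- function(scheme) {
  switch(scheme,
         s1s2 = c(1L, 2L),
         s1s3 = c(1L, 3L),
         stop("unknown pairing scheme: ", scheme))
}

#' All cross-session pair distances with match/non-match labels
#'
#' For scheme `"s1s2"` every session-1 sequence is paired with every
#' session-2 sequence (the 40-minute analysis); `"s1s3"` pairs session 1
#' with session 3 (the 1-week analysis).  A pair is a *match* when both
#' sequences come from the same subject.  Restricting non-matches to
#' cross-session pairs keeps the session structure of match and
#' non-match distances identical, so practice or fatigue effects cancel.
#' Scheme `"all"` instead takes every unordered pair of sequences.
#' Subjects lacking a required session are skipped with a warning.
#'
#' @param std A `std_score_set` from [standardize_scores()].
#' @param scheme `"s1s2"`, `"s1s3"` or `"all"`.
#' @param robust Use the tanh-damped distance (default `TRUE`).
#' @return A tibble with columns `subject_a`, `session_a`, `subject_b`,
#'   `session_b`, `n`, `distance`, `label` (`"match"`/`"non_match"`).
#' @export
pairwise_distances <- function(std, scheme = c("s1s2", "s1s3", "all"),
                               robust = TRUE) {
  scheme <- match.arg(scheme)
  stopifnot(inherits(std, "std_score_set"))
  Z <- std$z
  subj <- std$subject_id
  sess <- std$session
  n_len <- if (!is.null(std$space)) std$space$n else NA_integer_

  if (scheme == "all") {
    P <- utils::combn(nrow(Z), 2L)
    dist <- vapply(seq_len(ncol(P)), function(k)
      dls_distance(Z[P[1L, k], ], Z[P[2L, k], ], robust = robust), numeric(1))
    return(tibble::tibble(
      subject_a = subj[P[1L, ]], session_a = sess[P[1L, ]],
      subject_b = subj[P[2L, ]], session_b = sess[P[2L, ]],
      n = n_len, distance = dist,
      label = ifelse(subj[P[1L, ]] == subj[P[2L, ]], "match", "non_match")))
  }

  ses <- scheme_sessions(scheme)
  have <- vapply(unique(subj), function(s)
    all(ses %in% sess[subj == s]), logical(1))
  keep_subj <- unique(subj)[have]
  if (any(!have))
    warning("skipping subject(s) lacking session ", ses[2L], ": ",
            paste(unique(subj)[!have], collapse = ", "))
  if (length(keep_subj) < 2L)
    stop("need at least 2 subjects with both sessions")
  ia <- match(paste(keep_subj, ses[1L]), paste(subj, sess))
  ib <- match(paste(keep_subj, ses[2L]), paste(subj, sess))
  k <- length(keep_subj)
  D <- matrix(0, k, k)
  for (i in seq_len(k)) {
    diff <- sweep(Z[ib, , drop = FALSE], 2L, Z[ia[i], ])
    D[i, ] <- if (robust) sqrt(rowSums(tanh(diff)^2)) else sqrt(rowSums(diff^2))
  }
  tibble::tibble(
    subject_a = rep(keep_subj, each = k), session_a = ses[1L],
    subject_b = rep(keep_subj, times = k), session_b = ses[2L],
    n = n_len, distance = as.vector(t(D)),
    label = ifelse(rep(keep_subj, each = k) == rep(keep_subj, times = k),
                   "match", "non_match"))
}

#' Write pair distances as TSV
#'
#' @param pairs Tibble from [pairwise_distances()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_distances <- function(pairs, path) {
  utils::write.table(as.data.frame(pairs), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, eol = "\n", fileEncoding = "UTF-8")
  invisible(path)
}
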