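# Pattern preference / inhibition individuality analysis.
#
# Unlike the identification distance, this analysis uses the FULL 9^n
# pattern space including adjacent-repeat patterns: universally avoided
# patterns (e.g. triplets of one digit) are themselves informative here.
# For each subject, patterns are ordered from most rare (rank 1) to
# most common (rank 9^n) in her first-session scores; the within-
# subject score difference (session 1 vs 2, same pattern) is compared
# with the between-subject difference (session 1 vs other subjects,
# same pattern) at every ordinal rank.  The excess of between over
# within measures how individual the patterns at that rank are.

#' Ordinal ranks of patterns by prevalence score
#'
#' Rank 1 is the most rare (lowest score, most inhibited) pattern, rank
#' `9^n` the most common (most preferred).  Ties are broken in favour of
#' the lexicographically smaller pattern.
#'
#' @param values Score vector aligned with the full (repeats included)
#'   pattern space.
#' @param space The [pattern_space()] the scores refer to; must not
#'   have repeats excluded.
#' @return Integer vector of ranks, one per pattern.
#' @export
ordinal_ranks <- function(values, space) {
  stopifnot(inherits(space, "pattern_space"))
  if (space$exclude_repeats)
    stop("individuality analysis requires the full pattern space ",
         "(exclude_repeats = FALSE)")
  if (length(values) != nrow(space$patterns))
    stop("score vector does not match the pattern space")
  r <- integer(length(values))
  r[order(values)] <- seq_along(values)  # stable: ties -> lexicographic
  r
}

# align session score matrices by subject; returns list(subjects, S1, S2)
align_sessions <- function(scores, sessions) {
  stopifnot(inherits(scores, "score_set"))
  subj <- unique(scores$subject_id)
  key <- paste(scores$subject_id, scores$session)
  i1 <- match(paste(subj, sessions[1L]), key)
  i2 <- match(paste(subj, sessions[2L]), key)
  if (anyNA(i1) || anyNA(i2))
    stop("every subject must have sessions ",
         paste(sessions, collapse = " and "))
  list(subjects = subj,
       S1 = scores$scores[i1, , drop = FALSE],
       S2 = scores$scores[i2, , drop = FALSE])
}

#' Within- vs between-subject score differences along the ordinal scale
#'
#' For each subject and each ordinal rank k, the rank-k pattern of her
#' first-session scores is located; the *within*-subject difference is
#' the absolute score change of that pattern between her two sessions,
#' the *between*-subject difference the mean absolute difference of her
#' first-session score from the other subjects' scores for the same
#' pattern.  Aggregating over subjects gives one curve per quantity;
#' `delta = between - within` is the degree of individuality of the
#' rank-k patterns.
#'
#' @param scores A `score_set` over the full pattern space containing
#'   both sessions for every subject (see [score_corpus()]).
#' @param sessions The two sessions to compare (default `c(1, 2)`).
#' @param between_session Which session of the *other* subjects the
#'   between-subject comparison uses (default the first).
#' @return A tibble of class `individuality_curve` with one row per
#'   ordinal rank: `ordinal`, `within`, `within_se`, `between`,
#'   `between_se`, `delta`, `delta_se`.
#' @export
individuality_curve <- function(scores, sessions = c(1L, 2L),
                                between_session = sessions[1L]) {
  if (scores$space$exclude_repeats)
    stop("individuality analysis requires the full pattern space ",
         "(exclude_repeats = FALSE)")
  al <- align_sessions(scores, sessions)
  S1 <- al$S1
  S2 <- al$S2
  key <- paste(scores$subject_id, scores$session)
  iB <- match(paste(al$subjects, between_session), key)
  SB <- scores$scores[iB, , drop = FALSE]
  ns <- length(al$subjects)
  if (ns < 2L) stop("need at least 2 subjects")
  P <- ncol(S1)
  W <- matrix(0, ns, P)  # within, ordinal order
  B <- matrix(0, ns, P)  # between, ordinal order
  for (i in seq_len(ns)) {
    ord <- order(S1[i, ])  # rank k -> pattern index ord[k]
    W[i, ] <- abs(S1[i, ] - S2[i, ])[ord]
    btw <- colMeans(abs(sweep(SB[-i, , drop = FALSE], 2L, S1[i, ])))
    B[i, ] <- btw[ord]
  }
  D <- B - W
  out <- tibble::tibble(
    ordinal = seq_len(P),
    within = colMeans(W),
    within_se = apply(W, 2L, stats::sd) / sqrt(ns),
    between = colMeans(B),
    between_se = apply(B, 2L, stats::sd) / sqrt(ns),
    delta = colMeans(D),
    delta_se = apply(D, 2L, stats::sd) / sqrt(ns)
  )
  class(out) <- c("individuality_curve", class(out))
  out
}

#' Default ordinal bands for the length-3 individuality analysis
#'
#' Named inclusive ordinal ranges delimiting regions of the length-3
#' individuality curve: universal exceptions (patterns nobody produces,
#' e.g. digit triplets), rare duplet and x-y-x patterns, individual
#' inhibitions, and individual preferences.  The printed ranges overlap
#' at ordinal 230 and leave 301..699 unassigned; they are reproduced
#' as-is.
#'
#' @param n Pattern length the bands refer to (default 3).
#' @return Tibble with columns `band`, `lo`, `hi`.
#' @export
default_bands <- function(n = 3L) {
  tibble::tibble(
    band = c("universal_exceptions", "rare_duplets", "rare_xyx",
             "individual_inhibitions", "individual_preferences"),
    lo = c(1L, 11L, 201L, 230L, 700L),
    hi = c(10L, 200L, 230L, 300L, as.integer(9^n))
  )
}

#' Data-driven band boundaries from the delta curve
#'
#' Locates local minima of the moving-average-smoothed delta curve;
#' useful as an alternative to the fixed [default_bands()].
#'
#' @param curve An [individuality_curve()].
#' @param window Moving-average window (odd, default 11).
#' @return Integer vector of ordinals at local minima of the smoothed
#'   delta curve.
#' @export
find_band_minima <- function(curve, window = 11L) {
  stopifnot(window %% 2L == 1L, window >= 3L)
  x <- curve$delta
  sm <- stats::filter(x, rep(1 / window, window), sides = 2L)
  sm <- as.numeric(sm)
  inner <- which(!is.na(sm))
  idx <- inner[-c(1L, length(inner))]
  idx[sm[idx] < sm[idx - 1L] & sm[idx] <= sm[idx + 1L]]
}

#' Most common patterns per ordinal band
#'
#' For every band, counts across subjects how often each pattern's
#' ordinal rank (in the subject's first-session scores) falls inside
#' the band, and returns the patterns with the highest counts (ties in
#' favour of the lexicographically smaller pattern).
#'
#' @param scores A `score_set` over the full pattern space.
#' @param bands Tibble with `band`, `lo`, `hi` (default
#'   [default_bands()]).
#' @param top_k Number of patterns per band (default 5); bands holding
#'   fewer distinct patterns return all of them.
#' @param session Session whose scores define the ranks (default 1).
#' @return Tibble with `band`, `pattern`, `count`.
#' @export
band_top_patterns <- function(scores, bands = default_bands(),
                              top_k = 5L, session = 1L) {
  if (scores$space$exclude_repeats)
    stop("individuality analysis requires the full pattern space")
  if (any(bands$hi < bands$lo)) stop("empty band range")
  S <- scores$scores[scores$session == session, , drop = FALSE]
  if (nrow(S) == 0L) stop("no sequences in session ", session)
  P <- ncol(S)
  if (any(bands$lo < 1L) || any(bands$hi > P))
    stop("band ranges must lie within [1, ", P, "]")
  ranks <- t(apply(S, 1L, ordinal_ranks, space = scores$space))
  out <- list()
  for (b in seq_len(nrow(bands))) {
    counts <- colSums(ranks >= bands$lo[b] & ranks <= bands$hi[b])
    nz <- which(counts > 0L)
    ordid <- nz[order(-counts[nz], nz)]
    ordid <- ordid[seq_len(min(top_k, length(ordid)))]
    out[[b]] <- tibble::tibble(band = bands$band[b],
                               pattern = scores$space$labels[ordid],
                               count = as.integer(counts[ordid]))
  }
  do.call(rbind, out)
}

#' Extract length-3 patterns from a familiar digit string
#'
#' Familiar numbers (birthdates, phone numbers, postal codes) may
#' contain the digit 0, which cannot occur in the task's 1..9 range;
#' zeros are dropped before taking all contiguous length-3 subpatterns,
#' which preserves the remaining order structure.  Patterns are
#' deduplicated.
#'
#' @param x A digit string (characters '0'..'9').
#' @return Character vector of length-3 pattern labels (possibly
#'   empty).
#' @export
extract_familiar_patterns <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  y <- gsub("0", "", x, fixed = TRUE)
  if (!grepl("^[1-9]*$", y)) stop("non-digit character in familiar string")
  k <- nchar(y)
  if (k < 3L) return(character(0))
  unique(substring(y, 1:(k - 2L), 3:k))
}

#' Read a familiar-number table
#'
#' TSV with columns `subject_id`, `kind` (one of `birthdate`, `phone`,
#' `postal`) and `digits` (a digit string which may contain '0').
#'
#' @param path Path to the TSV file.
#' @return Tibble with those three columns.
#' @export
read_familiar <- function(path) {
  if (!file.exists(path)) stop("familiar table not found: ", path)
  raw <- utils::read.delim(path, colClasses = "character", check.names = FALSE)
  need <- c("subject_id", "kind", "digits")
  if (!all(need %in% names(raw)))
    stop("malformed header: expected columns ", paste(need, collapse = ", "))
  bad <- !raw$kind %in% c("birthdate", "phone", "postal")
  if (any(bad)) stop("unknown familiar kind: ",
                     paste(unique(raw$kind[bad]), collapse = ", "))
  tibble::as_tibble(raw[need])
}

#' Test over-/under-representation of familiar patterns
#'
#' For each subject, the statistic is the mean, over her familiar
#' length-3 patterns, of her own first-session score minus the mean
#' score of the same pattern over all other subjects' first-session
#' sequences.  Across subjects, a one-sample two-sided t-test against 0
#' asks whether familiar patterns are systematically over- (positive)
#' or under- (negative) represented; a KS test checks normality of the
#' per-subject statistics.  Each familiar kind is tested separately.
#'
#' @param scores A `score_set` over the full length-3 pattern space.
#' @param familiar Tibble as from [read_familiar()].
#' @param session Session used for all scores (default 1).
#' @return Tibble with one row per kind: `kind`, `n_subjects`, `t`,
#'   `df`, `p`, `ks_D`, `ks_p`.
#' @export
familiar_pattern_test <- function(scores, familiar, session = 1L) {
  if (scores$space$exclude_repeats)
    stop("familiar-pattern test requires the full pattern space")
  if (scores$space$n != 3L)
    stop("familiar-pattern test is defined for length-3 scores")
  S <- scores$scores[scores$session == session, , drop = FALSE]
  subj <- scores$subject_id[scores$session == session]
  out <- list()
  for (kind in unique(familiar$kind)) {
    fk <- familiar[familiar$kind == kind, , drop = FALSE]
    stats_per_subject <- c()
    skipped <- character(0)
    for (s in unique(fk$subject_id)) {
      row <- match(s, subj)
      if (is.na(row)) { skipped <- c(skipped, s); next }
      pats <- unique(unlist(lapply(fk$digits[fk$subject_id == s],
                                   extract_familiar_patterns)))
      if (length(pats) == 0L) { skipped <- c(skipped, s); next }
      ci <- match(pats, scores$space$labels)
      own <- S[row, ci]
      others <- colMeans(S[-row, ci, drop = FALSE])
      stats_per_subject[s] <- mean(own - others)
    }
    if (length(skipped))
      warning("familiar kind '", kind, "': skipping subject(s) ",
              paste(skipped, collapse = ", "))
    if (length(stats_per_subject) < 3L)
      stop("familiar kind '", kind, "': fewer than 3 usable subjects")
    tt <- stats::t.test(stats_per_subject, mu = 0)
    m <- mean(stats_per_subject)
    sdev <- stats::sd(stats_per_subject)
    ks <- suppressWarnings(stats::ks.test(stats_per_subject, "pnorm", m, sdev))
    out[[kind]] <- tibble::tibble(
      kind = kind, n_subjects = length(stats_per_subject),
      t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value,
      ks_D = unname(ks$statistic), ks_p = ks$p.value)
  }
  do.call(rbind, out)
}
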