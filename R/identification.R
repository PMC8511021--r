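# Threshold classifier over pair distances: ROC/AUC, leave-one-subject-
# out jackknife, and trend / difference tests on jackknife replicates.
#
# The classifier has no free parameters: a pair is declared a match when
# its distance falls below a threshold, and the threshold is swept over
# all distances.  AUC is computed with the rank (Mann-Whitney) statistic
# -- the probability that a random match pair is closer than a random
# non-match pair, ties counted 1/2 -- which equals the trapezoidal area
# under the full ROC.

#' ROC curve and AUC for labelled pair distances
#'
#' @param pairs A data frame with numeric `distance` and `label`
#'   (`"match"`/`"non_match"`), as produced by [pairwise_distances()].
#' @return An object of class `roc_result`: list with `auc`, `points`
#'   (tibble of threshold, tpr, fpr at every distinct distance, plus the
#'   origin), `n_match`, `n_non_match`.
#' @examples
#' p <- data.frame(distance = c(1, 3, 2, 4),
#'                 label = c("match", "match", "non_match", "non_match"))
#' roc_auc(p)$auc  # 0.75
#' @export
roc_auc <- function(pairs) {
  d <- pairs$distance
  lab <- as.character(pairs$label)
  is_m <- lab == "match"
  nm <- sum(is_m)
  nn <- sum(!is_m)
  if (nm == 0L || nn == 0L)
    stop("need at least one match and one non-match pair")
  r <- rank(d)  # average ranks handle ties with weight 1/2
  U <- sum(r[is_m]) - nm * (nm + 1) / 2  # pairs where match > non-match
  auc <- 1 - U / (nm * nn)
  th <- sort(unique(d))
  tpr <- vapply(th, function(t) sum(d[is_m] <= t) / nm, numeric(1))
  fpr <- vapply(th, function(t) sum(d[!is_m] <= t) / nn, numeric(1))
  points <- tibble::tibble(threshold = c(-Inf, th),
                           tpr = c(0, tpr), fpr = c(0, fpr))
  structure(list(auc = auc, points = points,
                 n_match = nm, n_non_match = nn),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> AUC = %.4f (%d match, %d non-match pairs)\n",
              x$auc, x$n_match, x$n_non_match))
  invisible(x)
}

#' Jackknife standard error from leave-one-out replicates
#'
#' `SE = sqrt((n - 1)/n * sum((theta_i - mean(theta))^2))`.
#'
#' @param replicates Numeric vector of leave-one-out estimates.
#' @return The jackknife standard error.
#' @export
jackknife_se <- function(replicates) {
  n <- length(replicates)
  if (n < 3L) stop("need at least 3 replicates")
  sqrt((n - 1) / n * sum((replicates - mean(replicates))^2))
}

#' Jackknife a statistic over the elements of a vector
#'
#' Validates the jackknife machinery on statistics with known standard
#' errors (for the sample mean it reproduces `sd(x)/sqrt(n)` exactly).
#'
#' @param x Numeric vector.
#' @param statistic Function of a vector returning a scalar.
#' @param ... Passed to `statistic`.
#' @return List with `estimate` (full-sample), `se`, `replicates`.
#' @export
jackknife_statistic <- function(x, statistic, ...) {
  n <- length(x)
  if (n < 3L) stop("need at least 3 observations")
  reps <- vapply(seq_len(n), function(i) statistic(x[-i], ...), numeric(1))
  list(estimate = statistic(x, ...), se = jackknife_se(reps),
       replicates = reps)
}

# AUC for one subject subset: re-standardize over the retained
# sequences, form cross-session distances, rank AUC.  `S` is the raw
# score matrix whose rows align with (subj, sess).
auc_for_subjects <- function(S, subj, sess, ses, keep_subj, robust = TRUE) {
  rows <- which(subj %in% keep_subj & sess %in% ses)
  Sr <- S[rows, , drop = FALSE]
  mu <- colMeans(Sr)
  centered <- sweep(Sr, 2L, mu)
  sigma <- sqrt(colMeans(centered^2))
  Z <- sweep(centered, 2L, ifelse(sigma > 0, sigma, 1), "/")
  Z[, sigma == 0] <- 0
  rs <- subj[rows]
  rt <- sess[rows]
  ia <- match(paste(keep_subj, ses[1L]), paste(rs, rt))
  ib <- match(paste(keep_subj, ses[2L]), paste(rs, rt))
  k <- length(keep_subj)
  dist <- numeric(k * k)
  is_m <- logical(k * k)
  for (i in seq_len(k)) {
    diff <- sweep(Z[ib, , drop = FALSE], 2L, Z[ia[i], ])
    di <- if (robust) sqrt(rowSums(tanh(diff)^2)) else sqrt(rowSums(diff^2))
    dist[((i - 1) * k + 1):(i * k)] <- di
    is_m[(i - 1) * k + i] <- TRUE
  }
  nm <- sum(is_m)
  nn <- sum(!is_m)
  r <- rank(dist)
  U <- sum(r[is_m]) - nm * (nm + 1) / 2
  1 - U / (nm * nn)
}

#' Same-author identification performance by pattern length
#'
#' For each pattern length: score every sequence, standardize over the
#' sequences entering the analysis (both sessions pooled), compute all
#' cross-session pair distances, and evaluate the threshold classifier
#' by AUC.  With `jackknife = TRUE`, leave-one-subject-out replicates
#' recompute the entire pipeline downstream of the raw scores
#' (standardization, pairing, AUC) on the remaining subjects, giving a
#' jackknife standard error per length and a replicate table for
#' [trend_test()] and [difference_test()].
#'
#' @param corpus An `rng_corpus` whose subjects have both sessions of
#'   the scheme (others are skipped with a warning).
#' @param lengths Pattern lengths to analyse (default 1:6).
#' @param scheme `"s1s2"` (40-minute interval) or `"s1s3"` (1-week).
#' @param scoring `"dls"` (edit-tolerant) or `"exact"` (baseline).
#' @param exclude_repeats Drop adjacent-repeat patterns from the space
#'   (default `TRUE`, as for the identification distance).
#' @param robust Use the tanh-damped distance (default `TRUE`).
#' @param jackknife Compute leave-one-subject-out replicates.
#' @param method Scoring backend, see [score_vector()].
#' @return An object of class `identification_result`: list with
#'   `summary` (tibble: n, auc, se, n_match, n_non_match), `replicates`
#'   (subjects x lengths matrix of leave-one-out AUCs, or `NULL`),
#'   `lengths`, `subjects`, `scheme`, `scoring`.
#' @export
identification_analysis <- function(corpus, lengths = 1:6,
                                    scheme = c("s1s2", "s1s3"),
                                    scoring = c("dls", "exact"),
                                    exclude_repeats = TRUE, robust = TRUE,
                                    jackknife = TRUE, method = "trie") {
  scheme <- match.arg(scheme)
  scoring <- match.arg(scoring)
  stopifnot(inherits(corpus, "rng_corpus"))
  ses <- scheme_sessions(scheme)
  sw <- subjects_with_sessions(corpus, ses)
  if (length(sw$missing))
    warning("skipping subject(s) lacking session ", ses[2L], ": ",
            paste(sw$missing, collapse = ", "))
  subjects <- sw$present
  if (length(subjects) < 3L) stop("need at least 3 subjects with both sessions")
  tb <- corpus$sequences
  keep <- tb$subject_id %in% subjects & tb$session %in% ses
  subj <- tb$subject_id[keep]
  sess <- tb$session[keep]
  digits <- tb$digits[keep]

  k <- length(subjects)
  reps <- if (jackknife) matrix(NA_real_, k, length(lengths),
                                dimnames = list(subjects, lengths)) else NULL
  rows <- vector("list", length(lengths))
  for (li in seq_along(lengths)) {
    n <- lengths[li]
    space <- pattern_space(n, exclude_repeats = exclude_repeats)
    f <- if (scoring == "dls") {
      function(z) score_vector(z, space, method = method)
    } else {
      function(z) exact_count_vector(z, space)
    }
    S <- t(vapply(digits, f, numeric(nrow(space$patterns))))
    auc <- auc_for_subjects(S, subj, sess, ses, subjects, robust)
    se <- NA_real_
    if (jackknife) {
      for (i in seq_len(k)) {
        reps[i, li] <- auc_for_subjects(S, subj, sess, ses, subjects[-i],
                                        robust)
      }
      se <- jackknife_se(reps[, li])
    }
    rows[[li]] <- tibble::tibble(n = n, auc = auc, se = se,
                                 n_match = k, n_non_match = k * (k - 1))
  }
  structure(list(summary = do.call(rbind, rows), replicates = reps,
                 lengths = lengths, subjects = subjects,
                 scheme = scheme, scoring = scoring),
            class = "identification_result")
}

#' @export
print.identification_result <- function(x, ...) {
  cat("<identification_result> scheme = ", x$scheme, ", scoring = ",
      x$scoring, "\n", sep = "")
  print(as.data.frame(x$summary), row.names = FALSE)
  invisible(x)
}

# z and p from a mean and jackknife SE, with degenerate-variance flags
jk_z_test <- function(m, se, tail = c("two", "one")) {
  tail <- match.arg(tail)
  if (se == 0) {
    if (m == 0)
      return(list(z = 0, p = if (tail == "one") 0.5 else 1,
                  flag = "degenerate-zero"))
    return(list(z = sign(m) * Inf, p = 0, flag = "degenerate-certain"))
  }
  z <- m / se
  p <- if (tail == "one") stats::pnorm(z, lower.tail = FALSE)
       else 2 * stats::pnorm(-abs(z))
  list(z = z, p = p, flag = "ok")
}

#' Jackknife trend test of AUC against pattern length
#'
#' Fits, per jackknife replicate, an ordinary least-squares slope of AUC
#' on pattern length; the test statistic is the mean slope divided by
#' its jackknife standard error, referred to the standard normal.
#'
#' @param replicates Replicate matrix (subjects x lengths), e.g.
#'   `identification_analysis(...)$replicates`, or an
#'   `identification_result`.
#' @param lengths Pattern lengths matching the columns (taken from the
#'   result object when one is supplied).
#' @return List with `z`, `p` (two-sided), `slope` (mean replicate
#'   slope), `se` and a `flag` (`"ok"` or a degenerate-variance marker).
#' @export
trend_test <- function(replicates, lengths = NULL) {
  if (inherits(replicates, "identification_result")) {
    lengths <- replicates$lengths
    replicates <- replicates$replicates
  }
  if (is.null(replicates)) stop("no jackknife replicates available")
  stopifnot(is.matrix(replicates), ncol(replicates) == length(lengths))
  if (length(lengths) < 2L) stop("need at least 2 pattern lengths")
  if (nrow(replicates) < 3L) stop("need at least 3 jackknife replicates")
  lc <- lengths - mean(lengths)
  slopes <- as.numeric(replicates %*% lc) / sum(lc^2)
  se <- jackknife_se(slopes)
  out <- jk_z_test(mean(slopes), se, tail = "two")
  out$slope <- mean(slopes)
  out$se <- se
  out
}

#' Jackknife difference test between two replicate sets
#'
#' Tests whether statistic A exceeds statistic B using aligned
#' leave-one-subject-out replicates: per-replicate differences, mean
#' over jackknife SE, standard normal reference.  Swapping the arguments
#' negates `z`.
#'
#' @param rep_a,rep_b Aligned numeric replicate vectors (same left-out
#'   subject per position).
#' @param tail `"one"` (A > B) or `"two"`.
#' @return List with `z`, `p`, `delta` (mean difference), `se`, `flag`.
#' @export
difference_test <- function(rep_a, rep_b, tail = c("one", "two")) {
  tail <- match.arg(tail)
  if (length(rep_a) != length(rep_b))
    stop("replicate sets must be aligned (equal length)")
  if (length(rep_a) < 3L) stop("need at least 3 replicates")
  d <- rep_a - rep_b
  se <- jackknife_se(d)
  out <- jk_z_test(mean(d), se, tail = tail)
  out$delta <- mean(d)
  out$se <- se
  out
}

#' Cross-length grand-average replicates
#'
#' Collapses a replicate matrix to one grand-average AUC per replicate
#' (row mean), for comparing pairing schemes (e.g. 40-minute vs 1-week
#' intervals) with [difference_test()].
#'
#' @param replicates Replicate matrix or `identification_result`.
#' @return Numeric vector, one grand-average value per replicate.
#' @export
grand_average_replicates <- function(replicates) {
  if (inherits(replicates, "identification_result"))
    replicates <- replicates$replicates
  if (is.null(replicates)) stop("no jackknife replicates available")
  rowMeans(replicates)
}
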