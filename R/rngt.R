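# Classical random-generation-task indices and the associated
# sanity-check statistics.

#' Redundancy of digit usage
#'
#' `R = 1 - H / log2(9)` where `H` is the Shannon entropy of the
#' observed digit frequencies.  0 when all nine digits are used equally
#' often, 1 when a single digit is used throughout.  Depends only on the
#' digit histogram, not on order.
#'
#' @param z Digit sequence (integer vector or digit string), digits 1..9.
#' @return A real in `[0, 1]`.
#' @export
redundancy <- function(z) {
  z <- as_digits(z)
  if (length(z) < 1L) stop("sequence must be non-empty")
  p <- tabulate(z, nbins = 9L) / length(z)
  p <- p[p > 0]
  H <- -sum(p * log2(p))
  r <- 1 - H / log2(9)
  min(max(r, 0), 1)  # clip floating error only
}

#' Seriation (ascending runs) index
#'
#' The sequence is segmented into maximal strictly ascending runs
#' (blocks where each digit exceeds its predecessor); the index is the
#' population variance of the run lengths.  A pure count-up sequence is
#' a single run (index 0); alternating between counting and resetting
#' inflates the variance.  Order-sensitive by construction.
#'
#' @param z Digit sequence of length `>= 2`.
#' @return A non-negative real.
#' @examples
#' runs_index(1:9)                  # 0
#' runs_index(c(2, 1, 2, 1, 2, 1))  # runs 1,2,2,1 -> variance 0.25
#' @export
runs_index <- function(z) {
  z <- as_digits(z)
  if (length(z) < 2L) stop("sequence must have length >= 2")
  breaks <- which(diff(z) <= 0)
  len <- diff(c(0L, breaks, length(z)))
  mean((len - mean(len))^2)
}

#' Kolmogorov-Smirnov test against a log-normal distribution
#'
#' One-sample KS test of the log-values against a normal distribution
#' with moment-estimated parameters.  Estimating the parameters from
#' the same data makes the test conservative (the Lilliefors effect);
#' that plain form is deliberately retained as it is the conventional
#' distributional sanity check for these indices.
#'
#' @param values Positive reals, at least 5.
#' @return List with the KS statistic `D` and `p`.
#' @export
ks_lognormal <- function(values) {
  if (any(values <= 0)) stop("all values must be positive")
  if (length(values) < 5L) stop("need at least 5 values")
  lv <- log(values)
  res <- suppressWarnings(stats::ks.test(lv, "pnorm", mean(lv), stats::sd(lv)))
  list(D = unname(res$statistic), p = res$p.value)
}

#' Paired t-test between sessions
#'
#' Classical paired t statistic with two-sided p, for aligned
#' per-subject index vectors.  Zero-variance differences are flagged:
#' identical vectors give `t = 0, p = 1`; a constant non-zero shift is
#' degenerate and reported with an infinite statistic.
#'
#' @param v1,v2 Numeric vectors aligned by subject, length `>= 3`.
#' @return List with `t`, `df`, `p`, `flag`.
#' @export
paired_session_test <- function(v1, v2) {
  if (length(v1) != length(v2)) stop("vectors must be aligned (equal length)")
  n <- length(v1)
  if (n < 3L) stop("need at least 3 paired observations")
  d <- v1 - v2
  if (stats::sd(d) <= 1e-12 * max(1, abs(mean(d)))) {
    if (all(d == 0)) return(list(t = 0, df = n - 1L, p = 1,
                                 flag = "degenerate-zero"))
    return(list(t = sign(mean(d)) * Inf, df = n - 1L, p = 0,
                flag = "degenerate-certain"))
  }
  res <- stats::t.test(v1, v2, paired = TRUE)
  list(t = unname(res$statistic), df = unname(res$parameter),
       p = res$p.value, flag = "ok")
}

#' Per-sequence randomness indices and session summary
#'
#' Computes redundancy and the ascending-runs index for every sequence,
#' summarises each session (mean, SD, KS test against log-normal) and
#' runs paired t-tests between the first two requested sessions on
#' subjects present in both.
#'
#' @param corpus An `rng_corpus`.
#' @param sessions Sessions to summarise (default `c(1, 2)`).
#' @return An object of class `rngt_summary`: list with `records`
#'   (tibble: subject_id, session, redundancy, runs), `session_summary`
#'   (tibble: session, index, mean, sd, ks_D, ks_p) and `paired`
#'   (tibble: index, t, df, p, flag; `NULL` when fewer than 3 subjects
#'   share both sessions).
#' @export
rngt_summary <- function(corpus, sessions = c(1L, 2L)) {
  stopifnot(inherits(corpus, "rng_corpus"))
  tb <- corpus$sequences[corpus$sequences$session %in% sessions, , drop = FALSE]
  if (nrow(tb) == 0L) stop("no sequences in the requested sessions")
  records <- tibble::tibble(
    subject_id = tb$subject_id,
    session = tb$session,
    redundancy = vapply(tb$digits, redundancy, numeric(1)),
    runs = vapply(tb$digits, runs_index, numeric(1))
  )
  summ <- list()
  for (s in sort(unique(records$session))) {
    for (index in c("redundancy", "runs")) {
      v <- records[[index]][records$session == s]
      ks <- if (length(v) >= 5L && all(v > 0)) ks_lognormal(v)
            else list(D = NA_real_, p = NA_real_)
      summ[[length(summ) + 1L]] <- tibble::tibble(
        session = s, index = index, mean = mean(v), sd = stats::sd(v),
        ks_D = ks$D, ks_p = ks$p)
    }
  }
  paired <- NULL
  s12 <- sessions[1:2]
  both <- intersect(records$subject_id[records$session == s12[1L]],
                    records$subject_id[records$session == s12[2L]])
  if (length(sessions) >= 2L && length(both) >= 3L) {
    rows <- list()
    for (index in c("redundancy", "runs")) {
      v1 <- records[[index]][records$session == s12[1L]][
        match(both, records$subject_id[records$session == s12[1L]])]
      v2 <- records[[index]][records$session == s12[2L]][
        match(both, records$subject_id[records$session == s12[2L]])]
      pt <- paired_session_test(v1, v2)
      rows[[index]] <- tibble::tibble(index = index, t = pt$t, df = pt$df,
                                      p = pt$p, flag = pt$flag)
    }
    paired <- do.call(rbind, rows)
  }
  structure(list(records = records,
                 session_summary = do.call(rbind, summ),
                 paired = paired),
            class = "rngt_summary")
}

#' @export
print.rngt_summary <- function(x, ...) {
  cat("<rngt_summary>\n")
  print(as.data.frame(x$session_summary), row.names = FALSE)
  if (!is.null(x$paired)) {
    cat("paired session test:\n")
    print(as.data.frame(x$paired), row.names = FALSE)
  }
  invisible(x)
}
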