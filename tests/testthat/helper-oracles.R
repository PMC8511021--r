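# Independent reference implementations used to validate the package's
# computations.  These are deliberately written from the definitions,
# not from the package's code paths.

# Optimal-string-alignment Damerau-Levenshtein distance by memoized
# recursion over suffix positions, straight from the recurrence:
# d(i, j) = min(deletion, insertion, substitution, and -- when the last
# two characters cross over -- one transposition of the adjacent pair).
osa_oracle <- function(a, b) {
  na <- length(a)
  nb <- length(b)
  memo <- matrix(NA_integer_, na + 1L, nb + 1L)
  rec <- function(i, j) {
    if (!is.na(memo[i + 1L, j + 1L])) return(memo[i + 1L, j + 1L])
    v <- if (i == 0L) j else if (j == 0L) i else {
      cost <- if (a[i] == b[j]) 0L else 1L
      best <- min(rec(i - 1L, j) + 1L, rec(i, j - 1L) + 1L,
                  rec(i - 1L, j - 1L) + cost)
      if (i > 1L && j > 1L && a[i] == b[j - 1L] && a[i - 1L] == b[j]) {
        best <- min(best, rec(i - 2L, j - 2L) + 1L)
      }
      best
    }
    memo[i + 1L, j + 1L] <<- as.integer(v)
    memo[i + 1L, j + 1L]
  }
  rec(na, nb)
}

# all digit strings over `alphabet` with length 0..maxlen, as a list of
# integer vectors
all_digit_strings <- function(alphabet, maxlen) {
  out <- list(integer(0))
  level <- list(integer(0))
  for (k in seq_len(maxlen)) {
    level <- unlist(lapply(level, function(p)
      lapply(alphabet, function(d) c(p, d))), recursive = FALSE)
    out <- c(out, level)
  }
  out
}

# AUC by exhaustive pair counting: P(match < non-match) + 1/2 P(equal)
auc_bruteforce <- function(distance, label) {
  dm <- distance[label == "match"]
  dn <- distance[label == "non_match"]
  total <- 0
  for (x in dm) {
    total <- total + sum(x < dn) + 0.5 * sum(x == dn)
  }
  total / (length(dm) * length(dn))
}

# naive prevalence score of one pattern, written independently of the
# package: explicit window loop with the oracle distance
pattern_score_oracle <- function(m, z) {
  L <- length(z)
  n <- length(m)
  s <- 0
  for (start in 1:(L - n + 1)) {
    s <- s + 1 / (osa_oracle(m, z[start:(start + n - 1)]) + 1)
  }
  s / L
}
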