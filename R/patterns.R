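# Pattern-space enumeration.
#
# A pattern is an n-tuple of digits 1..9 (n in 1..6).  The full space
# has 9^n patterns; with adjacent-repeat exclusion (no two neighbouring
# digits equal) it has 9 * 8^(n-1).  Enumeration is lexicographic and
# deterministic, and downstream score vectors are aligned to it.

#' Enumerate the space of digit patterns of length n
#'
#' @param n Pattern length, an integer in 1..6.
#' @param exclude_repeats If `TRUE`, drop every pattern containing a
#'   pair of adjacent equal digits (e.g. "115", "511").  The repeat
#'   exclusion applies to the pattern space only, never to the data.
#' @return An object of class `pattern_space` with components `n`,
#'   `exclude_repeats`, `patterns` (integer matrix, one row per pattern,
#'   lexicographic order), `labels` (concatenated digit strings) and
#'   `full_index` (row index of each pattern within the full 9^n
#'   enumeration).
#' @examples
#' pattern_space(1)$labels
#' nrow(pattern_space(3, exclude_repeats = TRUE)$patterns)  # 9 * 8 * 8
#' @export
pattern_space <- function(n, exclude_repeats = FALSE) {
  if (!is.numeric(n) || length(n) != 1L || is.na(n) || n != round(n) ||
      n < 1 || n > 6)
    stop("pattern length n must be an integer in 1..6")
  n <- as.integer(n)
  P <- 9L^n
  idx <- 0:(P - 1)
  mat <- matrix(0L, P, n)
  for (k in n:1) {
    mat[, k] <- as.integer(idx %% 9 + 1)
    idx <- idx %/% 9
  }
  full_index <- seq_len(P)
  if (exclude_repeats && n > 1L) {
    keep <- rowSums(mat[, -1L, drop = FALSE] == mat[, -n, drop = FALSE]) == 0L
    mat <- mat[keep, , drop = FALSE]
    full_index <- full_index[keep]
  }
  labels <- do.call(paste0, lapply(seq_len(n), function(k) mat[, k]))
  structure(list(n = n, exclude_repeats = isTRUE(exclude_repeats),
                 patterns = mat, labels = labels, full_index = full_index),
            class = "pattern_space")
}

#' @export
print.pattern_space <- function(x, ...) {
  cat("<pattern_space> n = ", x$n, ", ", nrow(x$patterns), " patterns",
      if (x$exclude_repeats) " (adjacent repeats excluded)", "\n", sep = "")
  invisible(x)
}

# lexicographic index of a digit tuple within the full 9^n space
full_space_index <- function(digits) {
  n <- length(digits)
  sum((digits - 1) * 9^((n - 1):0)) + 1L
}
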