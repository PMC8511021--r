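# Corpus representation, TSV I/O and subject-level exclusion screens.
#
# A corpus holds one digit sequence per (subject, session).  Digits are
# restricted to 1..9 (the task instructs participants to draw from that
# range); response onsets in seconds are optional and only used by the
# pause screen.  Sequences are stored 0-indexed internally like any R
# vector; user-facing position reports are 1-based.

new_corpus <- function(sequences, exclusion_log = NULL) {
  exclusion_log <- exclusion_log %||%
    tibble::tibble(subject_id = character(), reason = character(),
                   statistic = numeric())
  structure(list(sequences = sequences, exclusion_log = exclusion_log),
            class = "rng_corpus")
}

#' Construct a single subject-session digit sequence
#'
#' @param subject_id Subject identifier (string).
#' @param session Session number, an integer `>= 1`.
#' @param digits Integer vector of digits, each in 1..9.
#' @param onsets Optional numeric vector of response onsets in seconds,
#'   same length as `digits`, strictly increasing.
#' @return A list of class `digit_sequence`.
#' @export
digit_sequence <- function(subject_id, session, digits, onsets = NULL) {
  stopifnot(is.character(subject_id), length(subject_id) == 1L)
  session <- as.integer(session)
  if (is.na(session) || session < 1L) stop("session must be an integer >= 1")
  digits <- as_digits(digits)
  if (length(digits) < 1L) stop("sequence must contain at least one digit")
  if (any(digits < 1L)) stop("digits must lie in 1..9")
  if (!is.null(onsets)) {
    onsets <- as.numeric(onsets)
    if (length(onsets) != length(digits))
      stop("onsets must have the same length as digits")
    if (any(diff(onsets) <= 0)) stop("onsets must be strictly increasing")
  }
  structure(list(subject_id = subject_id, session = session,
                 digits = digits, onsets = onsets),
            class = "digit_sequence")
}

#' Build a corpus from digit sequences
#'
#' @param sequences A list of [digit_sequence()] objects.
#' @return An object of class `rng_corpus` with components `sequences`
#'   (a tibble with list-columns `digits` and `onsets`) and
#'   `exclusion_log`.
#' @export
as_corpus <- function(sequences) {
  stopifnot(is.list(sequences), length(sequences) >= 1L)
  tb <- tibble::tibble(
    subject_id = vapply(sequences, function(s) s$subject_id, character(1)),
    session = vapply(sequences, function(s) s$session, integer(1)),
    digits = lapply(sequences, function(s) s$digits),
    onsets = lapply(sequences, function(s) s$onsets)
  )
  key <- paste(tb$subject_id, tb$session)
  if (anyDuplicated(key))
    stop("duplicate (subject_id, session): ",
         paste(unique(key[duplicated(key)]), collapse = ", "))
  new_corpus(tb)
}

#' Read a corpus from a TSV file
#'
#' Expects a header with columns `subject_id`, `session`, `sequence`
#' (contiguous characters '1'-'9', no separators) and optionally
#' `onsets` (comma-separated decimal seconds).  Rows containing any
#' character outside '1'..'9' in `sequence` are reported with their row
#' number and the read fails.
#'
#' @param path Path to a tab-separated file.
#' @return An `rng_corpus`.
#' @export
read_corpus <- function(path) {
  if (!file.exists(path)) stop("corpus file not found: ", path)
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character", check.names = FALSE,
                           quote = "", comment.char = "")
  need <- c("subject_id", "session", "sequence")
  if (!all(need %in% names(raw)))
    stop("malformed header: expected columns ", paste(need, collapse = ", "))
  n <- nrow(raw)
  if (n == 0L) stop("corpus file contains no rows")
  errs <- character()
  digits <- vector("list", n)
  onsets <- vector("list", n)
  session <- suppressWarnings(as.integer(raw$session))
  has_onsets <- "onsets" %in% names(raw)
  for (i in seq_len(n)) {
    if (is.na(session[i]) || session[i] < 1L) {
      errs <- c(errs, sprintf("row %d: invalid session '%s'", i, raw$session[i]))
      next
    }
    ch <- strsplit(raw$sequence[i], "", fixed = TRUE)[[1]]
    bad <- setdiff(unique(ch), as.character(1:9))
    if (length(ch) == 0L || length(bad)) {
      errs <- c(errs, sprintf(
        "row %d (%s): invalid character(s) %s in sequence", i,
        raw$subject_id[i],
        if (length(bad)) paste(sQuote(bad), collapse = ", ") else "<empty>"))
      next
    }
    digits[[i]] <- as.integer(ch)
    if (has_onsets && !is.na(raw$onsets[i]) && nzchar(raw$onsets[i])) {
      on <- suppressWarnings(as.numeric(strsplit(raw$onsets[i], ",", fixed = TRUE)[[1]]))
      if (anyNA(on) || length(on) != length(digits[[i]]) || any(diff(on) <= 0)) {
        errs <- c(errs, sprintf("row %d (%s): malformed onsets", i, raw$subject_id[i]))
        next
      }
      onsets[[i]] <- on
    }
  }
  if (length(errs))
    stop("invalid corpus rows:\n  ", paste(errs, collapse = "\n  "))
  key <- paste(raw$subject_id, session)
  if (anyDuplicated(key))
    stop("duplicate (subject_id, session): ",
         paste(unique(key[duplicated(key)]), collapse = ", "))
  tb <- tibble::tibble(subject_id = raw$subject_id, session = session,
                       digits = digits, onsets = onsets)
  new_corpus(tb)
}

#' Write a corpus to a TSV file
#'
#' Inverse of [read_corpus()]: `read_corpus(write_corpus(x, f))`
#' reproduces `x` up to the written onset precision.
#'
#' @param corpus An `rng_corpus`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_corpus <- function(corpus, path) {
  stopifnot(inherits(corpus, "rng_corpus"))
  tb <- corpus$sequences
  any_onsets <- any(!vapply(tb$onsets, is.null, logical(1)))
  df <- data.frame(
    subject_id = tb$subject_id,
    session = tb$session,
    sequence = vapply(tb$digits, paste0, character(1), collapse = ""),
    stringsAsFactors = FALSE
  )
  if (any_onsets) {
    df$onsets <- vapply(tb$onsets, function(o) {
      if (is.null(o)) "" else paste(format(o, digits = 15, trim = TRUE,
                                           scientific = FALSE), collapse = ",")
    }, character(1))
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, eol = "\n", fileEncoding = "UTF-8")
  invisible(path)
}

#' Apply the cohort exclusion screens
#'
#' Two screens, mirroring common practice in random-generation studies:
#' (a) *uniformity*: for each subject the chi-square statistic of the
#' pooled digit histogram against the uniform distribution over nine
#' digits is computed; subjects whose statistic lies more than
#' `sigma_threshold` standard deviations above the cohort mean are
#' removed; (b) *pause*: subjects with any inter-onset gap longer than
#' `max_pause` seconds are removed.  Sequences without onsets pass the
#' pause screen.  Removals are recorded in the `exclusion_log`.
#'
#' @param corpus An `rng_corpus`.
#' @param sigma_threshold Positive z-score cutoff for the uniformity
#'   screen (default 3.5).
#' @param max_pause Maximum tolerated inter-response gap in seconds
#'   (default 15).
#' @param per Whether the uniformity statistic is pooled per subject
#'   (default, subjects are the exclusion unit) or computed per
#'   sequence.
#' @return The filtered `rng_corpus`; excluded subjects appear in
#'   `$exclusion_log` with reasons `"uniformity"` or `"pause"`.
#' @export
filter_subjects <- function(corpus, sigma_threshold = 3.5, max_pause = 15,
                            per = c("subject", "sequence")) {
  per <- match.arg(per)
  stopifnot(inherits(corpus, "rng_corpus"))
  tb <- corpus$sequences
  if (nrow(tb) == 0L) stop("empty corpus")
  if (!is.numeric(sigma_threshold) || sigma_threshold <= 0)
    stop("sigma_threshold must be positive")

  unit <- if (per == "subject") tb$subject_id else paste(tb$subject_id, tb$session)
  units <- unique(unit)
  chisq <- vapply(units, function(u) {
    counts <- tabulate(unlist(tb$digits[unit == u]), nbins = 9L)
    e <- sum(counts) / 9
    sum((counts - e)^2 / e)
  }, numeric(1))
  z <- if (length(units) > 1L && stats::sd(chisq) > 0)
    (chisq - mean(chisq)) / stats::sd(chisq) else rep(0, length(units))
  bad_units <- units[z > sigma_threshold]
  unif_subjects <- if (per == "subject") bad_units else
    unique(tb$subject_id[unit %in% bad_units])
  unif_stat <- if (per == "subject") z[match(unif_subjects, units)] else
    vapply(unif_subjects,
           function(s) max(z[units %in% unit[tb$subject_id == s]]), numeric(1))

  long_pause <- vapply(tb$onsets, function(o) {
    !is.null(o) && length(o) > 1L && any(diff(o) > max_pause)
  }, logical(1))
  pause_subjects <- setdiff(unique(tb$subject_id[long_pause]), unif_subjects)
  pause_stat <- vapply(pause_subjects, function(s) {
    max(vapply(tb$onsets[tb$subject_id == s], function(o)
      if (is.null(o) || length(o) < 2L) 0 else max(diff(o)), numeric(1)))
  }, numeric(1))

  log_new <- tibble::tibble(
    subject_id = c(unif_subjects, pause_subjects),
    reason = c(rep("uniformity", length(unif_subjects)),
               rep("pause", length(pause_subjects))),
    statistic = c(as.numeric(unif_stat), as.numeric(pause_stat))
  )
  drop <- tb$subject_id %in% log_new$subject_id
  new_corpus(tb[!drop, , drop = FALSE],
             rbind(corpus$exclusion_log, log_new))
}

#' @export
print.rng_corpus <- function(x, ...) {
  tb <- x$sequences
  cat("<rng_corpus> ", nrow(tb), " sequence(s), ",
      length(unique(tb$subject_id)), " subject(s), sessions: ",
      paste(sort(unique(tb$session)), collapse = ", "), "\n", sep = "")
  if (nrow(x$exclusion_log))
    cat("  excluded subjects: ", nrow(x$exclusion_log), " (",
        paste(unique(x$exclusion_log$reason), collapse = ", "), ")\n", sep = "")
  invisible(x)
}

# subjects present in every session of `sessions`
subjects_with_sessions <- function(corpus, sessions) {
  tb <- corpus$sequences
  subj <- unique(tb$subject_id)
  ok <- vapply(subj, function(s)
    all(sessions %in% tb$session[tb$subject_id == s]), logical(1))
  list(present = subj[ok], missing = subj[!ok])
}
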