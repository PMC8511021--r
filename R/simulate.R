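# Synthetic human-RNG cohort generator.
#
# The generator realizes, as simply as possible, the three mechanisms
# the analysis assumes in human pseudorandom sequences: (1) reuse of a
# small set of preferred patterns, obscured by occasional single edits
# (insertion, deletion, substitution, adjacent transposition); (2) a
# baseline emission process with repetition suppression, a mild
# counting (seriation) bias, and inhibition of specific patterns; and
# (3) subject-specific preference/inhibition profiles that are stable
# across sessions up to a mild drift.  Every sequence is fully
# determined by (master_seed, subject index, session): streams are
# derived by a counter-based scheme, so adding subjects or sessions
# never perturbs existing sequences.

#' Specify a synthetic cohort
#'
#' Defaults emulate the acquisition design of a typical random-number-
#' generation study: 115 subjects producing two 300-digit sequences
#' from 1..9, with an optional third session for a subset.
#'
#' @param n_subjects Number of subjects (default 115).
#' @param sessions Number of sessions per subject (default 2).
#' @param third_session_subjects How many of the first subjects also
#'   produce a session-3 sequence (default 0); ignored when `sessions
#'   >= 3`.
#' @param sequence_length Digits per sequence (default 300).
#' @param kappa Individuality strength `>= 0`: scales the weight of
#'   subject-specific preferred patterns and the suppression of
#'   subject-specific inhibited patterns.  `kappa = 0` makes all
#'   subjects share one profile (exchangeable cohort).  Default 1.
#' @param session_drift Log-normal SD of the per-session perturbation
#'   of preference weights (default 0.1).
#' @param template_rate Probability of starting a preferred-pattern
#'   template at a free position (default 0.15; since a template emits
#'   its whole 3-4 digit instance, roughly a third of all digits then
#'   stem from templates).
#' @param edit_noise Probability that a template instance receives one
#'   random edit before emission (default 0.15).
#' @param repetition_suppression Down-weighting of an immediate digit
#'   repeat in the baseline process, in `[0, 1]`; 1 forbids repeats
#'   (default 0.8).
#' @param seriation_bias Up-weighting of `previous + 1` in the baseline
#'   process (default 0.15).
#' @param n_preferred,n_inhibited Number of subject-specific preferred /
#'   inhibited patterns (default 4 each).
#' @param n_shared_preferred,n_shared_inhibited Number of cohort-shared
#'   preferred / inhibited patterns (default 2 each).
#' @param preferred_weight Base template-selection weight: shared
#'   preferred patterns get half of it, subject-specific patterns
#'   `kappa * preferred_weight` (default 1).
#' @param suppression Resampling probability when an emission would
#'   complete a shared inhibited pattern; subject-specific inhibitions
#'   use `min(1, kappa * suppression)` (default 0.9).
#' @param familiar_boost Template-selection weight given to patterns
#'   extracted from a subject's familiar numbers (default 0, i.e. the
#'   familiar numbers leave no trace in the sequences).
#' @param master_seed Integer master seed (default 1).
#' @return A validated list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 115L, sessions = 2L,
                        third_session_subjects = 0L,
                        sequence_length = 300L, kappa = 1,
                        session_drift = 0.1, template_rate = 0.15,
                        edit_noise = 0.15, repetition_suppression = 0.8,
                        seriation_bias = 0.15, n_preferred = 4L,
                        n_inhibited = 4L, n_shared_preferred = 2L,
                        n_shared_inhibited = 2L, preferred_weight = 1,
                        suppression = 0.9, familiar_boost = 0,
                        master_seed = 1L) {
  spec <- list(n_subjects = as.integer(n_subjects),
               sessions = as.integer(sessions),
               third_session_subjects = as.integer(third_session_subjects),
               sequence_length = as.integer(sequence_length),
               kappa = kappa, session_drift = session_drift,
               template_rate = template_rate, edit_noise = edit_noise,
               repetition_suppression = repetition_suppression,
               seriation_bias = seriation_bias,
               n_preferred = as.integer(n_preferred),
               n_inhibited = as.integer(n_inhibited),
               n_shared_preferred = as.integer(n_shared_preferred),
               n_shared_inhibited = as.integer(n_shared_inhibited),
               preferred_weight = preferred_weight,
               suppression = suppression, familiar_boost = familiar_boost,
               master_seed = as.integer(master_seed))
  with(spec, {
    stopifnot(n_subjects >= 1L, sessions >= 1L, sequence_length >= 10L,
              kappa >= 0, session_drift >= 0,
              template_rate >= 0, template_rate <= 1,
              edit_noise >= 0, edit_noise <= 1,
              repetition_suppression >= 0, repetition_suppression <= 1,
              seriation_bias >= 0, suppression >= 0, suppression <= 1,
              familiar_boost >= 0, third_session_subjects <= n_subjects)
  })
  structure(spec, class = "cohort_spec")
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat("<cohort_spec> ", x$n_subjects, " subject(s) x ", x$sessions,
      " session(s) x ", x$sequence_length, " digits, kappa = ", x$kappa,
      ", seed = ", x$master_seed, "\n", sep = "")
  invisible(x)
}

# one random repeat-free pattern of the given length (digits 1..9)
random_pattern <- function(len) {
  p <- integer(len)
  p[1L] <- sample.int(9L, 1L)
  for (k in seq_len(len - 1L)) {
    p[k + 1L] <- sample(setdiff(1:9, p[k]), 1L)
  }
  p
}

# draw `count` repeat-free patterns (lengths 3..4) avoiding `taken` labels
draw_patterns <- function(count, taken = character(0)) {
  out <- vector("list", count)
  labs <- character(count)
  k <- 0L
  while (k < count) {
    p <- random_pattern(sample(3:4, 1L))
    lab <- paste0(p, collapse = "")
    if (lab %in% c(taken, labs[seq_len(k)])) next
    k <- k + 1L
    out[[k]] <- p
    labs[k] <- lab
  }
  list(patterns = out, labels = labs)
}

#' Sample a subject's generation profile
#'
#' Deterministic given `(master_seed, index)`.  The profile combines a
#' cohort-shared component (drawn once from the master seed) with a
#' subject-specific component whose preference weights and inhibition
#' strengths scale with `kappa`; at `kappa = 0` the shared base profile
#' is returned unchanged for every subject.
#'
#' @param spec A [cohort_spec()].
#' @param index Subject index (1-based).
#' @return A list of class `subject_profile` with `subject_id`,
#'   `preferred` (list of patterns), `pref_weights`, `inhibited` (list
#'   of patterns), `inh_suppression`, the baseline rates, and `index`.
#' @export
sample_profile <- function(spec, index) {
  stopifnot(inherits(spec, "cohort_spec"), index >= 1L)
  base <- with_local_seed(substream_seed(spec$master_seed, 7L, 0L), {
    pref <- draw_patterns(spec$n_shared_preferred)
    inh <- draw_patterns(spec$n_shared_inhibited, taken = pref$labels)
    list(pref = pref, inh = inh)
  })
  # shared preferences carry half the base weight: universal tendencies
  # exist but are weak relative to idiosyncratic ones, and a strong
  # shared component would skew the cohort-level digit marginals that
  # the task instructions keep near uniform
  preferred <- base$pref$patterns
  pref_weights <- rep(0.5 * spec$preferred_weight, length(preferred))
  inhibited <- base$inh$patterns
  inh_supp <- rep(spec$suppression, length(inhibited))
  if (spec$kappa > 0) {
    taken <- c(base$pref$labels, base$inh$labels)
    own <- with_local_seed(substream_seed(spec$master_seed, 7L, index), {
      pref <- draw_patterns(spec$n_preferred, taken = taken)
      inh <- draw_patterns(spec$n_inhibited, taken = c(taken, pref$labels))
      list(pref = pref, inh = inh)
    })
    preferred <- c(preferred, own$pref$patterns)
    pref_weights <- c(pref_weights,
                      rep(spec$kappa * spec$preferred_weight,
                          length(own$pref$patterns)))
    inhibited <- c(inhibited, own$inh$patterns)
    inh_supp <- c(inh_supp,
                  rep(min(1, spec$kappa * spec$suppression),
                      length(own$inh$patterns)))
  }
  structure(list(subject_id = sprintf("S%03d", index), index = as.integer(index),
                 preferred = preferred, pref_weights = pref_weights,
                 inhibited = inhibited, inh_suppression = inh_supp,
                 template_rate = spec$template_rate,
                 edit_noise = spec$edit_noise,
                 repetition_suppression = spec$repetition_suppression,
                 seriation_bias = spec$seriation_bias,
                 familiar = NULL),
            class = "subject_profile")
}

# apply one random edit (insertion / deletion / substitution / adjacent
# transposition) to a digit tuple
apply_random_edit <- function(p) {
  ops <- c("sub", "ins", if (length(p) > 1L) c("del", "swap"))
  op <- sample(ops, 1L)
  n <- length(p)
  switch(op,
    sub = { i <- sample.int(n, 1L); p[i] <- sample.int(9L, 1L); p },
    ins = { i <- sample.int(n + 1L, 1L)
            append(p, sample.int(9L, 1L), after = i - 1L) },
    del = p[-sample.int(n, 1L)],
    swap = { i <- sample.int(n - 1L, 1L); p[c(i, i + 1L)] <- p[c(i + 1L, i)]; p })
}

#' Generate one synthetic subject-session sequence
#'
#' At each position: if a template (a preferred pattern instance,
#' possibly carrying one random edit) is in progress, its next digit is
#' emitted; otherwise a new template starts with probability
#' `template_rate`, or a digit is drawn from the baseline distribution
#' over 1..9, which down-weights repeating the previous digit by
#' `1 - repetition_suppression`, up-weights `previous + 1` by
#' `seriation_bias`, and resamples (with probability equal to the
#' inhibition strength) any digit that would complete an inhibited
#' pattern.  Session drift perturbs the preference weights per session.
#'
#' @param profile A [sample_profile()].
#' @param spec The [cohort_spec()].
#' @param session Session number.
#' @return A [digit_sequence()] of length `spec$sequence_length`.
#' @export
generate_sequence <- function(profile, spec, session) {
  stopifnot(inherits(profile, "subject_profile"), inherits(spec, "cohort_spec"))
  L <- spec$sequence_length
  with_local_seed(substream_seed(spec$master_seed, 11L, profile$index, session), {
    w <- profile$pref_weights
    if (spec$session_drift > 0 && length(w)) {
      w <- w * exp(spec$session_drift * stats::rnorm(length(w)))
    }
    have_templates <- length(profile$preferred) > 0L && sum(w) > 0
    max_inh <- if (length(profile$inhibited))
      max(vapply(profile$inhibited, length, integer(1))) else 0L
    z <- integer(L)
    pos <- 0L
    buffer <- integer(0)
    while (pos < L) {
      if (length(buffer)) {
        d <- buffer[1L]
        buffer <- buffer[-1L]
      } else if (have_templates && stats::runif(1) < profile$template_rate) {
        ti <- sample.int(length(profile$preferred), 1L, prob = w)
        inst <- profile$preferred[[ti]]
        if (profile$edit_noise > 0 && stats::runif(1) < profile$edit_noise) {
          inst <- apply_random_edit(inst)
        }
        d <- inst[1L]
        buffer <- inst[-1L]
      } else {
        prev <- if (pos > 0L) z[pos] else 0L
        base_w <- rep(1, 9)
        if (prev > 0L) {
          base_w[prev] <- base_w[prev] * (1 - profile$repetition_suppression)
          nxt <- prev %% 9L + 1L
          base_w[nxt] <- base_w[nxt] * (1 + profile$seriation_bias)
        }
        for (try in 1:20) {
          d <- sample.int(9L, 1L, prob = base_w)
          supp <- 0
          if (max_inh > 1L && pos > 0L) {
            for (q in seq_along(profile$inhibited)) {
              ip <- profile$inhibited[[q]]
              k <- length(ip)
              if (pos >= k - 1L && d == ip[k] &&
                  all(z[(pos - k + 2L):pos] == ip[-k])) {
                supp <- max(supp, profile$inh_suppression[q])
              }
            }
          }
          if (supp == 0 || stats::runif(1) >= supp) break
        }
      }
      pos <- pos + 1L
      z[pos] <- d
    }
    digit_sequence(profile$subject_id, session, z)
  })
}

#' Generate a full synthetic cohort
#'
#' @param spec A [cohort_spec()].
#' @param familiar Optional familiar-number tibble (`subject_id`,
#'   `kind`, `digits`); when supplied and `spec$familiar_boost > 0`,
#'   each subject's familiar length-3 patterns are added to her
#'   preferred set with weight `familiar_boost`, planting an
#'   over-representation that [familiar_pattern_test()] should detect.
#' @param path Optional path; when given the corpus is also written as
#'   TSV via [write_corpus()].
#' @return An `rng_corpus`, reproducible from `spec$master_seed`.
#' @export
generate_corpus <- function(spec, familiar = NULL, path = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  seqs <- list()
  for (i in seq_len(spec$n_subjects)) {
    prof <- sample_profile(spec, i)
    if (!is.null(familiar) && spec$familiar_boost > 0) {
      rows <- familiar$subject_id == prof$subject_id
      pats <- unique(unlist(lapply(familiar$digits[rows],
                                   extract_familiar_patterns)))
      if (length(pats)) {
        prof$preferred <- c(prof$preferred,
                            lapply(pats, function(s) as_digits(s)))
        prof$pref_weights <- c(prof$pref_weights,
                               rep(spec$familiar_boost, length(pats)))
      }
    }
    ses <- seq_len(spec$sessions)
    if (spec$sessions < 3L && i <= spec$third_session_subjects)
      ses <- c(ses, 3L)
    for (s in ses) {
      seqs[[length(seqs) + 1L]] <- generate_sequence(prof, spec, s)
    }
  }
  corpus <- as_corpus(seqs)
  if (!is.null(path)) write_corpus(corpus, path)
  corpus
}

#' Generate a synthetic familiar-number table
#'
#' Birthdates (DDMMYYYY), phone numbers (10 digits) and postal codes
#' (5 digits), deterministic given the spec's master seed.  Digits may
#' include 0, as in real familiar numbers.
#'
#' @param spec A [cohort_spec()].
#' @param kinds Which kinds to generate (default all three).
#' @param n_phone_postal How many subjects (from the first) get phone
#'   and postal entries (default all); birthdates are generated for
#'   everyone.
#' @return Tibble with `subject_id`, `kind`, `digits`.
#' @export
generate_familiar <- function(spec, kinds = c("birthdate", "phone", "postal"),
                              n_phone_postal = spec$n_subjects) {
  stopifnot(inherits(spec, "cohort_spec"))
  rows <- list()
  for (i in seq_len(spec$n_subjects)) {
    sid <- sprintf("S%03d", i)
    with_local_seed(substream_seed(spec$master_seed, 13L, i), {
      if ("birthdate" %in% kinds) {
        rows[[length(rows) + 1L]] <- tibble::tibble(
          subject_id = sid, kind = "birthdate",
          digits = sprintf("%02d%02d%04d", sample.int(28L, 1L),
                           sample.int(12L, 1L), sample(1950:2000, 1L)))
      }
      if (i <= n_phone_postal) {
        if ("phone" %in% kinds) {
          rows[[length(rows) + 1L]] <- tibble::tibble(
            subject_id = sid, kind = "phone",
            digits = paste(sample(0:9, 10L, replace = TRUE), collapse = ""))
        }
        if ("postal" %in% kinds) {
          rows[[length(rows) + 1L]] <- tibble::tibble(
            subject_id = sid, kind = "postal",
            digits = paste(sample(0:9, 5L, replace = TRUE), collapse = ""))
        }
      }
    })
  }
  do.call(rbind, rows)
}
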