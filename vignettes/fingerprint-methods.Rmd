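---
title: "Quantifying cognitive fingerprints in human random number generation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying cognitive fingerprints in human random number generation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(rngprint)
```

## The problem

When people are asked to call out "random" digits from 1 to 9 at a steady
pace, they cannot produce mathematical randomness.  They cycle response
alternatives, avoid repeating themselves, count in small ascending steps —
and, more interestingly, they reuse a personal repertoire of short digit
patterns, disguising the reuse with small changes: a digit inserted,
dropped, substituted, or two neighbours swapped.  If that repertoire is
stable within a person and different between people, two sequences can be
attributed to the same author from the digits alone.  `rngprint`
implements that attribution pipeline and the analyses around it.

## The prevalence score

The unit of analysis is the *pattern*: an n-tuple of digits, with n from
1 to 6 (effects beyond length 6 are not expected in 300-digit sequences).
The prevalence of pattern $m$ in sequence $z$ of length $L$ is

$$
s(m, z) \;=\; \frac{1}{L}\sum_{t=1}^{L-n+1} \frac{1}{d(m,\; z_{t:t+n-1}) + 1},
$$

where $d$ is the Damerau–Levenshtein edit distance between the pattern
and the window starting at position $t$: the minimum number of unit-cost
insertions, deletions, substitutions and adjacent transpositions turning
one into the other.  An exact occurrence contributes 1, a one-edit
variation 1/2, and so on; dividing by $L$ normalises across sequence
lengths.  Only positions where a full n-length window fits are scored:
comparing a pattern against a truncated trailing fragment would conflate
truncation with genuine edits.  The denominator is the sequence length
rather than the window count $L-n+1$; the difference is a constant factor
per pattern length and is absorbed by the standardization below.

Two deliberate choices about the distance:

* **Optimal string alignment (OSA).**  "Adjacent transposition" admits
  two classical variants.  We use the OSA restriction (no substring is
  edited again after a transposition), which is the standard single-table
  dynamic program.  For patterns of length at most 6 the difference from
  the unrestricted distance is immaterial; the OSA variant is also why
  `dl_distance("31", "123")` is 3 rather than 2, and why the triangle
  inequality can fail in rare corner cases (documented and quantified in
  the test suite — symmetry and identity hold universally).
* **Unit costs.**  Only counts of operations matter; no digit-similarity
  weighting.

The full space of length-n patterns has $9^n$ elements.  For the
identification distance we *exclude adjacent-repeat patterns* ("11",
"555"): people are inconsistent in how they use such rare patterns, and
their inclusion adds noise.  The exclusion removes patterns from the
vector space only — the data are never modified — leaving
$9 \cdot 8^{\,n-1}$ patterns.  The individuality analysis (below)
deliberately keeps the full space: universally avoided patterns are part
of what it measures.

`score_vector()` computes all $9^n$ scores with a shared-prefix dynamic
program over the 9-ary pattern trie (implemented in C++), which agrees
with the naive per-pattern loop to within $10^{-12}$ (an explicit test);
`exact_count_vector()` is the edit-intolerant baseline: windows exactly
equal to the pattern, divided by $L$.  For length-1 patterns a window is
either a hit (term 1) or one substitution away (term 1/2), so the score
is exactly $\tfrac12 + \tfrac12 c_i$ in the exact frequency $c_i$ — the
two representations are affinely equivalent at $n = 1$ and all
rank-based results coincide there by construction.

## From scores to a sequence distance

Raw scores are standardized per pattern (column) over all sequences
entering an analysis — both sessions pooled, since a pair classifier
should treat its two inputs symmetrically — using the population SD;
zero-variance columns are set to zero.  The distance between two
standardized score vectors is

$$
d_n(z_1, z_2) \;=\; \sqrt{\textstyle\sum_{i=1}^{9^n}
  \tanh^2\!\big(s_i(z_1) - s_i(z_2)\big)},
$$

the Euclidean norm of tanh-damped pattern-wise differences.  The damping
bounds each coordinate's contribution below 1, so a handful of strategy
changes between sessions cannot dominate a 729-dimensional distance; the
plain Euclidean form is available via `robust = FALSE`.

## Identification

Pairs of sequences recorded in different sessions are labelled *match*
(same subject) or *non-match* (different subjects); a pair is classified
as a match when its distance falls below a threshold.  Sweeping the
threshold yields the ROC; the area under it is computed with the rank
(Mann–Whitney) statistic — the probability that a random match pair is
closer than a random non-match pair, ties counted 1/2 — which is exact,
grid-free, and equals the trapezoidal ROC area (asserted to $10^{-12}$).
Non-match pairs are restricted to cross-session pairs so that match and
non-match distances share the same session structure and practice or
fatigue effects cancel.

Uncertainty comes from a leave-one-*subject*-out jackknife: pairs
sharing a subject are dependent, so the subject is the exchangeable
unit.  Each replicate recomputes the entire downstream pipeline —
standardization, pairing, AUC — on the remaining subjects;
$SE = \sqrt{\tfrac{n-1}{n}\sum_i (\theta_{(i)} - \bar\theta)^2}$.  The
machinery is validated against the closed-form jackknife SE of the
sample mean.  Two derived tests use the replicate tables, both referred
to the standard normal (as is conventional for jackknife z statistics):

* `trend_test()` — per-replicate OLS slope of AUC on pattern length,
  mean slope over its jackknife SE;
* `difference_test()` — per-replicate differences between two aligned
  analyses (e.g. edit-tolerant vs exact baseline, or 40-minute vs
  1-week pairing collapsed with `grand_average_replicates()`).

Degenerate replicate tables (zero jackknife variance) are reported with
explicit flags rather than NaNs.

## Data screens

`filter_subjects()` mirrors the usual acquisition screens.  The
uniformity screen computes, per subject, the chi-square statistic of the
pooled digit histogram against uniformity over nine digits and removes
subjects more than 3.5 SD above the cohort mean; the chi-square-then-
z-score construction is the simplest statistic measuring "maintaining a
uniform digit distribution", and z-scoring matches the sigma phrasing of
such screens.  Pooling per subject is the default (a per-sequence mode
exists).  The pause screen removes subjects with any inter-response gap
above 15 s; it requires onset times, which the corpus format keeps
optional because the analysis object proper is the digit string —
sequences without onsets pass.  Exclusions are logged with reasons.

## Classical indices

`redundancy()` is $1 - H/\log_2 9$ over the digit histogram (0 = equal
use of all digits, 1 = one digit only) and `runs_index()` is the
population variance of the lengths of maximal strictly-ascending runs,
the usual seriation ("counting") index.  The runs literature contains
variants (ascending-only vs both directions, increments of exactly one
vs any increase); we implement the variance of maximal strictly
ascending run lengths with any increase, the most common reading, and
note that published summary values cannot arbitrate the choice without
raw data.  `ks_lognormal()` reproduces the conventional distributional
sanity check — a one-sample KS test of log-values against a
moment-estimated normal.  Estimating parameters from the data makes it
conservative (the Lilliefors effect); the plain form is retained
deliberately because it is the procedure being replicated, not an
optimal test.

## Individuality: preferences and inhibitions

Identification works because subjects prefer and inhibit *different*
patterns, so group-level pattern analysis is uninformative.  Instead,
for each subject the full $9^3$ length-3 pattern space is ordered from
her most rare (rank 1) to most common (rank 729) pattern in session 1.
At each rank the within-subject score difference (same pattern, her
session 2) is compared with the between-subject difference (same
pattern, other subjects' session-1 sequences; absolute differences in
both cases); `delta = between - within` is the degree of individuality
at that rank.  Elevated delta at the top of the scale indicates
individual preferences; elevated delta near the bottom, individual
inhibitions.  `band_top_patterns()` reports the most frequent patterns
per ordinal band; the default bands reproduce the printed ranges of the
reference analysis verbatim — including their overlap at ordinal 230 and
the unassigned stretch 301–699 — and `find_band_minima()` offers a
data-driven alternative (local minima of the delta curve smoothed with
an 11-point moving average).

`familiar_pattern_test()` asks whether familiar numbers (birthdates,
phone numbers, postal codes) leave traces: per subject, the mean excess
of her own score over other subjects' mean score across the length-3
patterns extracted from her familiar strings, then a one-sample t-test
across subjects (plus a KS normality check), per kind.  Familiar strings
may contain the digit 0, which cannot occur in task sequences; zeros are
*dropped* before extracting contiguous length-3 subpatterns.  This is an
interpretation — it preserves the order structure of the remaining
digits but fabricates adjacency across removed zeros — and is flagged
here prominently.  Per-subject aggregation (not per-pattern) is used, in
line with the degrees of freedom such tests conventionally report.

## The synthetic cohort generator

No public human corpus exists for this task, so the package ships a
generator whose output has the statistical structure the analysis
assumes, making every stage testable end to end.  Per subject and
session, digits are produced by a loop that either continues a
*template* — a preferred pattern instance that with probability
`edit_noise` carries one random edit (insertion, deletion, substitution
or adjacent transposition) — or draws from a baseline distribution that
suppresses immediate repeats (`repetition_suppression`), mildly favours
`previous + 1` (`seriation_bias`, wrapping 9 to 1), and resamples digits
that would complete an inhibited pattern.  Profiles combine a
cohort-shared component with a subject-specific one; the individuality
strength `kappa` scales the subject-specific preference weights and
inhibition strengths, with `kappa = 0` collapsing everyone onto the
shared profile (an exchangeable cohort, the null of every calibration
test).  Session-to-session drift multiplies preference weights by a
log-normal factor (`session_drift`).

Default rates (chosen once, as a realistic operating point, and
documented here rather than fitted to any published summary): 115
subjects, 2 sessions, 300 digits; `template_rate = 0.15`, so with mean
template length 3.5 roughly a third of digits stem from templates;
`edit_noise = 0.15`; `repetition_suppression = 0.8`;
`seriation_bias = 0.15`; 4 subject-specific preferred and 4 inhibited
patterns (drawn from the repeat-free length-3/4 space) against 2 shared
ones each; shared preferences carry half the base weight — universal
tendencies exist but are weak relative to idiosyncratic ones, and a
strong shared component would push the cohort-level digit marginals
outside the near-uniform envelope (each digit within $1/9 \pm 0.03$
pooled) that the generator is designed to keep, so that generated
cohorts pass the uniformity screen.  Randomness is counter-based: every
stream is derived from `(master_seed, subject, session)` with a small
multiplicative hash, so adding subjects or sessions never perturbs
existing sequences.

What the generator does *not* emulate: response timing (onsets), the
log-normal shape of human index distributions, fatigue and practice
effects beyond weight drift, and any fitted correspondence to published
index means.  Passing tests therefore demonstrate the pipeline's
correctness and its qualitative behaviour under the assumed mechanisms —
chance-level AUC for exchangeable cohorts, rising AUC with individuality
strength, the collapse of exact matching at long patterns under edit
noise, individuality concentrated at the ordinal extremes — not
quantitative claims about human data.

## Numerical choices and edge cases

* Ties in ordinal ranking are broken lexicographically by pattern
  digits, making ranks deterministic.
* Standardization uses the population (divide by N) SD; the choice is
  immaterial after column scaling but fixed for reproducibility.
  Zero-variance columns standardize to zero rather than NaN.
* AUC orientation is fixed so smaller distance means match; ties count
  1/2.
* Degenerate inference inputs (all-zero differences, zero jackknife
  variance) return flagged finite results instead of errors, except
  where the input violates a precondition (single-class ROC, fewer than
  2 pattern lengths, fewer than 3 replicates).
* The third (1-week) session is supported throughout via the `s1s3`
  pairing scheme; standardization for an `s1s2` analysis pools sessions
  1 and 2 only, so an appended session 3 never shifts the 40-minute
  results.

## Problem sizes used in validation

The shipped validation suite exercises the pipeline at reduced but
structurally faithful sizes, chosen so the full suite runs in a few
minutes: oracle sweeps are exhaustive over a 3-symbol alphabet up to
length 4 (distance) and 50 random 300-digit sequences for lengths 1–3
(scoring); cohort-level properties use 20–30 subjects at 2 × 300 digits,
10 seeds for calibration and monotonicity surfaces, and 200 reduced
cohorts (12 subjects × 150 digits) for the familiar-test calibration.
`scripts/acceptance.R` recomputes the headline quantities on a
30-subject cohort from a user-supplied seed.

## Known limitations

* The OSA distance is not a metric in corner cases involving
  transpositions; all uses here are comparative (scores, rankings), not
  metric-dependent.
* The uniformity screen's z-scoring is cohort-relative: one screening
  pass is defined on the input cohort, and re-screening an already
  filtered cohort can in principle flag new borderline subjects.
* The zero-dropping rule for familiar numbers is one of several
  defensible readings; results of `familiar_pattern_test()` should be
  interpreted with that in mind.
* Band defaults are length-3 specific and inherit the printed ranges'
  overlap and gap.
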