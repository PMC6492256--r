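---
title: "Measuring morphological conditioning complexity in miniature-language experiments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring morphological conditioning complexity in miniature-language experiments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(morphocomplex)
```

## The problem

Miniature artificial-language experiments probe how adults acquire, transmit
and negotiate morphological complexity. A learner is trained on a small
language whose descriptions are built from transparent stems plus suffixes;
the suffixes may redundantly mark number and do so with lexically conditioned
irregularities. The analytical questions are then: how accurately are stems
and suffixes reproduced; *how much of the scene's semantics conditions the
learner's suffix choice*; whether mixing input from several (possibly
simplifying) speakers changes what a second generation learns; and whether a
speaker of a complex variant simplifies during live interaction with a
partner who acquired a simpler one.

`morphocomplex` implements the full analysis chain plus a seeded synthetic
generator for every experimental structure, so each stage can be exercised
and tested without human data.

## The target language and production scoring

`build_exp1_target()` constructs the 18-scene complex language (2 number x 3
animal x 3 motion; word classes Q, N, V). Stored forms are unhyphenated; the
stem/suffix segmentation is carried as an index in the spec, never re-derived
at scoring time. Hyphens in input files are treated as presentational and
stripped at parse time.

Produced words are segmented by `segment_word()`: if a target stem of the
word's class is an exact prefix, the split is automatic (longest stem on
ties); otherwise every split point is scored against every candidate stem by
edit distance and the minimizing split is used, with deterministic
tie-breaks (smaller distance, longer stem, lexicographic stem, longer
prefix) and a review flag. This automates the manual fallback a human coder
would apply, while keeping an audit trail. A zero-marked suffix is coded as
the token `NULL` and enters distance computations as the empty string.

Accuracy is `1 - d(a, b) / max(|a|, |b|)` with `d` the unit-cost Levenshtein
distance (`utils::adist` underneath; the test suite checks it exhaustively
against a bottom-up tabulation of the textbook recurrence for all pairs of
strings up to length 6 over a three-letter alphabet, and against plain
recursion at tiny sizes). Division by the longer string's length is the
normalization assumed throughout; `d("", "") = 0` by convention. Missing
words score 0 on both morphemes rather than being dropped — conservative,
and it keeps denominators fixed. Aggregation is a mean of by-participant
means, with 95% confidence intervals from the t distribution below 30
participants (degenerate zero width for a single participant).

## Conditioning complexity

For one participant x word class x phase, the statistic asks how many
semantic features the best statistical account of suffix choice needs.

* **Predictor variants.** Each feature enters either at full granularity or
  collapsed to one-vs-rest. Number (two levels) has a single binary variant;
  Animal and Motion each have four (full three-way plus three
  binarizations). Collapsed and full variants of one feature are never
  co-included (the collapsed variant is nested and co-inclusion is
  collinear).
* **Model space.** All additive models with at most one variant per feature
  — `2 x 5 x 5 = 50`, including the intercept-only model — plus, for each of
  the 40 selections with at least two variants, the same selection augmented
  with all interactions among its variants (full factorial): 90 candidates,
  in a fixed canonical order.
* **Fitting.** Each candidate is a multinomial logit fit by maximum
  likelihood (`nnet::multinom`, iteration cap 100, relative tolerance 1e-8).
  The parameter count is `k = (C - 1) * p` for `C` suffix categories and `p`
  design columns including the intercept; `AIC = 2k - 2 loglik`. Two
  degenerate cases use closed forms: a single observed category scores
  `loglik 0, k 0, AIC 0`, and the intercept-only model uses the empirical
  category frequencies. Under complete separation the capped iterative fit
  drives the log-likelihood to numerical zero, so a perfectly predictive
  model scores essentially `2k`; this deliberately mirrors the standard
  fitting routine's behaviour so AIC values are comparable to analyses run
  with it.
* **Selection.** Lowest AIC wins; ties within 1e-9 break to fewer
  parameters, then canonical order. The complexity score is the number of
  distinct features in the winner: 0 (invariant suffix) to 3.

```{r worked-example}
ex <- example_learner_suffixes()
q2 <- subset(ex, phase == 2 & word_class == "Q")
best_model(q2$suffix, q2[c("number", "animal", "motion")])
```

The package's worked example (`example_learner_suffixes()`) is a learner
whose round-2 quantifiers are conditioned on number alone but whose round-8
system matches the target; the pipeline recovers complexities (1, 3, 1) at
round 2 and (2, 2, 3) at round 8 for (Q, N, V), and scores the target
language itself at Q = 2, N = 2, V = 3.

Suffix entropy (`suffix_entropy()`) is the meaning-independent companion:
Shannon token entropy, in bits, of the empirical form distribution within a
word class. Token weighting and base 2 are package choices, documented here
because alternative conventions exist.

## The synthetic learner generator

`simulate_learner_productions()` is phenomenological — a grammar plus noise,
not an acquisition model; the pipeline only needs data with a controlled
dependency structure. A learner's grammar conditions each word class's
suffix on a configurable feature subset, assigning a *distinct* form to
every conditioning cell (drawn from the target inventory, invented, or the
target mapping verbatim); production applies per-item zero-marking (default
rate 0.05, characteristic of early learners of this language) and
per-character edit noise.

One cap matters and is deliberate: conditioning grids are limited to 9
cells, so a grammar conditioned on all three features enters each through a
binary contrast (as the target verbs do). With one production per scene, an
18-cell grammar with all-distinct forms produces 18 singleton suffix
categories, for which the intercept-only model is *correctly* preferred by
AIC (34 + 104.0 versus at least 204 for any separating model): such a system
is statistically unidentifiable at this design size, which is a property of
the measure, not a defect of the fit. The cap keeps injected structure
within the measure's resolving power, which is what makes exact parameter
recovery a fair test.

`simulate_exp1_cohort()` emulates a 26-learner study: early-phase
productions from idiosyncratically simplified grammars (number-based, with
per-learner form choices), late-phase productions from the target grammar
with small noise (0.005 per character; suffix noise 0.01-level effects).
Early stem fidelity is bimodal — half the cohort exact, half with 0.01-0.08
per-character noise — so that roughly half meets the 90% exact-stem
screening criterion, matching the structure such studies report. These
values parameterize realism, not any test outcome.

What the generator does **not** emulate: within-round learning dynamics,
participant fatigue, phonotactic biases in errors, or consensus effects
among simplifiers. Passing tests therefore certify the pipeline's
arithmetic and the measure's behaviour on data with known structure — not
claims about human learners.

## Mixed multi-speaker input

`select_sources()` screens a cohort at the early phase for >= 90%
exact-stem labels (a label counts only if all three stems are exact).
`construct_training_phase()` samples 9 of the 18 scenes without replacement
and divides them across sources — {5, 4} for two sources, {2, 1 x 7} for
eight, double-contributor uniform — pairing each scene with that source's
own description at its assigned phase; phases are resampled independently.
`construct_training_input()` assembles the four canonical conditions
(small/large x complex/mixed; mixed splits sources half early, half late).
Pooling idiosyncratically simplified systems yields data that is more
variable than any source — the package demonstrates this through entropy:
mixing two number-conditioned systems with disjoint form inventories
strictly raises suffix entropy above either source's.

## Dyadic interaction with accommodation

`generate_exp3_language()` builds the reduced 9-scene noun-verb languages:
three fixed nouns; three of five verb forms assigned at random to the
motions as regulars; the two remaining forms placed as irregulars in two
cells sharing neither animal nor motion (18 admissible placements, uniform;
2160 distinct languages). Which irregular form lands in which chosen cell is
randomized — the constraint set does not determine it, and the choice
affects no statistic.

`simulate_dyad()` alternates two directing streams per round (each agent
directs all nine scenes in random order). A simple speaker knows only the
seven regular pairings and regularizes irregular cells (rate 119/120). A
complex speaker may adopt the partner's regularized form: a speaker-by-cell
case is *receptive* with probability 29/40; receptive cases, once exposed,
switch at an opportunity with probability 27/29 and persist per trial with
probability 21/22. Matching succeeds at 0.97 for forms in the matcher's
grammar and at 0.5 when a simple matcher faces an unknown irregular form —
a behavioural constant, since pragmatic exclusion would predict near-certain
success and observed behaviour does not show it. All defaults are printed
counts from the study this emulates, fixed before any simulation was run.
The conditional counts alone (27/29, 21/22) would overshoot the observed
50% marginal regularization — they are conditional on regularizing at all —
which is why receptivity (29/40, also a printed count) is a separate
parameter. With these settings the Monte-Carlo distribution of the
complex-speaker regularization proportion (20 mixed dyads, 3 rounds)
brackets one half, which the acceptance suite checks across 200 replicates.

Known limitations: adoption is modelled only through exposure (no separate
failure-triggered channel); post-test production applies the same
persistence rule as interaction, so the simulator does not reproduce the
drop-off between interaction and post-test regularization that humans show;
matcher behaviour is a constant rather than a choice model.

## Descriptive statistics and the contingency test

`chi2_2x2()` is the uncorrected Pearson statistic
`n(ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d))` on 1 df, erroring on zero margins;
no continuity correction, because the uncorrected value (5.625 on the
canonical post-test table (7, 13, 1, 19)) matches the conventionally
reported value to rounding while the corrected one does not. Condition
comparisons elsewhere report estimates with confidence intervals rather
than significance tests. `run_exp1()`, `run_exp2()` and `run_exp3()`
orchestrate the three analyses and write tidy CSVs plus a JSON manifest;
inferential mixed-effects regressions are intentionally out of scope — the
tables are emitted in a form suitable for external refitting.

## Numerical choices and problem sizes

Fitting: iteration cap 100, relative tolerance 1e-8, no penalty by default
(a ridge could be added, but unpenalized fits keep AIC comparable to the
standard routine). AIC ties: 1e-9 window, then fewer parameters, then
canonical order. Variants that do not vary over a data subset are dropped
from the design; the equivalent smaller model exists in the enumeration and
wins ties through its lower `k`. All randomness flows through explicit
integer seeds (Mersenne-Twister), recorded in generated specs and
manifests; simulators are bit-reproducible given a seed.

The shipped test suite uses: exhaustive edit-distance verification to
length 6 (1093 strings); 18,000 generated reduced languages for the
placement-uniformity goodness of fit; 105 seeds for exact parameter
recovery; 2,000 training phases for the scene-inclusion check; and 200
replicates of a 20-dyad study for the regularization calibration. These
sizes were chosen to give comfortable statistical resolution at interactive
runtimes.
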