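---
title: "Cascaded multimodal classification of MCI: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cascaded multimodal classification of MCI: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mcicascade)
```

## The problem

Mild cognitive impairment (MCI) is a clinically observable deficit in at
least one cognitive domain that does not yet interfere with daily living.
Language-based tasks are attractive screening instruments because they are
naturalistic, repeatable and sensitive to early decline across several
cognitive systems at once. `mcicascade` implements a cascaded multimodal
classification framework for distinguishing MCI from healthy controls (HC)
using three tasks per data-collection session — Cookie Theft picture
description, silent paragraph reading, and reading aloud — each observed
through a subset of four modes: speech timing, transcript language, eye
movements over word-level areas of interest (AOIs), and comprehension
question responses. Seven (task, mode) combinations exist; each is
summarized by a fixed-length feature vector (26 language, 12 speech, 22
eye-movement, 11 comprehension features), and classifiers are fused at four
alternative levels of the hierarchy.

## Feature extraction

**Eye movements.** Every fixation is assigned to one of four exclusive
classes. A *first-pass first fixation* is the first fixation on its word
while no later word has yet been fixated; a *later-pass first fixation* is
a first fixation after some later word has been visited; a
*multi-fixation* is a non-first fixation inside the consecutive run opened
by a first-pass first fixation; everything else is a *re-fixation*. The
trial is also split into a reading phase (up to and including the fixation
that first enters the last AOI — the entering fixation is counted as
reading so the two phase counts always partition the total) and a
re-reading phase. The *gaze duration* of a word is the summed duration of
its first-pass run, the standard reading-research definition. Wrap-up
measures compare gaze durations on sentence-final words against the mean
over all sentence-internal words. Saccade and regression statistics
(amplitude in degrees, distance in words) treat within-word saccades as
distance 0 and never as regressions: a regression requires a strictly
earlier end AOI.

**Speech.** A pause is a silent gap between consecutive voiced intervals
*strictly longer* than 150 ms (configurable). Leading and trailing silence
is not between speech and never counts as a pause, but contributes to the
total duration. Phonation time is the summed voiced time; speech rate is
syllables per second of total duration; average syllable duration is
phonation time per syllable.

**Language.** Counted words exclude punctuation and all dysfluent tokens
(filled pauses, false starts). Phrase- and clause-type proportions divide
the number of words carrying a tag by total words; the clause proportions
deliberately mirror the phrase formula. Information units are
keyword-spotted against a four-category lexicon (3 subjects, 11 objects, 2
places, 7 actions, the standard Cookie Theft inventory); distinct-unit
counts are normalized by total words, while content density and efficiency
use total mentions including repetitions, per word and per second
respectively. The type-token ratio is computed over lowercased surfaces of
counted words, and the median word frequency averages the two central
values for even counts.

**Comprehension.** Average accuracy plus per-question correctness and
response time; with `q` questions the dimensionality is `2q + 1` (the
default five gives 11).

Statistics over empty sets (no regressions, fewer than two pauses) are
explicitly masked missing, never silently zeroed: zero is a meaningful
value for most of these features. Standard deviations use the sample
(n − 1) denominator and are masked below two observations.

## Classifiers and fusion

Every component classifier follows one probability contract: fit on a
feature matrix with labels HC = 0 / MCI = 1, emit `p(MCI)` in [0, 1]. Two
families are provided — L2-regularized logistic regression and an RBF-kernel
SVM whose decision values are mapped to probabilities by Platt's sigmoid,
fitted by regularized maximum likelihood on out-of-fold decision values and
constrained monotone non-decreasing. The regularization strength is the
conventional `C = 1.0` for every classifier in a cascade; it is
deliberately not tuned, and no classifier gets its own setting, so the
scores that are averaged or stacked remain comparable. Features are imputed
with training means (masked-missing entries only) and z-standardized with
training statistics, because both model families are scale sensitive. The
RBF kernel width defaults to the reciprocal of (feature count × pooled
training variance), a deterministic data-driven rule.

Four architectures combine the seven mode-level vectors:

* **feature fusion** — early fusion: one classifier on the concatenated
  116-feature vector;
* **mode fusion** — seven (task, mode) classifiers; the final score is
  their unweighted mean;
* **task fusion** — mode scores feed one classifier per task; the three
  task scores are averaged;
* **session fusion** — the task scores feed one final classifier, so
  probability estimates exist at every level of the tree.

Upper levels are trained on *out-of-fold* lower-level scores from an
internal seeded stratified 5-fold split, then the lower levels are refit on
the full training split for prediction. In-sample meta-features would let
the upper level learn the lower levels' training optimism; stacking is the
standard remedy. Because the available text does not pin down how the
original cascade generated its meta-features, an in-sample mode is kept
behind `cascade_config(stacking = "in_sample")` for comparison.

## Evaluation

Performance is estimated by leave-pair-out cross-validation: every possible
(MCI, HC) pair is held out once, the model is refit on the remainder, and
the pair is scored. The AUC estimate is the mean concordance indicator over
folds (1 if the MCI member outscores the HC member, 0.5 on ties, 0
otherwise), which is unbiased for small samples, and its dispersion is
reported as the standard deviation of the per-fold indicators. Accuracy,
sensitivity and specificity are computed from per-participant scores
averaged over all folds in which the participant was held out, at a
configurable threshold (default 0.5, ties called MCI to favor
sensitivity); a per-fold counting mode exists behind a flag. The
fold-averaged per-participant scores also feed individual-level reporting:
threshold shifting, narrative explanation reports quoting the probability
tree to two decimals, and the correlation analysis below.

## Neuropsychological battery

A 25-test battery (memory, language, attention, visuo-spatial, executive,
plus MMSE as a global screen) provides a flat baseline classifier under the
same probability contract, with training-mean imputation for missing
scores. Spearman rank correlations (average-rank ties, pairwise complete)
relate each prediction level's fold-averaged score to each test; for tests
where higher scores mean better function the sign is flipped, and flagged,
so that every test correlates positively with MCI. The four-vote *combined*
fusion averages the three task scores with the neuropsychological
probability. Retrospective MCI subtyping flags a test as impaired when its
score is worse than the age-stratified (50–64 / 65–80) healthy-control mean
by more than 1.5 control standard deviations, direction-aware — for timed
tests the impaired tail is the high side. Amnestic single-/multi-domain and
non-amnestic single-/multi-domain labels follow the usual impairment
patterns; "single domain" requires all flagged non-memory tests to fall in
one domain, and profiles whose missing scores leave a rule undecidable are
returned unclassifiable with the reason. MMSE is excluded from the subtype
rules.

## The synthetic cohort generator

The clinical data this framework targets cannot be shared, so the package
ships a generator that emulates the study conditions end to end. Each
participant draws a latent impairment value `z` — HC from N(0, 1), MCI from
N(d, 1) with `d` the configured effect size (default 2, a moderate-to-large
separation; `d = 0` gives exchangeable groups). Generation happens at the
raw-record level — scanpaths, voiced intervals, annotated token streams,
question responses, test scores — so every extractor and reader sits on the
tested path. All generation parameters are monotone in `z`, following the
expected direction of early decline: more fixations, regressions and
re-reading with longer fixations; slower speech in shorter chunks with more
and longer pauses; reduced information-unit coverage and lexical diversity
with more dysfluencies and pronouns; slower, slightly less accurate
comprehension; worse (direction-aware) neuropsychological scores with
configurable missingness. Defaults mirror the reference study conditions:
29 HC and 26 MCI participants, 146-word reading texts in 10 sentences, five
comprehension questions.

Because every mode reflects the *same* latent `z`, the attainable session
AUC is bounded by the group separation of `z` itself (about Φ(d/√2), e.g.
0.983 at `d = 3`). The per-mode noise scales were chosen once so that a
participant three latent standard deviations out is nearly always
separable — i.e. `d` is measured on a scale where `d = 3` means clearly
impaired — giving single-mode AUCs around 0.9 and task-fusion recovery
above 0.95 at `d = 3`, while `d = 0` cohorts are classified at chance.
These are generator design choices, fixed in code, not tuned quantities.

What the generator does *not* emulate: real Swedish lexical, syntactic or
discourse structure (the word bank is a small annotated vocabulary);
correlated mode-specific deficits (a single `z` drives all modes, whereas
real MCI subtypes dissociate); oculomotor physics beyond a
left-to-right sweep with refixations, regressions and re-reading passes;
and acoustic waveforms (syllable counts are generated, not detected).
Passing tests therefore demonstrate correctness of the pipeline and
recoverability of a planted signal — not clinical performance on real
cohorts.

## Numerical and design choices

* Canonical feature order is the documented top-to-bottom order of the
  four feature tables, expanding mean before s.d. and questions 1–5 in
  order; `feature_names()` is the reference.
* The ridge-logistic solver is a Newton/IRLS implementation in compiled
  code (unpenalized intercept, backtracking line search, tolerance 1e-9),
  matching the usual `C`-parameterized objective; the out-of-fold stacking
  loop for this family also runs compiled, with semantics identical to the
  generic path (asserted by a test). Leave-pair-out over all architectures
  and seeds requires millions of component fits, which is why this inner
  loop is compiled.
* Internal fold assignments and all generator draws derive
  deterministically from the configured seed; identical configuration and
  seed reproduce every number bit-for-bit, and the text writers print 17
  significant digits so disk round-trips are also bit exact.
* Platt calibration is constrained to slope ≥ 0 (monotone map); SVM
  decision values are re-oriented, if necessary, so larger means more
  MCI-like before calibration.
* Degenerate inputs: a cohort with a single class refuses to fit; a
  leave-pair-out cohort of one participant per class is flagged degenerate
  (empty training set); features that are missing for every training row
  are imputed at the standardized mean (zero), which neutralizes them.
* Problem sizes in the test suite: unit tests run on reduced cohorts and
  30–40-word texts; the calibration studies use 30+30 cohorts at the
  default text length (50 seeds for the null, 3 for the planted-effect
  recovery). These sizes were chosen as the smallest at which the studied
  properties are stable.

## Limitations

The evaluation refits the full cascade for every held-out pair, so
leave-pair-out cost grows as n_MCI × n_HC model fits; the compiled solver
keeps a 55-participant cohort to a few seconds per architecture, but very
large cohorts would warrant a different cross-validation scheme. AUC
dispersion is the per-fold indicator standard deviation — a descriptive
spread, not a confidence interval, and no DeLong or bootstrap inference is
provided. The information-unit normalization divides *distinct* unit
counts by total words (mentions including repetitions enter only the
density/efficiency features); whether the original counts were distinct or
mention-based is not recoverable from the available description, and the
choice is flagged for sensitivity analysis. Whether wrap-up statistics
should use first-pass gaze only is likewise one defensible reading, made
explicit here.
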