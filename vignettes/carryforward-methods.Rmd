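---
title: "Detecting and classifying carry-forward effects in multimodal game-play data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and classifying carry-forward effects in multimodal game-play data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(carryforward)
```

## The problem and the model

In a motion-based educational game, a child reads a multiple-choice
question at the bottom of the screen, mentally solves it, reaches out to
grab the chosen answer and drags it to its target. The package models this
as the S2MR cycle — See-Solve, Move, Respond — and asks, for each of seven
gaze- and physiology-derived measurements, whether the difference between
right- and wrong-answered cycles persists across all three phases while
peaking during problem solving. A measurement with that profile carries
information about the outcome *forward* into phases where no problem
solving happens; we call this a carry-forward effect (CFE) and classify it
per measurement as Perfect, Pseudo or None.

Two independent routes establish the CFE:

* an **inferential route** built on per-phase group tests and effect
  sizes, and
* a **predictive route** built on per-phase feature-importance ranks of a
  correctness classifier.

Their agreement on synthetic data with known planted effects is the
package's central validity check, since the original child data cannot be
redistributed.

## Phase segmentation

See-Solve starts at the first fixation whose centroid lies in the question
AOI at or after the logged question onset (gaze before the onset is
ignored: the question does not exist yet). Move starts at the first
skeletal frame after that whose whole-body displacement — the sum over the
25 joints of the Euclidean frame-to-frame distance, the least biased
scalar when no joint subset is privileged — exceeds an individual
threshold. Respond runs from the logged selection to the logged response.
The three segments are contiguous and half-open, so they partition
`[see_solve_start, response)` exactly; a movement onset detected after the
selection collapses the Move segment to zero length at the selection.

The movement threshold is `mean + k * SD` (default `k = 2`) of baseline
displacements. How the study computed its "individual threshold" is not
recoverable from the available description, so the package uses a
per-cycle expanding baseline (frames observed since the See-Solve onset),
floored by a participant-level threshold computed from the rest period.
The floor matters: with three to five baseline frames the sample SD is
unstable, and without the floor quiet stretches of postural sway
occasionally trigger early. Cycles in which no fixation ever lands on the
question AOI are excluded and counted, never imputed.

## Preprocessing choices

* **Gaze events** come from an I-VT classifier: a sample whose
  point-to-point velocity exceeds the threshold (default 1.0 screen
  units/s, calibrated on the synthetic streams) is a saccade sample;
  invalid or pupil-missing runs are blinks; adjacent same-kind samples
  merge; fixations shorter than 60 ms are relabelled (between saccades) or
  dropped. The proprietary eye-tracker algorithm this stands in for is
  isolated behind this one function, so a different event classifier can
  be swapped in.
* **Pupil diameter** is averaged over valid eyes and z-scored against the
  participant's first 30 s. The z-score satisfies the purpose of removing
  subjective and contextual bias without importing an external index; the
  cognitive-load measurement is then simply the windowed mean of the
  normalized diameter. This is deliberately the most testable choice, and
  it is isolated so a pupillometry-specific index can replace it.
* **EDA** is smoothed with a 0.5 s centered moving average (the exact
  smoothing kernel is unspecified in the source description; a moving
  average is deterministic and sufficient to remove sensor spikes), then
  split into a tonic component (4 s centered moving median) and a phasic
  remainder, so tonic + phasic reconstructs the smoothed signal exactly —
  an identity the tests assert. SCR peaks are local maxima of the phasic
  component with prominence at least 0.01 uS.
* **EDA and HR** are additionally normalized against their first 30 s
  (mean/SD; a zero-SD baseline divides by 1 and raises a flag).
* **Windows** are 10 s long with a 5 s hop over the whole session, and
  each window takes the phase of the segment containing its midpoint.
  Windowing *within* phases was the alternative reading; it was rejected
  because phases (median 2 s for Move and Respond) are usually shorter
  than one window, which would leave those phases without any data. The
  midpoint rule is total and unambiguous, at the cost that a window's
  samples can straddle phase boundaries — a known, deliberate
  approximation. A trailing truncated window is kept only when strictly
  longer than half the window; at exactly half it duplicates the second
  half of the preceding full window and is dropped (this also makes a
  20 s interval yield exactly the three windows at 0, 5 and 10 s).

## Measurements and features

The seven measurements are cognitive load, information processing index
(IPI), saccade velocity, mean HR, number of EDA peaks, phasic EDA and
tonic EDA; plus the three AOI-transition shares per window and the
per-question time to first fixation. IPI classifies each (fixation,
following saccade) pair as global (short fixation and long saccade) or
local (long fixation and short saccade) and reports
`(n_global + 1) / (n_local + 1)`; the +1 smoothing keeps the ratio finite.
The thresholds default to within-participant medians of fixation duration
and saccade amplitude, because absolute visual-angle thresholds would
require screen geometry that the normalized coordinates deliberately
abstract away. Transition shares count only the three named categories
(question-right, question-wrong, right-wrong); wrong-to-wrong moves are
excluded from the denominator. All measurements except time to first
fixation are MinMax-normalized per (domain, measurement); constant groups
map to zero with a flag.

Each measurement's window series per (participant, question, phase) is
reduced to nine features: five histogram statistics (SD needs two values,
skewness/kurtosis three), AR(1)/AR(2) coefficients from a Yule-Walker
order-2 fit (six values), and GARCH(1,1) alpha/beta from a Gaussian
maximum-likelihood fit written against `optim` (ten values). Below these
lengths the features are explicit `NA` markers — never silent zeros — and
the predictive stage imputes them with training-fold medians. With the
default per-question series (one to three windows) the AR and GARCH
features are mostly missing; they become informative when series are
pooled per game, which is why the extractor is exercised directly on
simulated AR and GARCH processes in the tests (recovery asserted on
seed-averaged estimates, since single-sample GARCH estimates at n = 500
legitimately spread by more than +-0.15).

## Inferential route

Per (measurement, phase), the cycle value is the mean over that cycle's
windows, and cycle values are then averaged to participant-by-label means
— the design's unit of analysis (a repeated-measures ANOVA over 40
participants has df (1, 39); the Welch tests sit at fractional dfs just
below that). Both test paths operate on these same means: Shapiro-Wilk on
the residuals decides a z-transform of the values (the transform is affine
and cannot change the F statistic; it is implemented and flagged for
fidelity, not effect); Breusch-Pagan on the group model decides between
the repeated-measures ANOVA with the participant as grouping variable
(participants observed under both labels) and a Welch one-way ANOVA,
which has no repeated-measures form. The effect size is partial
eta-squared on the participant-level means for both paths — computing it
on different units depending on the heteroscedasticity decision would
make effect sizes incommensurable across phases, and the CFE conditions
compare them directly. It is the only effect-size family consistent with
the published 0-to-1 values. The Bonferroni family is all
measurement-by-phase tests of one game domain (7 x 3 = 21), matching how
the results tables are organized per game.

The CFE classifier evaluates four conditions — significant everywhere,
See-Solve effect size strictly maximal, Move strictly above Respond,
affinities consistent — with ties failing. The source description contains
a genuine contradiction: its decision text calls the affinity failure
"Pseudo", while its own worked example (saccade velocity, effect sizes
0.21/0.12/0.17, consistent affinity, classified Pseudo) and the predictive
definition both make the Move-vs-Respond ordering the Pseudo-breaking
condition. The package follows the worked examples by default; the literal
text variant stays selectable via `run_config(pseudo_rule = "text")`.

## Predictive route

The ensemble combines seven members — SVMs with linear, radial and
polynomial kernels; Gaussian-process classifiers with the same three
kernels; and an M5-style model tree (a pruned regression tree with linear
models in the leaves, since no exact M5 implementation exists in the R
ecosystem) — each emitting a probability-like score in [0, 1], thresholded
at 0.5, combined with validation-accuracy-proportional weights. Splits are
always by participant: 10% of participants (rounded up) form an untouched
outer holdout, the rest cycle leave-one-participant-out. Minority
oversampling runs inside training folds only, using the 5-nearest-neighbor
variant that generates exactly four synthetic points per minority point
(the mean of the four closest neighbors jittered by +-25% and +-50% of the
neighbors' per-feature SD) — four per point because that exactly
rebalances 5:1 data, resolving the source's internal four-vs-five wording
conflict; the count is overridable. Gaussian-process members train on a
deterministic stratified subsample capped at 150 rows (the fit is cubic in
n), and the radial-basis bandwidth uses a deterministic median-distance
heuristic rather than a resampling-based estimate, keeping the whole
pipeline byte-reproducible for a fixed seed.

Importance is permutation importance on each fold's validation set,
combined across members by the ensemble weights, averaged across folds and
scaled to 0-100; ranks are dense (ties share a rank) and the top set is
the features with rank at most `ceiling(0.10 * k)`. The rank-based CFE
classifier mirrors the inferential one with "rank highest" meaning
numerically smallest, and strict comparisons throughout — a feature ranked
first in every phase is *not* Perfect, because no phase is strictly
highest. Published rank tables contain rows inconsistent with their own
stated rules; the package implements the stated rules and classifies such
rows accordingly rather than reverse-engineering the exceptions.

## Feedback prioritization

Within a plan, Perfect precedes Pseudo precedes None. Within Perfect and
Pseudo the See-Solve effect size decides. Among no-CFE measurements the
two published worked orderings disagree with a pure effect-size rule, so
the package scores the significance pattern lexicographically (significant
in See-Solve, then Move, then Respond) before the effect size, which
reproduces both published pairwise statements. The final tie-break puts
wrong-affinity (remediation-requiring) measurements first, and the
remaining order is alphabetical for determinism. Measurements whose higher
values co-occur with right answers map to encouragement — an addition to
the intervention vocabulary, since positive reinforcement is the stated
response when no remediation is needed.

## The synthetic cohort generator

The generator is first-class, tested code, and its defaults are the study
conditions: 40 participants, two game domains, three games per domain,
five questions per game, right answers with probability 5/6. Phase
durations are lognormal with medians 6 s (See-Solve) and 2 s (Move,
Respond) — chosen so a cycle spans one to three analysis windows, since
only the total session length is reported — and each session opens with a
35 s rest so the 30 s normalization baseline is question-free.

Streams are built to make downstream recovery well-defined:

* **Gaze** is a fixation/saccade event sequence (AOI scanning during
  See-Solve, option pursuit during Move/Respond, neutral wandering between
  questions) rendered at 50 Hz; the first question-AOI fixation starts
  exactly at the true See-Solve onset, and saccades land on their target
  by their final sample so the I-VT classifier recovers fixation onsets to
  one sample. Blinks are short invalid runs, vetoed in a small guard
  interval around each See-Solve onset so the planted marker stays
  observable.
* **Skeleton** idles as bounded whole-body postural sway (a slow
  oscillation) plus tiny sensor noise; because the sway's displacement
  distribution is bounded below its mean + 2 SD, the threshold rule
  does not false-trigger on idle frames, while answering motion is an
  order of magnitude larger and triggers within one frame.
* **EDA** is a tonic level with participant-specific drift plus
  Poisson-rate SCR bumps with a standard rise-1 s/decay-3 s morphology;
  **HR** is a participant baseline (SD 8 bpm between participants, the
  dominant variance component, as is realistic for children at play) plus
  AR(1) noise.

A planted effect of size `d` shifts the affinity group's raw channel by
`d` times a frozen reference SD — the Monte-Carlo-calibrated SD of the
per-cycle phase mean of that channel under the null — so a two-sample
Cohen's d computed directly on generated channel values recovers `d`. For
the level channels (HR, pupil, tonic EDA) this is exact by construction;
for the generative-knob channels (SCR rate and amplitude for peak count
and phasic level, scan geometry for IPI and saccade velocity) the
first-order coefficients make the direction exact and the magnitude
approximate (about +-20%), which the tests acknowledge by asserting
direction and ordering there and full recovery on the level channels.

What the generator does *not* emulate: the camera/homography chain (gaze
is emitted directly in screen coordinates), age and gender structure,
motivational drift across a session, and device dropouts beyond blinks.
Passing tests therefore show that the pipeline recovers what the model of
the data contains — not that the model captures every property of real
child recordings.

## Problem sizes and numerical choices

The test suite and the acceptance script run the recovery check under the
study conditions (20 cohorts of 40 participants, planted HR effect
d = 0.8/0.5/0.3) and the null calibration on 50 smaller cohorts of 12
participants — the false-positive level of a Bonferroni-controlled family
does not depend on the cohort size, so the null check spends its budget on
more replicates rather than larger ones. The demo cohort in `analysis/`
uses 12 participants for the same reason. Statistical acceptance bounds
are set from sampling theory at these sizes (binomial 99.9% bounds for
rate checks; seed-averaged estimates where single-replicate spread is
legitimately wide) and were chosen together with the sizes, not adjusted
afterwards.

Degenerate inputs have defined behavior throughout: constant MinMax groups
map to 0 with a flag, zero-SD baselines divide by 1 with a flag, windows
with no saccades or no categorized transitions yield missing markers, an
all-invalid gaze stream yields an empty flagged event list, and a label
with fewer than two observations marks the test untestable, which the CFE
classifier reports as None with a reason.

## Known limitations

* Phase-labeled 10 s windows overlap the neighbouring phases (the midpoint
  rule), so a Move-labeled window carries several seconds of See-Solve
  data; the effective between-phase contrast is thinner than the planted
  one, which is the main ceiling on recovery power.
* Permutation importance on leave-one-participant-out validation sets
  (10-30 cycles) is noisy per fold; stability comes from averaging over
  folds, and rank-level conclusions should be read at top-set granularity
  rather than single-rank precision.
* AR/GARCH features are mostly missing at the default per-question series
  length; the per-game pooling switch trades temporal resolution for
  feature availability.
* The generator's effect calibration is exact for level channels and
  first-order for rate/geometry channels; planted-d recovery tolerances
  reflect that asymmetry.
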