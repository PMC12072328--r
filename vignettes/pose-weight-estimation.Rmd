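---
title: "Pose-based pediatric weight estimation: model, assumptions, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pose-based pediatric weight estimation: model, assumptions, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pedipose)
```

## The estimation problem

Emergency pediatric dosing needs a weight when none can be measured.
Two estimators are implemented and compared on identical terms:

* a **length-zone tape**: the child's supine length selects one of a
  fixed set of contiguous length intervals, each carrying a single
  weight (valid only on the tape's 45.9–146.5 cm domain);
* a **pose-based estimator**: 17 photographic body keypoints plus sex,
  age and visually assessed body habitus feed a small feedforward
  network that predicts stature, which a growth reference converts to
  weight.

The package's job is to make both estimators, and the agreement
statistics used to compare them, fully testable against synthetic
ground truth.

## The two-stage weight model

### Stage 1: height regression

The feature vector has 21 entries: the 16 Euclidean distances between
anatomically connected keypoints in normalized image coordinates,
followed by sex (male 0, female 1), age/155 (age in months scaled by
the maximum modeled age), and a one-hot habitus triple. The regressor
is a fully connected network 21 → 256 → 128 → 1 (ReLU hidden layers,
linear output) trained by minibatch Adam on mean-squared error with
dropout on the hidden layers and early stopping on a held-out split.

An important property of this design is that pure \[0,1\]
normalization of keypoints discards absolute image scale: the network
must reconstruct size from body *proportions* (which change
systematically with age — see the renderer below) and from the
metadata. With a roughly standardized camera distance, normalized
distances retain a scale signal as well; the capture model treats the
residual distance variation as a log-normal scale jitter.

### Stage 2: growth-reference conversion

The growth chart stores, per sex and month of age (1–155), the median
and coefficient of variation of height and weight under a log-normal
percentile model: the *p*-quantile at a cell with median *m* and
coefficient of variation *c* is
`qlnorm(p, log(m), sqrt(log(1 + c^2)))`, so the 50th percentile is the
median exactly and all quantiles are strictly positive. Habitus bands
are anchored at weight-for-age percentiles: thin strictly below the
25th, overweight strictly above the 75th, normal in between with both
boundaries inclusive.

A predicted height ĥ is mapped to the (fractional) age whose median
height equals ĥ, by linear interpolation on the median curve; the
weight estimate is the weight-for-age quantile at that age, at the
band's representative percentile — 12.5 % / 50 % / 87.5 %, the band
midpoints. These are configurable (`band_percentiles`) because any
single-number summary of a band is a modeling choice, not a fact.

**Why height and not weight?** Both modes exist
(`mlp_config(target = )`). Height is the default because the
photograph measures geometry: stature is what the keypoints determine,
and the growth reference is the principled bridge from stature and
habitus to weight. Direct weight regression is retained for users who
prefer a single-stage model; in that mode the reported height is the
chart inverse of the predicted weight.

## Tunable parameters

| parameter | default | units | rationale |
| --- | --- | --- | --- |
| `hidden_units` | 256, 128 | – | two hidden layers; small enough for on-device inference |
| `dropout_rate` | 0.1 | – | mild regularization for small training sets |
| `learning_rate` | 0.001 | – | Adam step size |
| `epochs` / `patience` | 200 / 20 | epochs | patience ≈ 10 % of the budget |
| `batch_size` | 16 | rows | small-batch regime |
| `split_fraction` | 0.8 | – | 80:20 split; `floor()` on the training side, so 278 rows split 222/56 |
| `band_percentiles` | 0.125/0.5/0.875 | fraction | habitus-band midpoints |
| `rank_rho` | 0.7 | – | Spearman correlation of height and weight percentiles in the generator |
| `assessor_error_rate` | 0.15 | fraction | probability a visual habitus call lands in an adjacent band |
| capture noise | jitter sd 0.08, rotation sd 3°, landmark sd 3 px | see below | plausible hand-held capture |

## What the synthetic generator emulates — and what it does not

`sample_cohort()` draws ages from three strata (1–12, 13–71, 72–155
months) with the mix of a pediatric emergency cohort (fractions
150/825/360 of 1335), balanced sex, and a latent habitus percentile
uniform on (0.02, 0.98). Height is the height-for-age quantile at the
latent percentile; weight is the weight-for-age quantile at a
percentile coupled through a Gaussian copula with Spearman correlation
0.7 (converted internally to the corresponding Pearson correlation),
reflecting that tall children tend to be heavy but habitus varies.
The recorded body type is the chart classification of the sampled
weight, flipped to an adjacent band with probability 0.15 by default:
visual habitus assessment after brief training is imperfect, and an
idealized error-free assessor would understate real-world difficulty.
The chart's weight coefficient of variation rises from 0.11 in infancy
to 0.21 at twelve years, matching the dispersion real weight-for-age
references reach by school age.

`render_pose()` places keypoints by body-segment proportions: the head
falls from ~1/4 of stature at 1 month to ~1/7 at 12 years (linear in
log-age) and the leg share of the remainder grows correspondingly, so
proportions carry an age/size signal exactly as infant anatomy does.
The crown of the head is placed at the nose keypoint so the
nose-to-ankle span equals stature; the figure is scaled by
`pixels_per_cm × exp(N(0, scale_jitter_sd))` (monocular distance
ambiguity), rotated, translated, and perturbed with iid Gaussian pixel
noise. Off-image points are clamped to the border and flagged with low
confidence.

The generator deliberately does **not** emulate: flexed or occluded
limbs, clothing, perspective foreshortening, pose-detector failure
modes (confidences are decorative, not model-driven), or real
reference-population data — the growth chart is a smooth parametric
stand-in whose file format accepts real tables. Passing tests
therefore demonstrate that the pipeline recovers parameters under its
own generative assumptions, not that it performs clinically.

## Numerical choices

* **Internal standardization.** Features and targets are z-scored
  inside `mlp_train()` (constants stored in the checkpoint, undone at
  prediction). With raw centimeter-scale targets, Adam's
  magnitude-bounded steps at learning rate 0.001 would spend ~10⁵
  steps just reaching the target mean. Reported losses are
  back-transformed to original units.
* **Determinism.** Every stochastic component (cohort, renderer,
  split, initialization, shuffling, dropout masks) runs under an
  explicit seed via `withr::with_seed()`, so cohorts are byte-identical
  and training curves repeat exactly. Inference never draws random
  numbers: two predictions on one input are bit-identical.
* **Early stopping** tracks the validation minimum and (by default)
  restores that epoch's deep-copied parameters;
  `restore_best = FALSE` returns the final state, which is what
  optimizer-convergence checks (e.g. fitting a noiseless line to below
  1 % of the target SD) should measure.
* **Divergence guard.** A non-finite loss aborts with the epoch index
  rather than propagating NaN.
* **Degenerate inputs.** Constant feature columns get unit scale
  instead of 0; constant targets likewise. Charts validate strict
  monotonicity of medians and CV ∈ (0, 0.5); zone tables validate
  contiguity, monotone weights and the exact tape domain; pose frames
  validate the exact 17-keypoint schema.
* **Boundary conventions.** PW thresholds are inclusive (an error of
  exactly 10 % counts as "within 10 %"); the final length zone is
  upper-inclusive at 146.5 cm so the domain is closed; habitus-band
  boundaries belong to "normal".
* **SD convention.** The Bland–Altman SD divides by *n* (population
  convention) by default, which makes `rmse² = mean_diff² + sd²` an
  exact identity — the engine behind reconstructing an RMS error from
  printed limits of agreement. The sample convention is available
  (`sd_type = "sample"`); the identity then holds only approximately.
* **Percentages** in the cohort summary are rounded half-to-even to
  one decimal (R's `round()`); raw fractions are kept in the numeric
  columns. Quantiles use linear interpolation (`type = 7`).

## Open design points, resolved

* **ICC form.** Two-way, absolute-agreement, single-measures —
  ICC(A,1) — because method-versus-reference agreement must penalize
  systematic offsets, which consistency forms forgive. Confidence
  intervals use the F-method with Satterthwaite degrees of freedom.
* **Difference direction** is predicted − actual throughout, so a
  positive MPE and a positive Bland–Altman mean both read
  "overestimates".
* **Subgroup gap.** Stratum labels phrased as "1–12 months" and "2–5
  years" leave 13–23-month-olds unassigned; they are placed in the
  middle stratum so the partition is exhaustive (subgroup n's must sum
  to the total).
* **Sample-size formula.** The standard normal-approximation
  two-proportion formula gives 356 per group (712 total) for 60 %
  versus 70 % at two-sided α = 0.05 and power 80 %, confirmed by exact
  binomial power search (power 0.8013 at 356, 0.7999 at 355). Other
  conventions — continuity correction, unpooled variance, attrition
  inflation — yield larger totals; published studies quoting a
  different number for these inputs likely used one of those, and this
  operation implements only the standard formula.

## Problem sizes

The parameter-recovery runs use 1000-subject cohorts with an 80:20
split, chosen as the smallest size at which the stratified age mix is
well represented and the validation MAPE estimates are stable to well
under a percentage point across seeds. Under zero capture noise and an
error-free assessor the trained height model reaches validation MAPE
well under 3 %; under the default capture noise the end-to-end weight
MAPE sits near 9 % with ICC ≈ 0.96 — the same regime the estimator's
clinical analogues report. The property suites run 1000 random paired
datasets (metric inequalities), 20 random ICC fixtures against an
ANOVA mean-squares oracle at 10⁻⁹, and 1000 random lengths against a
linear-scan zone lookup.

## Known limitations

* The growth chart, pose proportions and capture noise are synthetic;
  swapping in real reference tables and real keypoints changes all
  absolute numbers.
* Keypoint confidences are generated but not consumed: no
  confidence-weighted distances or missing-landmark imputation —
  frames with missing keypoints are schema errors by design.
* Monocular scale is modeled, not resolved; with genuinely
  uncontrolled camera distance, the pose features alone cannot
  identify stature and accuracy will degrade toward what metadata
  alone supports.
* ICC p-values test the null of zero correlation, which is rarely the
  clinically relevant question; the confidence interval and band are
  the quantities to read.
* Continuous retraining from field data, equipment-size
  recommendations per zone, and regression-based Bland–Altman
  (proportional bias) are out of scope.
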