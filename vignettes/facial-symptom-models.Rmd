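---
title: "Predicting SCL-90 symptom dimensions from facial key-point motion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting SCL-90 symptom dimensions from facial key-point motion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(facemotion)
```

## The problem

Self-report instruments such as the Symptom Checklist-90 (SCL-90) quantify
mental-health symptoms along several dimensions at once. Digital phenotyping
asks whether passively observable behaviour — here, the motion of 36 facial
key points tracked in 3D by a depth camera at 30 Hz while a participant
reads a neutral text — carries enough information to predict those
dimension scores. `facemotion` implements the full analysis pipeline for
six SCL-90 dimensions (interpersonal sensitivity, depression, anxiety,
hostility, phobic anxiety and psychoticism; 55 five-point Likert items in
total) and, just as importantly, the psychometric evaluation of the
resulting prediction models: if a "depression model" is to be taken
seriously as a measurement instrument, it should be assessed like one —
with reliability and validity coefficients, not only prediction error.

Because raw recordings from such studies are not generally shareable, the
package pairs the analysis pipeline with a synthetic cohort generator whose
ground truth is known. Every claim the test suite makes about the pipeline
is established on that generator.

## The pipeline

**Preprocessing.** For each participant's recording, (1) every frame is
translated so that key point 0 (the nose tip) is the origin — this removes
rigid head translations exactly; (2) each interior frame is replaced by the
average of its predecessor, itself and its successor, suppressing frame
noise; (3) frames at 0-based positions [100, 700) are retained, dropping
preparation time — exactly 600 frames ("whole" data); (4) adjacent frames
are subtracted, giving 108 coordinate-change series (36 points × 3 axes) of
length 599. Frames at even and odd positions within the window form two
300-frame "split-half" recordings, differenced to 299 changes each. The
window is read as half-open because the source protocol counts exactly 600
retained frames; the parity split operates on frames *before* differencing,
since the alternative (difference first) cannot produce two equal 300-frame
halves.

**Features.** Each change series is summarised by a catalogue of 30
time-series characteristics (maximum, minimum, mean, variance, standard
deviation, skewness, kurtosis, median, absolute energy, absolute sum of
changes, a variance-exceeds-sd indicator, counts and longest runs above and
below the mean, relative first/last locations of the extrema, duplication
indicators, mean (absolute) change, reoccurrence ratios and sums, the total
and the range). The feature matrix is participants × 3,240 columns
(3 axes × 36 points × 30 characteristics), with a stable point-major,
axis-middle, characteristic-minor column order shared by all variants.

Estimator conventions that the catalogue's names leave open are fixed as
follows: variance uses the population denominator; skewness is the adjusted
Fisher–Pearson sample estimator and kurtosis the adjusted sample excess
estimator, both defined as 0 for constant series so that the identically
zero series of the reference point never produce non-finite features;
"first" locations are 0-based indices divided by the length, "last"
locations 1-based; the two reoccurrence sums are distinguished as
with-multiplicity versus per-unique-value, preserving the 30-characteristic
count; booleans are encoded 0/1. The catalogue lists two near-synonymous
sums deliberately; each is implemented per its distinct meaning. These
choices are fixed rather than configurable: a single code path is what the
independent-oracle equivalence tests certify.

**Models.** For each dimension, the 50 features with the largest univariate
regression F value against the raw subscale score are selected (ties broken
by canonical column order; perfectly correlated features carry an infinite
F and sort first), standardised by their whole-data mean and standard
deviation, and fed to a LASSO regression minimising

$$\sum_{i=1}^N \Big(y_i - \beta_0 - \sum_j x_{ij}\beta_j\Big)^2 + \lambda \sum_j |\beta_j|,$$

with the intercept unpenalised. The penalty is tuned on a grid of 100
log-spaced values from $\lambda_{\max}$ (the smallest penalty that zeroes
every coefficient) down to $10^{-4}\lambda_{\max}$ by five-fold
cross-validation, choosing the mean out-of-fold MSE minimiser and breaking
exact ties toward the larger penalty. Each participant's predictions — for
the whole data and both split halves — come from the fold model that never
trained on them. The solver is a cyclic coordinate descent with warm starts
along the path; convergence is declared on the change in fit relative to
the outcome deviance, which keeps it robust to the exactly collinear column
pairs the catalogue produces (for example, the absolute sum of changes and
the mean absolute change of the same series). At $\lambda = 0$ it agrees
with ordinary least squares, and on orthonormal designs with the
soft-thresholding closed form, to $10^{-6}$; both facts are asserted in the
test suite, along with agreement with an independent LASSO implementation
at matched penalties.

**Evaluation.** Split-half reliability ($R_1$) is the Pearson correlation
between odd-half and even-half predictions of the same dimension; criterion
validity ($R_2$) the correlation between whole-data predictions and actual
raw scores. A 12 × 12 multitrait-multimethod (MTMM) matrix over the six
model predictions and six subscale scores supports convergent and
discriminant verdicts: a dimension converges when its validity-diagonal
entry (same trait, different method) strictly exceeds every different-trait
different-method correlation in its row and column, and discriminates when
it strictly exceeds every same-method different-trait correlation involving
it. Reliability is reported uncorrected (a Spearman–Brown column is
provided, clearly labelled); verdicts use strict numeric comparison since
no inferential test accompanies the published rule; two-sided p values are
attached to every correlation.

## The synthetic cohort generator

The generator emulates only the statistical structure the analysis relies
on, not faces:

* **Traits.** Six standard-normal latent severities per participant, drawn
  from a multivariate normal whose default correlation matrix spans
  0.30–0.70 — the band community samples show between SCL-90 subscales.
* **Items.** Each of the 55 items cuts `trait + N(0, 1)` at
  (−1.5, −0.5, 0.5, 1.5) into a 1–5 response: the simplest monotone ordinal
  map; a subscale's raw score then correlates about 0.8 with its trait.
* **Recordings.** Per frame, each key point is its anchor position plus a
  rigid head-translation random walk shared by all points (per-step SD
  1 mm), a stationary AR(1) wobble (coefficient 0.8, baseline SD 2 mm) and
  independent jitter (SD 0.5 mm). A point's wobble amplitude is
  `baseline × max(0, 1 + effect × trait × side_weight)`, with side weight
  `2 × laterality` on the left half of the face, `2 × (1 − laterality)` on
  the right and 1 on the midline (default laterality 0.8, echoing the
  left-face dominance reported for real data). Each mirrored left/right
  point pair is modulated by exactly one dimension, assigned round-robin in
  the packaged schema. This per-point assignment is deliberate: if every
  trait modulated every point identically, all six models would learn the
  same composite signal and convergent validity could never hold, so
  distinct facial signatures are the minimal extra assumption the recovery
  checks require. Recordings default to 720 frames (24 s), comfortably
  above the 700-frame inclusion bound.

What the generator does *not* model — facial geometry and rotation,
expression dynamics, tracking dropouts, autocorrelated measurement error,
demographic structure — bounds what green tests mean: they certify the
pipeline's arithmetic, its invariances (head-motion nulling, permutation
invariance, determinism under seeds) and its behaviour under planted signal
and under the null, on data whose generating process is known. They say
nothing about whether real faces carry symptom information.

Two effect-size regimes are used. The default, `effect_size = 0.15`, is a
deliberately clear signal for recovery checks: criterion validity
approaches 0.9 and all six dimensions converge. A calibrated weak regime,
`effect_size = 0.02` under leakage-free evaluation, reproduces the 0.2–0.5
criterion-validity band reported for real facial data, which is the regime
to use when one wants the synthetic cohort to *feel* like the real study.

## Leakage, and what the null teaches

The reference protocol selects features and fits the standardiser on the
*full* whole-data matrix before cross-validation. The package replicates
this by default, and exposes `strict_cv = TRUE` to refit selection and
scaling inside each training fold. The difference is not cosmetic: on
cohorts with **no** facial signal at all (`effect_size = 0`), the default
protocol still produces out-of-fold criterion correlations around 0.66,
because choosing 50 of 3,240 features by their whole-sample association
with the outcome plants that association in every held-out subset. Any
criterion validity reported under such a protocol is uninterpretable
without this null baseline. Under `strict_cv = TRUE` the same null cohorts
give criterion correlations centred near zero — but not *at* the nominal
5% false-positive rate, for a structural reason worth understanding:
under the null, cross-validation usually picks the full-shrinkage penalty,
making predictions constant within each fold (the training-fold mean).
Such predictions are anti-correlated with the held-out outcomes at about
−0.22 for five folds of 100 participants — beyond the 0.197 two-sided
critical value — so the exceedance rate of the honest pipeline sits far
above 5%. Likewise split-half reliability does not vanish under the null:
when every coefficient is zero the odd- and even-half predictions coincide
exactly ($R_1 = 1$), and even with non-zero coefficients both halves share
each recording's realised motion. High $R_1$ certifies measurement
stability, not the presence of symptom signal. The test suite states these
nominal-rate expectations as acceptance assertions and they fail; the
failures are retained as an honest record of the pipeline's null
behaviour rather than being tuned away.

## Numerical and design notes

* Windowing, smoothing edges: the first and last frames pass through the
  smoother unchanged; harmless, as the [100, 700) window never touches
  recording edges. Smoothed values can differ from exact constants by one
  ulp, so "all-zero" assertions on simulated stillness use tolerances.
* Fold assignment is a seeded uniform permutation into folds whose sizes
  differ by at most one; no stratification is applied because none is
  described for the reference protocol.
* One penalty per dimension is tuned globally across folds (the most
  common reading of "cross-validation was used to adjust model
  parameters"); the split-half rows are predicted by the held-out fold's
  model to preserve their out-of-sample character.
* Outcomes are raw subscale scores, matching the published score
  intervals; factor scores are provided by the scorer but not modelled.
* The reference-point coordinates (point 0) difference to identically zero
  series; their features are retained so the matrix keeps its 3,240-column
  schema, and their zero-variance columns standardise to zero rather than
  NaN.
* Problem sizes in the shipped checks: the oracle suite runs 1,000 random
  series of lengths 2–600; the null calibration runs 200 cohorts of 100
  participants; recovery checks use cohorts of 100. These sizes make the
  Monte-Carlo bands in the assertions meaningful at reasonable runtime.

## A worked example

```{r example, eval = FALSE}
study <- run_study(n = 100, seed = 1)
tidy(study$eval)
autoplot(study$eval$mtmm)
plot_selected_sides(study$fit)
```

`run_study()` generates a cohort, applies the inclusion rules (all-minimum
or all-maximum response patterns and recordings under 700 frames are
excluded), scores the scale, builds the three feature matrices, fits the
six models and evaluates them. The packaged reference matrix — the MTMM
table printed by a published facial-movement study of these six
dimensions — exercises the assessment half alone:

```{r reference}
ref <- read_mtmm(system.file("extdata", "reference_mtmm.csv",
                             package = "facemotion"))
validity_diagonal(ref)
assess_convergent(ref)
```

Its validity diagonal spans 0.26–0.42, and exactly one dimension —
depression — fails the convergent rule, while several fail the
discriminant rule: the familiar picture for instruments whose subscales
are themselves highly intercorrelated.

## Known limitations

The generator's linear trait-to-amplitude link matches the linearity
premise of the modelling approach but cannot probe misspecification; the
split-half design shares a single recording session, so $R_1$ overstates
test–retest stability; and the convergent/discriminant verdicts use strict
numeric dominance, not a dependent-correlation test, mirroring the
published rule rather than improving on it.
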