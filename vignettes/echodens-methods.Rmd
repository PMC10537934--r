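---
title: "Predicting percent mammographic density from ultrasound gray-level bins"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting percent mammographic density from ultrasound gray-level bins}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Percent mammographic density (PMD) — the fraction of fibroglandular
tissue area on a mammogram — is one of the strongest image-derived risk
factors for breast cancer, but mammography involves ionizing radiation.
B-mode breast ultrasound is radiation-free and cheap, and fibroglandular
tissue is echogenic (bright) while fat is hypoechoic (dark), so the gray
level composition of an ultrasound image plausibly carries information
about density. `echodens` implements a complete, reproducible pipeline
for testing how much: gray-level histogram features are extracted from a
standardized region of interest of five views per breast, and a ladder of
regression models is benchmarked against the PMD outcome with repeated
cross-validation.

Because no public image cohort accompanies this protocol, the package
includes a first-class synthetic-cohort generator with full ground truth.
Every stage — image I/O, ROI extraction, feature pooling, model fitting,
evaluation — is exercisable and testable without any download, and the
generator's known generative parameters supply the oracles for recovery
tests.

## Measurement protocol

1. **ROI.** The breast tissue between the skin line and the pectoral
   muscle is the region of interest. Within the ROI mask, the biggest
   axis-aligned rectangle is selected (`largest_rectangle()`, the
   row-stacked histogram method, `O(rows × cols)`). Ties on area are
   broken deterministically: smallest top row, then smallest left column,
   then largest height. Coordinates are 1-based and inclusive, the native
   convention for R matrices.
2. **Histogram.** The 256-level gray histogram of the rectangle is
   counted exactly per view; the five per-view histograms of a breast are
   pooled by summation into one combined histogram
   (`pool_histograms()`). Pooling counts before normalizing is the
   algebraically consistent reading of "combined by summation": the
   pooled bin percentages equal the pixel-weighted mean of the per-view
   percentages, which a test verifies.
3. **Bins.** The 0–255 spectrum is divided into 16 equal categories of
   16 consecutive gray levels, ordered white (bin 1 = 240–255) to black
   (bin 16 = 0–15), and each bin's percentage of ROI pixels is the
   feature. The 16 percentages sum to 100 by construction, so the 16th
   (darkest) bin is redundant and bins 1–15 are the model predictors.
   The orientation is a pure labelling convention — omitting the darkest
   rather than the whitest bin changes no model content — and the
   Spearman profile therefore reports both labelings.

## The model ladder

All models regress PMD (fraction scale) on the 15 bin percentages:

| id | family | data-dependent choices |
|----|--------|------------------------|
| M0 | intercept only | training mean |
| M1 | OLS, 15 bins | — |
| M2 | M1 + backward elimination | AIC (k = 2) |
| M3 | natural cubic spline per bin, 2 df | knots from training data |
| M4 | M3 + backward elimination | whole 2-column spline groups, AIC |
| M5 | lasso | penalty by inner 10-fold CV, min-MSE |
| M6 | ridge | penalty by inner 10-fold CV, min-MSE |
| M7 | random forest | 500 trees, mtry 5, node size 5 |

Design choices that the protocol leaves open, fixed here once:

* **Stepwise criterion.** "Backward selection" is implemented as
  `stats::step` with AIC (k = 2). M4 drops whole spline term groups,
  never single basis columns, so a bin is either modelled flexibly or
  not at all.
* **Spline type.** The natural (restricted) cubic spline with 2 degrees
  of freedom: one interior knot at the training median, boundary knots at
  the training range. Validation data are evaluated with the training
  knots via R's safe-prediction machinery. A constant training column
  cannot support a spline and falls back to a linear term with a warning.
* **Penalty grids.** glmnet's data-driven path with 100 log-spaced
  values down to `1e-6` of the maximal penalty (six orders of magnitude);
  predictors are standardized internally. An explicitly supplied
  single-value grid bypasses the inner CV; for ridge this single-penalty
  case is solved in closed form (SVD pseudo-inverse), which makes the
  identity ridge(λ=0) = OLS exact rather than approximate.
* **Forest settings.** Conventional regression defaults (500 trees,
  ⌊15/3⌋ = 5 candidate predictors per split, minimum node size 5); the
  benchmark compares fixed model classes, not tuned ones.
* **Degenerate designs.** Rank-deficient fits fall back to R's pivoted
  least squares (aliased terms dropped, warning logged); a saturated
  design that makes AIC −∞ keeps the full model with a warning.
* **Clipping.** Predictions are *not* clipped to [0, 1] by default:
  MSE/R² of raw model output is the conventional benchmark quantity.
  `predict(fit, clip = TRUE)` restricts to the unit interval.

## Evaluation

Performance is measured by MSE and R² = 1 − MSE/Var(y), with the
population variance (divisor n) of the observed outcome. On training
data the null model's R² is exactly 0; on held-out data R² can be
negative — the model predicts worse than the validation mean.

`repeated_cv()` runs the 100 × 3-fold protocol: each repetition draws a
fresh random partition into three near-equal folds, every model is
rebuilt from scratch on two folds (selection, tuning and knot placement
included — no leakage) and scored on the third. Apparent measures come
from fitting and scoring on the complete data; the model with the
smallest cross-validated MSE is flagged as final.

Two aggregation rules are implemented because the protocol does not pin
one down: the default computes R² within each held-out fold (fold-local
variance) and averages the 300 fold values — this reproduces the
characteristic slightly negative cross-validated R² of the null model,
since the training-fold mean is always a worse predictor of a fold than
the fold's own mean; the alternative (`aggregation = "pooled"`) pools
squared errors and relates them to the whole-cohort variance, making
"lower MSE ⇔ higher R²" an exact identity. The fold-partition RNG stream
is independent of the model RNG streams, so model suites are comparable
on identical partitions.

`spearman_profile()` gives the per-bin rank correlation with PMD
(average ranks on ties; constant bins are reported as missing with a
warning, not silently dropped). `holdout_illustration()` draws a single
2/3–1/3 train/validation split for the predicted-versus-observed scatter
of the final model.

## The synthetic cohort

`generate_cohort()` emulates, per patient:

* a **latent density** *d* from a Beta prior moment-matched to mean
  0.422 and variance 0.0396 (fraction scale) — the minimal
  bounded-support distribution reproducing the reported location and
  spread of screening-cohort PMD. On the fraction scale the null model's
  training MSE equals this variance, which anchors the scale of all MSE
  results.
* a **two-reader outcome**: two independent Gaussian perturbations of
  *d* (sd `reader_sd` = 0.03), truncated to [0, 1], averaged.
* **five views**, each a 400 × 400 8-bit image with a bright skin band,
  a dark muscle band, and between them a two-tissue field: a spatially
  correlated binary texture (a smoothed Gaussian field with correlation
  length `blob_scale`, thresholded at its (1 − p)-quantile) assigns each
  ROI pixel the fibroglandular or fat mean gray, where
  p = `signal_strength`·d + (1 − `signal_strength`)·0.5 + a per-view
  jitter. Every pixel is multiplied by gamma speckle with unit mean and
  shape 4 — a standard B-mode intensity model — then rounded and clipped.
  The ROI mask marks exactly the rows strictly between the bands.

Quantile thresholding makes the realized bright-tissue fraction equal p
up to pixel granularity, so the per-view fractions recorded in the truth
tables are exact. How disagreeing human annotators would be reconciled
is not modelled: one mask per image is emitted.

**Why the defaults are weak-signal.** A pooled rectangle contains on the
order of 10⁵ pixels, so the bin features estimate the bright-tissue
fraction almost noiselessly; the only density-irrelevant variation is
the per-view jitter, amplified by 1/`signal_strength` when inverting p
for *d*. The defaults `signal_strength = 0.12` and
`view_jitter_sd = 0.08` were chosen analytically so that the best
attainable (Bayes) out-of-sample R² of a default cohort is ≈ 0.31:
shrinking the five-view estimate toward the prior gives error variance
(1/0.0396 + 1/((0.08/(0.12·√5))²))⁻¹ plus reader noise ≈ 0.0278 against
an outcome variance of ≈ 0.040. That places default cohorts in the same
regime the protocol was designed for in vivo — echotexture only weakly
predictive of mammographic density — rather than in an unrealistically
clean one. Setting `signal_strength = 0` severs the texture–density link
entirely and is the package's negative control.

**What the generator does not emulate.** Real speckle is spatially
correlated and depth-dependent; gain and time-gain compensation vary per
acquisition; skin and muscle boundaries are curved and must be found, not
known; true tissue composition is not a stationary two-phase field; and
the bin–density relation in vivo need not be linear in any latent
variable, so on real cohorts a flexible model can beat the linear ones.
Passing recovery tests therefore
demonstrates the pipeline's correctness and calibration on a controlled
data-generating process, not clinical validity of ultrasound densitometry.

## Numerical and runtime choices

* All percentages are carried at full double precision; nothing is
  rounded before modelling.
* Fold sizes differ by at most one; every observation is validated
  exactly once per repetition.
* All randomness flows from explicit seeds (generator, partitions,
  per-fit model streams are separate, derived sub-streams), so every
  output — including written CSV/PNG artifacts — is byte-reproducible
  from a configuration.
* The test suite runs reduced problem sizes chosen to preserve the
  tested property: 20 CV repeats instead of 100 where only the mean
  matters, 120-pixel images where geometry is immaterial, 10³ patients
  for the signal-knob correlation checks, 10⁵ draws for moment checks.
  Full-scale runs (n = 168, 400 × 400, 100 × 3 CV) are the default in
  `run_pipeline()` and `scripts/acceptance.R`.

## Limitations

* The generator's texture–density coupling is linear in the latent
  density by construction, so flexible models can only lose to linear
  ones on synthetic cohorts; the benchmark's ordering on real data may
  differ (and in the motivating study it did).
* The ROI rectangle is chosen per view and pooled afterwards; selecting
  one rectangle in a merged multi-view ROI is a defensible alternative
  the protocol wording leaves open.
* The two-reader model is additive Gaussian with a single
  `reader_sd`; systematic inter-reader bias is not modelled.
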