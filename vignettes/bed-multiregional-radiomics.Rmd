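---
title: "BED-based multiregional radiomics for radiation pneumonitis risk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{BED-based multiregional radiomics for radiation pneumonitis risk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bedrad)
```

## The problem

Symptomatic radiation pneumonitis (SRP, CTCAE grade >= 2) is the most common
toxicity of stereotactic body radiotherapy (SBRT) for lung tumours, with
reported incidences around 9-28%. Classical predictors are dose-volume
histogram (DVH) scalars of the nontarget lung — V5, V20, mean lung dose —
computed on the *physical* dose. SBRT, however, is delivered in widely
varying fractionation schemes (here 4-12 fractions of 6-12.5 Gy), and the
biological insult to late-responding lung tissue depends strongly on the
fraction size. The linear-quadratic (LQ) model normalizes this through the
biologically effective dose,

$$\mathrm{BED} = n\,d\left(1 + \frac{d}{\alpha/\beta}\right),$$

with $n$ fractions of size $d$ and the tissue-specific $\alpha/\beta$ ratio
(~3 Gy for late-responding lung, ~10 Gy for tumour). `bedrad` implements a
risk-modelling pipeline in which the lung is analysed not only anatomically
but also through subregions defined by physical dose (D5, D20: lung
receiving >= 5 / 20 Gy) and by biological dose (B70: lung with BED$_3$
>= 70 Gy), with radiomic texture features extracted per region, a four-stage
feature-selection cascade, per-region and fused classifiers, and a combined
radiomic + dosimetric model.

Because no patient-level data are released with the study this package
emulates, every stage is exercised end-to-end on a synthetic thoracic
phantom cohort generator that is itself a first-class, tested module.

## Voxelwise BED and the iso-BED inverse

Physical dose grids are converted voxel by voxel with the per-voxel fraction
size $d_v = D_v / n$ (uniform fractionation — the planning system's
per-fraction grids are not available, so the total grid is divided evenly).
The conversion is strictly monotone in dose, so iso-BED regions can
equivalently be built by thresholding the physical dose at the closed-form
inverse

$$D = \frac{n\,\alpha/\beta}{2}\left(-1 + \sqrt{1 + \frac{4\,\mathrm{BED}}
{n\,\alpha/\beta}}\right),$$

and the test suite asserts the two constructions agree voxel for voxel. The
pipeline builds B70 from the BED grid; the inverse is kept as an independent
oracle (and is useful in its own right: for 4-12 fractions the physical dose
reaching BED$_3 = 70$ Gy is always above 23 Gy, which is why B70 nests
inside D20).

A note on conventions: the source literature is inconsistent about the lung
$\alpha/\beta$; following the dominant usage we compute all lung V\_BEDx and
B70 quantities at $\alpha/\beta = 3$ Gy and the tumour BED at 10 Gy. Both
are arguments, not constants. DVH comparisons are inclusive (>=), which
makes the volume at 0 Gy exactly 100% and keeps the two B70 constructions
exactly equivalent.

## The synthetic phantom cohort

`generate_phantom()` builds, on a 64^3 grid of 2.5 mm isotropic voxels
(160 mm field of view, matching the 2.5 mm dose-grid resolution typical of
SBRT planning), two ellipsoidal lungs of low intensity (-800 HU), a
spherical GTV placed uniformly inside one lung, and a PTV obtained by
anisotropic dilation with 3 mm lateral / 5 mm craniocaudal margins
(implemented as a scaled-spacing Euclidean distance transform, i.e. an
ellipsoidal structuring element). Lung texture is a stationary Gaussian
random field (FFT-filtered white noise) whose correlation length varies per
patient; this gives texture features non-degenerate between-patient
variance. An internal target volume is deliberately not modelled — motion
summation adds nothing to the pipeline under test — so the PTV dilates the
GTV directly.

`generate_dose()` is an analytic stand-in for a treatment planning system:
prescription dose inside the PTV, exponential decay
$\exp(-\mathrm{dist}/\lambda)$ in the Euclidean distance to the PTV outside,
with falloff $\lambda$ sampled per patient from 6-12 mm. This produces
monotone, nested iso-dose shells with realistic V20 (~5-12% of nontarget
lung) and steep SBRT-like gradients; it does not reproduce beam arrangements,
build-up, or heterogeneity corrections, and nothing downstream assumes it
does.

Fractionation schemes are sampled from {10 x 6, 8 x 7.5, 5 x 10, 4 x 12} Gy
(probabilities 0.45/0.20/0.20/0.15), spanning the 4-12-fraction range with
tumour BED$_{10}$ near 100 Gy and a modal 10 x 6 scheme. Tumour radii are
uniform on 8-22 mm (diameters 16-44 mm, mean ~30 mm); baseline covariates
(age ~ N(73, 10) truncated to 39-94, 60% male, 33% COPD, ECOG 0/1/2 at
18/51/31%) match the published cohort marginals and carry **no** planted
effect, mirroring the finding that no baseline clinical characteristic was
associated with SRP.

SRP labels are drawn from a logistic model,

$$\mathrm{logit}\,p_i = \beta_0 + \beta_V \cdot V\_BED70_i +
\beta_T \cdot z_i,$$

where $V\_BED70$ is in percent of nontarget lung, $z$ is the
cohort-standardized GLCM contrast inside the patient's B70 region, and
$\beta_0$ is calibrated by bisection (tolerance 0.005) so the mean event
probability matches the target prevalence, 14.6% by default. The default
$\beta_V = \ln 4.84$ plants the published odds ratio per percentage point;
$\beta_T = 0$ by default, so the dosimetric signal is the sole risk factor
unless a texture effect is requested explicitly. When $\beta_T = 0$ the
generator skips CT synthesis entirely (the CT cannot influence labels or
dose metrics), which makes large calibration simulations cheap; the full CT
path is taken whenever a texture covariate is needed, and either path is
bit-reproducible from the manifest via `phantom_patient()`.

## Features

Per region, the extractor computes 70 features: 11 shape descriptors, 18
first-order statistics, and texture features from four matrix families
(GLCM 14, GLRLM 11, GLSZM 11, NGTDM 5), with intensities discretized at a
fixed 25 HU bin width (configurable). GLCM is symmetric, distance 1,
averaged over the 13 unique 3D directions; GLRLM counts are summed over the
same 13 direction families before features are taken; GLSZM zones use
26-connectivity. The texture matrices are exhaustively cross-checked against
brute-force enumeration on small toys in the test suite. This is a fixed,
documented feature set, not a reproduction of any external tool's
1,834-feature configuration: the published per-region count depends on an
undisclosed filtered-image configuration, and the selection cascade — not
the inventory — is the method under test. The bookkeeping convention
(features per region x ten regions) is exposed by `feature_bookkeeping()`.

Surface area uses the gradient-magnitude integral of the Gaussian-smoothed
(sigma 0.8 voxel) mask indicator, accurate to ~1-2% against analytic
spheres; since digitization can push a near-perfect sphere marginally past
the theoretical sphericity bound of 1, sphericity is capped at 1. The
maximum 3D diameter is approximated from extreme boundary voxels along 49
near-uniform directions. Regions smaller than 27 voxels (one 3x3x3
neighbourhood — texture matrices need at least one neighbourhood) return a
missing-value sentinel; those entries are imputed with the training-column
median before selection.

Composite regions (RA = anatomical; RAP = + physical dose; RAPB = + B70)
are represented as *concatenations* of their member regions' feature
columns, not as merged masks; the published feature arithmetic is ambiguous
on this point, and concatenation keeps region provenance intact for the
fusion stage. Z-score normalization uses training-split means and sample
standard deviations (n - 1) only; validation rows are transformed with the
frozen training parameters, and zero-variance training columns are dropped.

## Selection cascade and models

Selection runs entirely on training rows, in four nested stages:

1. **Welch t-test** per feature between outcome classes, keep p < 0.05 (the
   unequal-variance form, since the event class is small);
2. **Pearson pruning**: while any surviving pair has |r| > 0.9, remove the
   feature with the largest mean absolute correlation to the survivors
   (lexicographically later name on ties — fixed for determinism);
3. **mRMR** greedy forward selection, capped at one-tenth of the training
   sample size. Relevance is the absolute point-biserial correlation with
   the label (the same ranking as the one-way F statistic) and redundancy
   the mean absolute Pearson correlation with already-selected features,
   combined in the difference form. Both terms must live on the same
   bounded scale: with raw F statistics (hundreds) against correlations
   (at most 1), the redundancy penalty could never reject a near-duplicate
   of an already-selected feature;
4. **LASSO** logistic regression over glmnet's lambda path, lambda chosen by
   stratified 10-fold cross-validation minimizing the mean squared error of
   predicted probabilities (the minimum criterion; a 1-SE option exists).

Classifier families are logistic regression, RBF-SVM, random forest,
extremely randomized trees and gradient boosting (xgboost) — the last
standing in for any boosted-tree implementation — each grid-searched with
stratified 5-fold CV scored by AUC and refit on the full training split.
The logistic family carries its ridge penalty in the grid
(lambda in {0, 0.01, 0.1, 1}): fused composite models bring 10-30 features
against ~15 training events, where the unpenalized fit separates the
training split and collapses on validation, so the regularization strength
is tuned like any other hyperparameter.
Composite models rerun the LASSO on the concatenated member-region
selections. The dosimetric model is the univariate V_BED70 logistic
regression; the combined model stacks the radiomic model's predicted
probability (as a logit) with V_BED70 in a logistic regression. The stack is
fitted on *out-of-fold* base-model probabilities: fitting it on in-sample
probabilities lets an overfit radiomic model monopolize the stack, which is
exactly the failure mode stacking is meant to avoid.

One upstream description of hyperparameter tuning ("optimal model
parameters were selected based on their performance metrics in the test
set") would leak test information; this implementation selects
hyperparameters strictly by cross-validation inside the training split.

## Evaluation

ROC AUC is trapezoidal with mid-rank tie handling and a DeLong 95% CI
(pROC); the brute-force concordant-pair fraction serves as the test oracle.
Operating-point metrics (accuracy, sensitivity, specificity, PPV, NPV) are
reported at the Youden-optimal threshold frozen on the training split.
Calibration uses the Hosmer-Lemeshow decile-of-risk statistic
$\sum (O-E)^2 / (E(1 - E/n_g))$ on $\chi^2_{\mathrm{bins}-2}$, merging
empty-expectation bins. Decision-curve analysis reports net benefit
$TP/n - (FP/n)\,p_t/(1-p_t)$ on a 0.01-0.60 threshold grid against
treat-all and treat-none.

## Numerical and design notes

- **Distance transforms** are exact separable squared-EDTs (lower-envelope
  parabolas) with physical spacing, implemented in C++.
- **Resampling**: trilinear for intensities, nearest-neighbour for masks;
  the phantom is generated isotropic at 2.5 mm, so pipeline analyses run at
  the native lattice and the 1 mm resampling path is exercised separately
  (mask volumes are preserved within 5% for spheres >= 8 mm radius).
- **Problem sizes.** The simulation studies shipped with the package use a
  64^3 phantom grid, 144-patient modelling cohorts (split 100/44 by the
  stratified floor(0.7 n) rule), 500-patient cohorts for risk-factor
  recovery, and 10-50 replicates per property. These sizes give stable
  qualitative behaviour while keeping the full suite comfortably
  re-runnable.
- **Stepwise screen.** The multivariate clinical/dosimetric screen uses
  forward stepwise entry with backward removal (entry and stay at p = 0.05,
  after univariate entry at p < 0.01). With twenty nearly-collinear V_BEDx
  candidates, pure backward elimination from the full model is rank-deficient
  and separation-prone; forward stepwise is the stable classical choice (and
  is what the major statistical packages' "stepwise" procedures do). Even
  so, with neighbouring V_BEDx correlated at r > 0.98, the screen sometimes
  retains V_BED60 or V_BED80 in place of the generating V_BED70 in any
  single cohort; across replicates V_BED70 is the modal retained variable.
- **Known limitation — selection-before-CV leakage.** Because the t-test,
  pruning and mRMR stages are fitted on the same training rows that the
  LASSO's CV folds reuse, spurious features that survive the early stages
  carry winner's-curse correlation into every fold, and the cross-validated
  MSE genuinely decreases along the lambda path even for label-independent
  data. On pure-noise cohorts the cascade therefore retains its mRMR-capped
  candidate set far more often than a naive reading of "CV will shrink noise
  to zero" suggests. This is a faithful property of the published procedure,
  not of this implementation; the honest fix (re-running the full cascade
  inside each CV fold) is out of scope here. Consequently the package's
  null-cohort false-selection suite documents, rather than suppresses, this
  behaviour.
- **What passing tests do and do not show.** The phantom reproduces the
  *statistical structure* the analysis assumes — geometry, nested dose
  shells, a dosimetric risk factor with a texture co-factor, realistic
  prevalence — but not real CT appearance, respiratory motion, planning
  heterogeneity, or inter-scanner effects. Green tests demonstrate the
  pipeline's internal correctness and its qualitative orderings under
  planted signal; they are not evidence about real patients.

## A short session

```{r, eval = FALSE}
co <- generate_cohort(144, risk = risk_model_spec(beta_texture = 0.8),
                      seed = 1)
study <- srp_pipeline(co, algorithm = "logistic", seed = 1)
study$evaluation            # per-model training/validation AUC

rep_ <- evaluation_report(study$probabilities$combined[!study$train],
                          study$table$label[!study$train],
                          youden_threshold(
                            study$probabilities$combined[study$train],
                            study$table$label[study$train]))
rep_
```
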