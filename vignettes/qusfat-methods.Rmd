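---
title: "Modelling hepatic fat fraction from quantitative ultrasound"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling hepatic fat fraction from quantitative ultrasound}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qusfat)
```

## The problem

Liver fat content is the defining quantity of metabolic
dysfunction-associated steatotic liver disease (MASLD). The reference
standard is the MRI proton-density fat fraction (MRI-PDFF, percent), graded
S0 to S3 at the fixed cut-offs 5%, 15% and 20%. Quantitative ultrasound
(QUS) offers two cheap surrogates: the attenuation coefficient (AC, in
dB/cm/MHz — how quickly the beam loses energy with depth, which rises with
fat) and the backscatter-distribution coefficient (BSC-D, unitless — a
statistic of the echo-amplitude distribution). Both rise with PDFF at low
fat fractions and then *saturate*: above roughly 20% fat, further increases
in PDFF move AC very little. A linear regression of PDFF on AC/BSC-D is
therefore accurate in low-grade steatosis and flattens out in S2–S3, while
an exponential model can follow the inverse of the saturating link but is
noisier at the low end. This package implements both model families and a
*compound* predictor that switches between them, plus everything needed to
train, compare and validate them.

Grade intervals are lower-closed (`[5, 15)` etc.): a subject at exactly 5%
is S1, matching the convention that ≥ 5% liver fat defines steatosis. The
same convention is applied to the fibrosis grades (cut-offs 5, 9, 13 kPa of
shear-wave stiffness).

## Model forms

* Linear: `PDFF = b1·X1 + … + bp·Xp + intercept`, fitted by ordinary least
  squares (`fit_linear()`, delegating to `lm`). Allowed predictors: `ac`,
  `bscd`, `bmi`, `sld`.
* Exponential: `PDFF = b1·exp(b21·X1 + … + b2p·Xp) + b3`
  (`fit_exp(form = "shared")`). The univariable case is the classic
  `b1·exp(b2·X) + b3`. With several predictors the exponent is a linear
  combination with a single amplitude and offset — the minimal
  multivariable generalization. An additive alternative
  (`Σ b1j·exp(b2j·Xj) + b3`) is available behind `form = "additive"` for
  sensitivity analyses, since either reading is defensible; the shared form
  is the default because it adds only one parameter per predictor and
  nests the univariable model exactly.

`n_params` always counts the error variance, so the univariable linear
model has 3 parameters and the univariable exponential 4.

### Numerical choices for the NLLS fit

Nonlinear least squares is solved by Levenberg–Marquardt
(`minpack.lm::nls.lm`, `ftol = ptol = 1e-10`, 200 iterations per start)
from a **deterministic multistart**: offset candidates are taken from
`min(y)` (minus a margin), zero, and `min(y) - sd(y)`; for each, amplitude
and rates come from a log-linear regression of `y - b3` on the predictors,
with the rates also scaled by 0.5 and 2. No randomness enters the fit, so
refits are bit-reproducible. Predictors are centred internally (and the
amplitude back-transformed) so that exponents stay well-scaled even for
BSC-D values near 100. If no start converges the fit is returned with
`converged = FALSE` rather than raising, so a model-comparison loop never
dies mid-menu.

### Likelihood comparison

Model fit is compared on the Gaussian maximum-likelihood log-likelihood
`LL = -n/2·(log 2π + log(rss/n) + 1)` and the LR statistic
`2·(LL_full - LL_reduced)` referred to a chi-square. For non-nested pairs
with equal parameter counts (`df = 0`) — e.g. a linear vs an exponential
model on the same predictors — the mechanical LR cannot discriminate and
the p-value is reported as 1. This mirrors common reporting practice for
such comparisons, and the caveat is deliberate: the LR test is only
formally valid for nested models.

## Training and evaluation protocol

`repeated_kfold_train()` implements five-times-repeated three-fold
cross-validation (both counts configurable). Folds are as even as possible
(remainder rows to the first folds), assigned by a seeded shuffle (the
Mersenne-Twister identifier is recorded in the result); each repeat derives
its seed deterministically from the CV seed. Because least-squares fitting
is deterministic, "choosing parameters by CV" is read as: CV estimates
out-of-sample performance and compares model forms, and the **reported
model is a refit on the full training set** — the conventional resolution.

Agreement statistics:

* `pearson_eval()` — Pearson r, R² = r², p from the t transform on n − 2
  degrees of freedom.
* `icc_a1()` — intraclass correlation, two-way model, absolute agreement,
  single measure (McGraw–Wong A,1) with k = 2 methods (prediction,
  MRI-PDFF): `ICC = (MSR − MSE)/(MSR + MSE + (2/n)(MSC − MSE))` from the
  subjects × methods mean squares. Unlike r, a constant bias lowers the
  ICC; the test suite checks it against an independent `aov()`
  decomposition to 1e-10.
* `bland_altman()` — mean bias and limits of agreement `bias ± 1.96·SD`
  of the paired differences (sample SD; the 1.96 multiplier rather than a
  t quantile, i.e. the standard large-sample presentation).
* `evaluate_by_grade()` — stratification uses the MRI-PDFF-derived grade
  (the reference standard), never the predicted grade; groups under 3
  subjects are flagged not-evaluable instead of erroring.
* `bonferroni_adjust()` — each raw p compared against `alpha/m`.

The exact conditional odds ratio (`fisher_exact_2x2()`) reports the
conditional MLE under the noncentral hypergeometric model with the exact
conditional CI and the minimum-likelihood two-sided p — not the sample
cross-product ratio, which differs already in the third decimal for the
cohort-composition tables this is used on.

## The compound model and the grid search

`compound_predict()` routes a subject to the nonlinear branch iff
`ac >= t_ac` **and** `bscd >= t_bscd` (both inclusive); everything else
uses the linear multivariable model. The two variants are CMT (nonlinear
multivariable AC + BSC-D) and CAC (nonlinear AC-only).

`grid_search_thresholds()` scores every candidate pair on the training set
by the R² and ICC(A,1) of the compound predictions against PDFF, with both
matrices retained for heatmap export. Default candidates span 0.75–0.94
dB/cm/MHz in 0.01 steps and 89–108 in unit steps — a 20 × 20 grid at the
precision the parameters are measured with. The selected pair maximizes
**R², with ties broken by higher ICC and then the lowest (t_ac, t_bscd)**;
R²-first was chosen because the grid search exists to improve overall fit,
with ICC as the agreement check, and the deterministic tie-break keeps runs
reproducible. Pairs that route every row to one branch are still scored —
they reproduce the single-model fit, which guarantees the compound training
R² never falls below the linear-only R² when such a pair is in the grid.
Both branch models are fitted once on the full training set, not refitted
per cell: threshold-dependent refitting would make the search
self-referential and was deliberately avoided. The pooled compound
residuals yield a training log-likelihood with `n_params` the sum of both
branches' counts (a conservative convention, used only for LR-style
comparison against the single models).

## The synthetic cohort generator

No public dataset of paired TAI/TSI and MRI-PDFF measurements exists, so
the package ships a generator (`generate_cohort()`, profiles in
`default_params()`) that emulates the *statistical* structure of such a
cohort. The forward model follows the causal direction — fat drives the
acoustics:

1. A steatosis grade is drawn from a mixture: 16/16/12/16 over S0–S3 for
   `training_like` (a retrospectively balanced design), 3/23/12/19 for
   `test_like` (a prospective screening population).
2. PDFF is drawn from a normal truncated to the grade's band, with
   per-grade location/scale (3 ± 1.8, 9 ± 3.5, 17.5 ± 2.5, 26 ± 7) and the
   S3 band capped at 45% (three SDs above a typical cohort mean). Sampling
   within the band makes grading round-trip *exactly*, which the tests
   exploit.
3. AC and BSC-D come from a link on PDFF plus Gaussian noise. For the
   default linear links the coefficients are **calibrated analytically**:
   writing the link `x = a0 + a1·PDFF + ε`, the inverse regression of PDFF
   on x has slope `a1·Vp/(a1²Vp + σ²)` and R² `a1²Vp/(a1²Vp + σ²)` (Vp the
   mixture variance of PDFF), so requiring slope 53.04 / R² 0.533 for AC
   (with marginal mean 0.84) and slope 0.573 / R² 0.265 for BSC-D (mean
   100.69) fixes `a1 = R²/slope`, `σ² = a1·Vp·(1/slope − a1)` and `a0`
   uniquely. The implied marginal SDs (≈ 0.14 for AC, ≈ 9.25 for BSC-D)
   agree with the population summaries the targets come from — the
   published slope, R² and SDs are mutually consistent, which is a good
   internal check of the calibration. The acceptance suite verifies the
   recovery at n = 5000.
4. The `plateau_stress` profile replaces the AC link with the saturating
   form `ac = 0.60 + 0.50·(1 − exp(−PDFF/10)) + N(0, 0.02)` — the simplest
   saturating curve consistent with the attenuation plateau, with strong
   curvature so compound-model behaviour can be exercised: its inverse is
   convex, so the exponential model fits it well and any linear fit
   degrades visibly in S2+S3.
5. USFF, when enabled, is the in-sample linear projection of PDFF on
   (AC, BSC-D) plus N(0, 1.2) noise, clipped to [0, 100] — it exists so
   that code paths comparing against a vendor fat fraction are testable,
   and its noise level makes it correlate ≈ 0.99 with a trained linear
   multivariable model, as a vendor linear combination would.
6. BMI, skin-to-liver distance, liver stiffness, age and sex are sampled
   independently from profile-specific marginals; they are plumbing for
   the optional-covariate code paths, not a physiological model.

Randomness is organized in per-stage substreams: stage k reseeds with
`(seed mod 2^27)·8 + k`, so enabling the USFF column (stage 5) can never
perturb the grades, PDFF or QUS values drawn in stages 1–4. AC and BSC-D
noise are independent by default; a `resid_cor` parameter exists but
defaults to 0 since no joint residual structure is published.

**What the generator does not emulate:** measurement-level replicates and
their QC (the R² < 0.7 discard rule for attenuation fits, the IQR/median
rule for stiffness), inter-operator and inter-vendor variability,
covariance between body habitus and liver fat, and any non-Gaussian
residual structure. Passing tests therefore demonstrate that the
*algorithms* behave correctly on data with the published first- and
second-moment structure — not that the fitted coefficients would transfer
to any scanner's patients.

## Problem sizes and seeds used by the test suite

The acceptance tests run the NLLS recovery study at n = 500 over 20 seeds
(rate recovered within 15%), the compound stress test at n = 300 train /
300 test over 10 seeds, the calibration check at n = 5000, and the
oracle comparisons (ICC/Pearson vs `aov`/covariance formulas, grid search
vs brute force) on 100 and ~60 cases respectively; the end-to-end study
emulation in `scripts/acceptance.R` uses the study sizes, 60 training and
57 test subjects. These sizes were chosen to make Monte-Carlo assertions
stable at comfortable margins.

## Known limitations

* The exponential model's multivariable form is an interpretation (see
  above); both readings are implemented but only the shared-exponent form
  is exercised by the default menu.
* The LR comparison between equal-size non-nested models is reported with
  p = 1 by construction; use the test-set agreement statistics, not the
  LR, to choose between linear and exponential forms.
* ICC confidence intervals are not computed (point estimates only).
* The compound model has exactly two branches and a hard switch; smooth
  blending and per-grade thresholds are out of scope.
* Predictions are not clipped to [0, 100]; an exponential model
  extrapolated far above the training AC range can produce fat fractions
  above 100%.
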