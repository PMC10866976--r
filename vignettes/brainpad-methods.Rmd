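---
title: "Methods: synthetic brain-age cohorts and the Brain-PAD pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: synthetic brain-age cohorts and the Brain-PAD pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`brainpadlab` implements a sex-stratified brain-age analysis for Parkinson's
disease as a fully testable pipeline. Real studies of this kind estimate a
subject's "brain age" from structural-MRI tissue maps, subtract the
chronological age to obtain the brain-predicted age difference (Brain-PAD),
and relate that difference to clinical severity — but the imaging cohorts
such studies rest on are access-gated, so nothing downstream can be verified
by a third party. This package inverts the problem: it ships a generative
model in which the quantity of interest (a sex-specific "accelerated aging"
gap) is injected with known value, so every stage of the analysis — feature
assembly, regression, bias adjustment, matching, multiple-testing control,
voxelwise inference — can be checked against ground truth.

## The generative model

Each subject has three tissue probability maps (GM, WM, CSF) on a common
voxel grid with an ellipsoidal brain mask. For voxel $v$ and subject $i$:

$$\mathrm{GM}_i(v) = s_i\left[T_{GM}(v) + r(v)\,(a_i + g_i) + m_i\,x(v) +
  c_{k(i)} + \varepsilon_i(v)\right]$$

where $T_{GM}$ is a smooth template, $r(v) \le 0$ the per-voxel atrophy rate
(probability units per year), $a_i$ the chronological age, $g_i$ the latent
accelerated-aging gap, $m_i \in \{0,1\}$ male sex, $x(v)$ a sex-offset map,
$c_{k}$ an additive scanner offset, $\varepsilon_i$ smooth Gaussian noise,
and $s_i$ a per-subject head-size factor. WM is built the same way at a
fraction (`wm_rate_scale`, default 0.4) of the GM atrophy rate; CSF absorbs
every deviation of GM and WM from their templates, so GM + WM + CSF is
constant per voxel and the total intracranial volume (TIV) is invariant to
age, gap, sex, scanner and noise within a subject.

The central design decision is that atrophy acts through the *effective age*
$a_i + g_i$. This makes the injected gap exactly the Brain-PAD construct: a
subject with gap $g$ has, voxel for voxel, the maps of a healthy subject $g$
years older (a property the test suite asserts bit-exactly in the noiseless
limit). Any consistent estimator must therefore recover the group-mean gaps,
which is what the recovery suite checks.

Default study conditions. Healthy groups are 53% female and the disease
group 34% female; ages are uniform over 18–94 years (a uniform distribution
is the simplest one with full support across the range, which matters for
exercising the bias adjustment); disease-group gaps are
$\mathcal{N}(3.5, 2^2)$ years for males and $\mathcal{N}(1.8, 2^2)$ for
females, zero for healthy subjects, echoing the sex-specific pattern the
analysis is designed to detect. Two scanner levels (1.5 T and 3 T) differ by
a small additive intensity offset and a noise-scale factor. Per-voxel smooth
noise has SD 0.02 (probability units) at 12-mm FWHM. The head-size factor
has a 3% coefficient of variation; it exists so TIV varies across subjects
(as a covariate must) while remaining age-invariant within subject.

The sex-offset map is laterally antisymmetric (a left–right gradient scaled
by the central tissue profile). The shape matters: a sex offset proportional
to the atrophy pattern itself would make sex and age effects collinear in
voxel space and hence unidentifiable — an earlier draft of the generator did
exactly that and systematically mis-allocated the sex offset to the age
prediction. Regionally specific, approximately age-orthogonal sex
differences are both more realistic and identifiable.

Clinical scores are generated from the same linear-model families the
analysis later fits: motor severity on intercept + Brain-PAD slot (the
latent gap) + age + disease duration + education + sex; non-motor scores add
the *realized* motor score; mood scores add the realized motor and cognition
scores. Residual SDs and per-outcome missingness complete the specification,
and the generating coefficient vectors are returned alongside the table so
coefficient-recovery tests need no bookkeeping. Disease duration is kept in
months, computed from the diagnosis age and the scan age.

What the generator does *not* emulate: anatomy (templates are analytic
functions of an ellipsoidal radius), nonlinear registration, scanner
physics, segmentation error, or non-Gaussian score distributions. Passing
tests therefore demonstrate the *statistical* correctness of the pipeline —
calibration, recovery, identities — not robustness to realistic artefacts.
The Gaussian form of the gap distribution is itself an assumption; the
studies this emulates report only means and confidence intervals.

## Morphometry operators

`smooth_grid()` is separable Gaussian convolution with
$\sigma = \mathrm{FWHM} / (2\sqrt{2\ln 2})$ per axis in mm. The 4-mm default
kernel width is interpreted as a FWHM, the convention of the segmentation
toolchains this step stands in for. The discrete kernel is normalized and
*renormalized at the array boundary*. The alternative (zero-padding) treats
outside-of-array as zero tissue, but it fails two properties the rest of the
package relies on: a constant map must smooth to itself, and smoothing must
commute with adding constants (linearity). Boundary renormalization
satisfies both, and still conserves the mass of any impulse further than one
kernel radius from the boundary.

`resample_grid()` downsamples by block averaging — the discrete analogue of
the volume-preserving intent of modulated VBM, and directly testable (each
coarse voxel equals the mean of its children; masked means are preserved to
well under 1% on smooth inputs). The target spacing must be an integer
multiple of the source spacing; arbitrary rational ratios would need
overlap-weighted pooling with no test leverage. The mask is resampled by
majority vote with ties counted in-mask; the affine is updated so world
coordinates refer to block centres.

The conventional figure of 3747 in-mask voxels per tissue at 8-mm resolution
is treated as a property of a particular template mask, not something to
reproduce from geometry; the `preset = "paper"` cohort spec pins the mask to
exactly 3747 voxels (innermost-first by ellipsoidal radius) on a 24³ grid.
The striatal binding ratio is included as the one scalar imaging-derived
measure: target over reference uptake minus one.

## Brain-age model and bias adjustment

Features follow a fixed schema: GM, WM and CSF in-mask voxel intensities,
the three tissue volumes and TIV, sex (F = 0, M = 1), scanner vendor
(drop-first indicators; a single vendor keeps one constant column so the
attribute always occupies a slot), and field strength. Features are z-scored
with training-set statistics and an $\varepsilon$-insensitive linear SVR is
fit (default cost 1, $\varepsilon$ = 0.1 — ordinary defaults, exposed in the
configuration; the underlying solver is libsvm via `e1071`). Whether to
standardize at all was an open choice; standardization is the default of
every SVR implementation in common use and makes the cost parameter
comparable across feature blocks with very different scales (voxels vs ml vs
tesla). The fitted model is stored as an explicit weight vector and
intercept, so prediction is a single matrix product and serialization is
plain JSON.

Cross-validation uses seeded random folds without age stratification; each
subject is predicted exactly once by a model that never saw it, and metrics
(MAE, RMSE, $R^2$, mean Brain-PAD with a normal-approximation 95% CI) are
pooled over out-of-fold predictions. The final deployed model is refit on
the whole training set.

Raw brain-age predictions of regularized regressors are biased toward the
training mean — young subjects are predicted old and old subjects young
(regression dilution). The adjustment fits, by OLS on healthy training
subjects only,

$$\hat{a}_i - a_i = \alpha\, a_i + \beta$$

and reports the corrected prediction $\hat{a}_i - (\alpha a_i + \beta)$.
Two consequences are exact algebra, not approximations: the training-set
mean of adjusted Brain-PAD is 0 and its correlation with age is 0 (OLS
residual identities), which is why the training row of a results table shows
0.00 by construction while hold-out rows show small non-zero means
(coefficients are frozen after fitting and merely *applied* to hold-out and
disease groups).

One subtlety decided during development: $(\alpha, \beta)$ are fit on the
**out-of-fold CV predictions** of the training set, not on the final model's
in-sample predictions. A flexible model fits its own training set with slope
near 1, so in-sample fitting sees almost no dilution and leaves the
out-of-sample shrinkage uncorrected — measured here as roughly 10%
attenuation of the injected disease gap. CV predictions are honest estimates
of out-of-sample behaviour, use only training subjects, and restore recovery
of the injected gaps to well within half a year at the default conditions.

## Matching, battery, voxelwise inference

**Propensity matching.** The male disease subgroup is matched to the female
subgroup on the clinical covariate list (age, education, diagnosis age, the
three motor scores, cognition, REM and sleepiness scores) via logistic
regression propensity scores. Greedy 1:1 nearest-neighbour matching without
replacement runs on the *logit* of the score (distances on the probability
scale compress near 0 and 1), processes the minority in a seeded random
order, breaks ties deterministically, and honours an optional caliper with a
warning for unmatched subjects. Subjects with missing matching covariates
are removed listwise before fitting. Balance diagnostics report
pooled-variance t-tests and standardized mean differences pre- and
post-match; zero-variance variables get an explicit `NA` rather than a
number.

**Regression battery.** One OLS model per outcome and subgroup (all
disease, females, males, matched males), with classical standard errors and
per-model listwise deletion — per-model, because real batteries report
different residual degrees of freedom across models of the same table, which
is only possible if each model deletes its own missing rows. The sex
predictor is dropped automatically in single-sex subgroups. The FDR family
is the results table (motor / non-motor / mood): Benjamini–Hochberg is
applied to the F-test p-values of all models in a family, and only to those
— coefficient p-values are reported raw, mirroring the way such tables
footnote their adjustment. Interaction terms (sex × Brain-PAD) are
deliberately out of scope, as is any robust-variance machinery.

**Voxelwise statistics.** `massuni_fit()` computes per-voxel OLS
t-statistics for a contrast column via one matrix solve across all voxels;
on any single voxel it agrees with the battery's `fit_ols()` to 1e-10, a
cross-module identity the suite asserts. Family-wise error control uses
max-statistic permutation instead of random-field theory: RFT needs
smoothness estimation machinery that is out of scope here, while the
permutation test is exact under exchangeability and — crucially for this
package — *testable*, by simulating null datasets and checking the
false-positive rate lands in its binomial band. Nuisance covariates are
handled with the Freedman–Lane scheme (permute residuals of the
nuisance-only model, add back nuisance fits, recompute the full-model
statistic), the standard choice for regression permutation tests. The
observed statistic is included in its own null distribution, so corrected
p-values are never zero and are monotone non-increasing in $|t|$. Tests are
two-sided with negative and positive clusters reported separately.

Clusters are 26-connectivity components of voxels passing the corrected
threshold, filtered by an extent threshold expressed in analysis-grid voxels
(the conventional "100 voxels" refers to a much finer VBM grid; the default
configuration uses 10 voxels at 8 mm, and the value is configurable). Sizes
are reported in voxels and ml, peaks in world mm through the affine, and
hemisphere as the sign of world x.

## Numerical choices and degenerate inputs

* RNG: every stochastic stage draws from a sub-stream derived from the
  master seed and a stage label (`substream_seed()`), so regenerating any
  one stage is reproducible regardless of how many draws other stages
  consumed, and identical configurations yield bit-identical outputs.
* Degenerate targets error early: constant training ages, zero age variance
  in the bias fit, zero pooled variance in t-tests, constant Brain-PAD in
  ROI correlations, rank-deficient designs (reported with the offending
  column names), perfect separation in the propensity model (reported with
  advice), empty subgroups.
* Constant covariates are *dropped with a warning* in the propensity model
  and silently (by necessity) in single-sex battery subgroups; constant
  feature columns get unit scale rather than a division by zero.
* Zero-variance voxels produce `NA` t-values with a logged count rather
  than infinities.
* Clipping: tissue values are clipped to [0, 1] after noise, and CSF is
  capped at $1 - \mathrm{GM} - \mathrm{WM}$, so probability bounds and the
  unit-sum ceiling hold even in extreme draws.

## Problem sizes

The shipped test-suite and acceptance script run the study at desk scale,
chosen as the package's reference conditions: a 16³ grid at 8 mm (~1900
in-mask voxels), 200 training controls, 22 hold-out controls, and 400
disease subjects for recovery runs; 20 seeds for sign-recovery rates; 500
replicate null batteries at n = 60; 200 null datasets at 150 permutations
for FWE calibration. The `"paper"` preset scales the grid to the
conventional 3747-voxel mask for users who want feature matrices of the
canonical width (11,248 columns).

## Known limitations

* The generator's linearity is also its limitation: a method could overfit
  to exact linearity and still pass recovery. Calibration suites (null
  batteries, null FWE) partially guard against this.
* Permutation FWE assumes exchangeability of nuisance-model residuals;
  heteroskedastic scanner noise violates this mildly (noise-scale factors
  differ by vendor), which the calibration band absorbs at the shipped
  settings.
* Greedy matching is order-dependent by nature; the seeded order plus
  logit-sorted deterministic tie-break makes it reproducible, not optimal.
* The anxiety score has no canonical scale here and is generated on an
  arbitrary continuous scale; only its regression structure is meaningful.
* Brain-PAD is a group-level construct in this pipeline; nothing here
  supports subject-level prognostic use.
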