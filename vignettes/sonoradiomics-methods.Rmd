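---
title: "Methods: masked-ROI ultrasound radiomics, penalized selection and patient-level evaluation"
author: "sonoradiomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: masked-ROI ultrasound radiomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its models and numerical
conventions: what each stage computes, which knobs matter, which
conventions were genuinely open choices, and what the synthetic cohort
does and does not establish about real ultrasound data.

## 1. The problem and the pipeline

Membranous nephropathy (MN) and IgA nephropathy are the two most common
primary glomerulopathies; definitive classification requires a renal
biopsy. Diffuse glomerular disease alters renal cortical echogenicity
and fine parenchymal texture on B-mode ultrasound, which motivates a
radiomics approach: quantify the texture of the manually delineated
parenchyma (an annulus-shaped ROI on most views), select the informative
features, and classify. The pipeline is

1. masked-ROI extraction of a 180-feature texture signature per slice,
2. min–max normalization and LASSO-logistic feature selection by
   cross-validated binomial deviance,
3. four standard classifiers with slice-to-patient probability
   aggregation and patient-level ROC evaluation.

MN is the positive class throughout: sensitivity is the true-positive
rate for MN, specificity the true-negative rate for IgA. Predicted
labels threshold probabilities at 0.5, with the tie counted as MN; the
accuracy is always computed from the same thresholded labels as the
confusion matrix.

## 2. The texture signature

All features are computed inside the binary mask only; the bounding box
is tight and coordinates are 0-based half-open, with in-mask pixels
enumerated row-major (`roi_view()`). ROIs under 16 pixels are rejected
— their co-occurrence and run-length matrices carry almost no counts
and the statistics are degenerate.

**Quantization.** GLCM/GLRLM features need discrete gray levels. We use
min–max uniform binning of the in-mask intensities into `Ng` levels,
`level(v) = min(Ng, floor((v − min)/(max − min) · Ng) + 1)`, with a
constant ROI mapping to level 1. `Ng = 32` by default: a common
radiomics compromise between gray-level resolution and sparsity of the
32×32 co-occurrence matrix on ROIs of a few thousand pixels. Min–max
binning makes every GLCM/GLRLM feature invariant to adding a constant to
the ROI (the tests assert this), which is desirable since absolute
ultrasound gain is operator-dependent.

**First-order features** are computed on the raw (unquantized) in-mask
intensities. Moments are population moments (1/N); kurtosis is
non-excess (a normal sample gives ≈ 3); skewness and kurtosis of a
constant ROI are defined as 0. Entropy (bits, 0·log 0 = 0) and
uniformity use a 32-bin min–max histogram of the same values.

**GLCM.** For each of the four distance-1 offsets (0°, 45°, 90°, 135°)
pairs with both endpoints in-mask are counted, symmetrized (each pair in
both orders) and normalized to sum 1. The nine Haralick-convention
statistics are computed per offset and then averaged feature-wise;
offsets admitting no valid pair are skipped from the average
(feature-then-average, not matrix-averaging — both exist in the
literature, so the choice is stated here once and fixed). A degenerate
matrix with zero marginal spread gets correlation 1 (all mass at one
level).

**GLRLM.** A run is a maximal chain of consecutive same-level in-mask
pixels along a direction; leaving the mask terminates the run, so runs
never jump across the annulus hole. The 13 classical run-length
statistics use 1-based level and length indices. The conservation law
Σᵢ Σ_r r·R[i,r] = N_pixels holds per direction and is tested. The same
four directions are averaged feature-wise.

**Wavelet sub-bands.** One level of a *non-decimated* (stationary)
separable 2-D wavelet transform of the bounding-box image, periodic
boundary handling, Haar filters by default (`db2` available). No
downsampling means every sub-band keeps the box shape, so the original
mask applies unchanged. Naming puts the row filter first: band `XY`
applies filter `X` along each row (across columns) and `Y` down each
column; `A` is the low-pass, `D` the high-pass, so a purely horizontal
ramp loads `DA` (a test pins this convention). Sub-band values are
signed, so each sub-band is re-quantized independently (min–max inside
the mask) before its GLCM/GLRLM features. 36 features × (original +
4 sub-bands) = 180, named `{band}_{family}_{feature}`.

The Haar default is a deliberate minimal choice: with no record of the
original filter bank, the shortest orthogonal filter adds the least
boundary distortion on small annular boxes.

## 3. The synthetic cohort

The patient images behind the motivating study are not publicly
deposited, so the package generates a surrogate cohort whose *structure*
matches the analysis assumptions:

* 46 MN + 22 IgA patients, ≥ 9 slices each, 623 slices total by default;
* a patient-level split into 51 training cases (470 slices) and 17
  validation cases (9 MN + 8 IgA, 153 slices). The eleven extra tenth
  slices go to training patients — the unique minimal allocation
  consistent with those printed totals — and the generator designates
  the validation patients *before* allocating extras, so the totals hold
  at any seed;
* an annulus ROI per slice (ellipse minus concentric inner ellipse,
  randomized center, axes, rotation), emulating the typical appearance
  of renal parenchyma;
* speckle texture: log-compressed ultrasound speckle is approximately a
  smooth log-normal field, so each slice is white Gaussian noise
  smoothed by a Gaussian kernel, standardized, exponentiated, scaled,
  plus sensor noise (SD 4 gray levels), quantized to 8-bit. The class
  contrast enters twice, both scaled by `texture_effect`: MN gets
  correlation length `base_sigma·(1 + texture_effect)` (vs `base_sigma`
  = 2 px) and a mean offset of `12·texture_effect` gray levels. The two
  routes make both the second-order (GLCM/GLRLM) and first-order
  families informative. `texture_effect = 1` is the default working
  point; at 0 the classes are literally the same distribution.

All randomness flows from one master seed through named sub-streams
(`masks`, `cohort`, `split`, and in the pipeline `cv` and one per
classifier) via a small string hash (`sub_seed()`), so regenerating any
stage alone is reproducible.

What passing on this cohort shows — and does not. The generator
reproduces the *statistical skeleton* (two classes differing in
second-order texture, patient/slice hierarchy, split geometry), so it
can certify the machinery: feature definitions, leakage-free
normalization and splitting, selection and evaluation logic, and the
directional benefit of patient-level aggregation. It does not emulate
scanner point-spread anisotropy, attenuation with depth, shadowing, or
anatomical heterogeneity, so absolute performance numbers on it say
nothing about clinical performance on real sonograms.

## 4. Normalization and penalized selection

Min–max parameters are learned from training rows only and applied
unchanged to validation rows, which may therefore fall outside [0, 1]
and are *not* clipped; constant training features are flagged and mapped
to 0. This mirrors a 0–1 feature scaling done before selection, and
keeping the solver free of internal re-standardization preserves that
scaling's meaning.

The selection model is ℓ1-penalized logistic regression,
`(1/n) Σ softplus(ηᵢ) − yᵢηᵢ + λ‖β‖₁` with unpenalized intercept.
The solver is a proximal-Newton scheme: an IRLS quadratic model at the
current iterate (weights floored at 10⁻³ for conditioning), an inner
cyclic coordinate descent with soft-thresholding and an active-set
strategy on that quadratic, and a line search on the *true* penalized
objective that may expand as well as backtrack. Because steps are
accepted only when the objective does not increase, the objective is
non-increasing across iterations (a property test asserts this to
1e−12). Convergence: maximum coefficient change < 1e−7, an objective
plateau (< 1e−11 decrease per step, the relevant stop under
near-separation), or 10⁵ iterations. The soft threshold carries a
1e−12 relative tie tolerance so coefficients whose gradient sits exactly
on the KKT boundary at λ_max stay exactly zero in floating point.

The λ grid has 100 log-spaced values from λ_max = maxⱼ |xⱼᵀ(y − ȳ)|/n
down to 10⁻³ λ_max, fitted with warm starts. In cross-validation the
grid top is raised to cover every training fold's own λ_max, so the path
starts at the exact null model in every fold and the held-out deviance
at the top of the grid equals the null-model deviance to 1e−10.

Cross-validation uses k = 5 stratified folds. The fold unit is the
slice by default, mirroring a selection done on slice-level rows; a
patient-grouped mode (`groups =`) is provided as the leakage-safe
alternative, since slices of one patient are correlated and slice-level
folds flatter the CV estimate. Held-out binomial deviance
(−2/n) Σ y ln p + (1−y) ln(1−p) uses probabilities clamped to
[1e−12, 1−1e−12]; `cv_deviance_se` is the standard error of the fold
means (sd/√k), and `lambda_1se` is the largest λ whose mean deviance is
within one standard error of the minimum. The default selection rule is
`lambda_min` (smallest cross-validated deviance); an AUC criterion
(`criterion = "auc"`, maximize mean held-out AUC on the same folds) is
available and in practice changes selections little. Selected features
are reported with coefficients sorted by |β|, ties broken by canonical
name order.

On signal-free data cross-validation rightly prefers the null model, so
`lambda_min` can sit at the top of the grid and select nothing. The
standalone selector reports that empty set faithfully, but the pipeline
needs classifier inputs, so `run_pipeline()` then falls back to the
largest λ at which any feature enters the path (the weakest admissible
model), flags the fallback in the provenance block and messages it;
under the null this produces chance-level classifiers rather than a
failed run.

## 5. Classifiers and evaluation

Hyperparameters follow common defaults, all configurable and logged in
the report's provenance block: ridge-logistic regression with λ = 10⁻³
(the light ℓ2 of standard ML toolkits), RBF-kernel SVM with probability
outputs (cost 1), a 500-tree random forest, KNN with k = 5. Each
trainer is seeded; identical seeds give identical predictions (KNN
breaks vote ties randomly, hence its seed matters).

Evaluation always reports both granularities. The patient probability
is the unweighted mean of the patient's slice probabilities — slices of
one patient carry independent noise around a shared disease state, so
averaging cancels noise and the patient-level AUC dominates the
slice-level AUC in expectation (tested directionally over 20 seeds).
The ROC is the empirical curve thresholded at every unique score; its
trapezoidal area equals the Mann–Whitney statistic with ties counted
one-half (tested against brute-force pair counting to 1e−12, and
against an independent ROC implementation).

## 6. Problem sizes used by the tests and the acceptance script

Chosen so a full run stays comfortable on a single CPU: the default
623-slice cohort is generated once for the bookkeeping check; the
end-to-end strong/null-effect runs use a 28-patient cohort (16 MN /
12 IgA, 8 + 8 validation, 96×96 images), where the strong effect
(`texture_effect = 1`) yields patient-level validation AUC > 0.9 and the
null effect stays inside the [0.2, 0.8] chance band (16 validation
patients make that band a ≳ 95% interval under the exact Mann–Whitney
null); the support-recovery simulation uses n = 400, p = 60, six true
coefficients ±2, 20 replicates; oracle-equivalence checks run on
hundreds of random 8–16 px masked images.

## 7. Known limitations

* The synthetic speckle is isotropic and stationary inside the ROI;
  real parenchyma is neither. Absolute AUCs on synthetic cohorts are
  not clinical estimates.
* Slice-level CV folds (the default, chosen for fidelity to slice-row
  selection) leak patient identity across folds; use
  `cv_grouping = "patient"` for honest generalization estimates.
* DICOM input is not supported (no DICOM reader among the package's
  dependencies); export to PNG/TIFF first.
* First-order features use raw intensities and the texture families
  re-quantize per band; pipelines that quantize before first-order
  statistics will produce different (also defensible) values.
* Shape/morphology features and multi-level or non-separable wavelet
  decompositions are out of scope.
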