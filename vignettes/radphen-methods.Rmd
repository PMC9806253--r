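---
title: "Radiomic immunophenotyping of breast DCE-MRI: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Radiomic immunophenotyping of breast DCE-MRI: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`radphen` predicts the spatial CD8+ T-cell immunophenotype of a breast
tumor (immune-desert, immune-excluded, inflamed) from the texture of
four-phase dynamic contrast-enhanced MRI. This vignette explains the model
and its assumptions, the tunable parameters and their defaults, what the
synthetic phantom generator does and does not emulate, the numerical
conventions, and the design decisions taken where the design was genuinely
open.

## The pipeline

1. **Imaging.** Volumes and binary tumor masks are read from NIfTI with the
   header spacing treated as authoritative. The preprocessing chain is
   deliberately minimal: resampling to 1 mm isotropic voxels (trilinear for
   intensities, nearest-neighbor for masks) and no intensity normalization
   — texture features are computed on fixed-bin-count discretized gray
   levels, which already makes them invariant to affine intensity
   rescaling. One ROI, drawn on the subtraction image (second post-contrast
   minus pre-contrast), is propagated unchanged to all four phases.
   The *tumor periphery* is the inner 2-mm rim: the in-mask voxels whose
   Euclidean distance (in mm, computed by an exact distance transform using
   the physical spacing) to the nearest out-of-mask voxel is at most 2.
   On a voxel grid this convention reproduces the analytic shell volume of
   a sphere to within the discretization error (≈ 2% at 0.5-mm voxels).

2. **Wavelet filter bank.** Each volume is decomposed by a single-level
   separable 3D discrete wavelet transform (symmetric half-point boundary
   extension, redundant boundary coefficients, exact reconstruction). The
   all-low-pass (LLL) sub-band is multiplied by a *ratio* r ∈ {1/2, 2/3,
   3/2, 2} and the seven detail sub-bands are kept at weight 1 before
   inverse transformation; ratios below 1 suppress and above 1 amplify the
   low-frequency content, and r = 1 reproduces the input exactly — the
   anchor identity for testing. Three families (Daubechies-2, Coiflet-1,
   Symlet-4) × four ratios give the 12 filtered images. This band-weighting
   reading of "ratio" is a declared interpretation: it is the simplest
   scheme consistent with ratio values straddling 1, but alternative
   conventions cannot be excluded, so the contract is stated rather than
   presumed canonical. By linearity the filtered image equals
   `v + (r − 1)·A`, with `A` the approximation reconstruction; the bank
   computes one `A` per family and shares it across ratios.

3. **Features.** One radiomic feature group (RFG) = ROI volume (mm^3) +
   64 texture features on the original image + 64 on each filtered image =
   833 features. The 64-feature roster is fixed as 14 first-order +
   13 GLCM + 16 GLRLM + 16 GLSZM + 5 NGTDM, using the standard
   Amadasun–King / Haralick / Galloway / Thibault formula canon — the five
   families sum to exactly 64. Matrices are built in 3D at distance 1:
   the GLCM accumulates all 13 unique directions into one symmetric matrix
   before normalizing; the GLRLM is built per direction and its features
   averaged over the 13 directions; GLSZM zones are 26-connected; the NGTDM
   uses the 26-neighborhood. Wavelet-filtered images are re-discretized
   independently because their intensity range differs from the original.
   The fused single-pass kernel is asserted (in the test suite) to
   reproduce the modular reference path exactly, and every matrix builder
   is checked against brute-force enumeration.

4. **Filtering.** Stability: a 20-patient subset is segmented a second
   time; features with ICC(2,1) — single-rater, absolute agreement, from
   the two-way random-effects ANOVA decomposition — below 0.8 are dropped.
   Absolute agreement is chosen because segmentation stability is about
   reproducing the same value, not a correlated one. Discrimination: the
   top 50 features per RFG by univariate AUC on the *training* cohort only
   (configurable to the whole cohort; training-only avoids leakage), ranked
   direction-agnostically by max(AUC, 1 − AUC) since a feature with AUC 0.1
   is highly informative; ties break lexicographically for determinism.
   RFGs with fewer than 50 stable features keep all of them.

5. **Models.** L1-penalized logistic regression (glmnet; alpha = 1,
   maxit = 10^4) with stratified, seeded 5-fold cross-validation; the
   penalty at minimum mean CV deviance is selected. Inputs are standardized
   to training mean 0 / sd 1 and the parameters stored with the model, so
   scores are reproducible from the serialized object alone. The logistic
   family is the natural choice for binary endpoints evaluated by ROC.
   When the minimum-CV penalty keeps the null model — a real possibility
   for genuinely weak single phases — the fit steps down the path to the
   largest penalty admitting at least one feature instead of failing: a
   weak phase still yields a (weak) score model, which mirrors how weak
   phases still carry a handful of selected features in practice. The
   score-combined model (SC) refits the LASSO on the four phase scores;
   the feature-combined model (FC) refits it on the union of the
   phase-selected features, with the same CV protocol (both fusions
   re-select their penalty by CV on their own inputs).

6. **Calling and evaluation.** Youden-optimal cutoffs (midpoints of sorted
   unique scores; ties resolve to the lowest threshold) are fitted on
   training scores of the two FC models. The cascade calls inflamed when
   the whole-tumor score reaches its cutoff, otherwise excluded when the
   peripheral score reaches its cutoff, otherwise desert. Orientation is
   pinned by construction: the whole-tumor model is trained with inflamed
   as the positive class (its score correlates positively with central
   CD8+ density) and the peripheral model with excluded as positive.
   Evaluation reports the 3×3 confusion matrix (rows = truth), accuracy,
   per-class F1 and the macro (unweighted mean) F1 — "average F1" is
   interpreted as the macro average. Model AUCs are compared pairwise
   within each six-model family by DeLong's paired test on the entire
   cohort, Holm-adjusted across the 15 pairs of the family.

7. **Statistical kernel.** AUC is the Mann–Whitney rank form with 0.5 tie
   credit. The DeLong comparison uses the placement-component covariance
   with a two-sided normal p-value and returns p = 1 with a warning when
   the placement variance degenerates. Holm adjustment, Pearson
   correlation, t-tests and one-way ANOVA with Tukey HSD are delegated to
   base R (`p.adjust`, `cor.test`, `t.test`, `aov`/`TukeyHSD`); the
   two-group default is the Welch test, with the pooled-variance form
   available. All tests are two-sided.

## The synthetic phantom cohort

The generator stands in for the institutional cohort and defines the study
conditions: 182 patients with phenotype prevalences 36.8 / 16.5 / 46.7%
(desert / excluded / inflamed, largest-remainder allocation), a 3:1
training/validation split (137/45, training rounded up), and a 20-patient
re-segmented subset.

Each phantom is an ellipsoidal tumor (semi-axes 5–9 mm) on a 32×32×26 grid
of 1-mm voxels, with a smooth enhancement dome and additive Gaussian
acquisition noise (sd 0.3) on every phase. Phase enhancement follows
wash-in/wash-out kinetics (3.0, 2.4, 1.9, 1.5 relative to a 0.3
pre-contrast scale), so the first post-contrast phase has the best
texture-to-noise ratio and single-phase models order accordingly.
Phenotype is encoded as Gaussian-smoothed speckle (correlation length 0.8
voxels) whose amplitude is region-specific: baseline 0.13 everywhere for
the desert phantom, 0.52 in the 2-mm rim for the excluded phantom, and
0.52 in the rim plus 0.72 in the core for the inflamed phantom. Amplitudes
are multiplied by patient-level lognormal nuisances (sdlog 0.1 global plus
0.15 per region, shared across phases) and by phase-level lognormal jitter
(sdlog 0.7, independent per phase and per region). The per-phase jitter is
the key structural choice: it limits what any single phase can
discriminate while averaging out under multi-phase fusion, which is what
makes the SC/FC models genuinely better than every single-phase model —
the qualitative structure the pipeline is supposed to recover. The
`effectSize` knob scales the log-amplitude contrast between phenotypes;
0 produces a null cohort with no phenotype–texture coupling, used as an
overfitting guard. A kinetic mechanism (phenotype-dependent texture
wash-out rates, the `corePersistence`/`rimPersistence` parameters) is
available but neutral by default: with class-dependent kinetics the
late-phase *level* contrast leaks straight into single-phase models, which
defeats the purpose.

Amplitude and noise values were designed so the fitted models sit in the
performance regime the method is meant to demonstrate — single-phase
validation AUCs well below the fusions, FC validation AUCs near 0.98 for
both endpoints, three-class validation accuracy around 0.9 — while keeping
every phase weakly informative on its own. In this phantom the single-phase
models are stronger (AUC ≈ 0.85–0.95) than is typical for real whole-tumor
single-phase models: phantoms lack the biological confounders (molecular
subtype, fibrosis, vascular heterogeneity) that depress single-phase
discrimination in patients. Passing tests on phantoms therefore
demonstrates that the pipeline recovers planted structure faithfully, not
that it would reach the same numbers on clinical data.

Second-rater segmentations perturb the signed distance of the mask
boundary with a smooth random field plus a global dilation/erosion bias;
the jitter scale is calibrated per case (deterministically from the seed)
so the Dice overlap lands in the inter-rater band [0.82, 0.97] — on a
1-mm grid a fixed sub-voxel amplitude would too often be quantized into a
near-identical mask — and boundary displacement is clamped so the
Hausdorff distance stays below 3 mm. Stromal CD8+ densities (cells/mm^2)
are generated lognormal covariates ordered by phenotype (inflamed highest
centrally; desert lowest peripherally); they are *not* derived from the
images, so their correlation with radiomic scores arises honestly through
the shared phenotype.

One caveat on ROI specificity: at these tumor sizes the 2-mm rim is a
large fraction of the whole tumor (one third to two thirds), and
distribution-shape features computed on the whole ROI still sense a
textured rim subpopulation. Peripheral features therefore out-discriminate
whole-ROI features for desert-vs-excluded (and are required for the
strongest models), but the whole-ROI handicap is a direction, not a chasm;
with centimeter-scale tumors the dilution would be far stronger.

## Numerical conventions and degenerate inputs

- Discretization: `level = min(G, floor(G (x − min)/(max − min)) + 1)`,
  G = 32 by default (fixed bin count bounds matrix sizes on
  arbitrary-unit MRI); a constant region maps to level 1.
- A constant ROI yields variance/entropy/range 0, uniformity 1, skewness
  and excess kurtosis defined as 0, GLCM correlation defined as 1, and the
  NGTDM epsilon guard (1e-6) caps coarseness at 1e6; no feature is ever
  NaN on a non-empty ROI.
- A single isolated voxel has no co-occurring pairs and is rejected as a
  degenerate ROI by name.
- Quantiles (median, IQR) use R's default type-7 definition.
- The rim uses "distance ≤ rim width" on voxel centers; thin structures
  (everywhere thinner than twice the rim) return the whole mask.
- Resampling grids align voxel centers at `index × spacing` and cover the
  same physical extent (`floor((n−1)·s/t)+1` output samples per axis).
- Model serialization writes 17 significant digits so reloaded models
  reproduce scores exactly.
- Every stochastic step (cohort generation, splits, CV folds, fold
  stratification) is seeded; a pipeline run is a pure function of its
  settings and seed.

## Problem sizes used by the test suite

The suite exercises the full study geometry (n = 182 with all eight RFGs)
for the end-to-end checks across ten generator seeds, twelve zero-effect
cohorts for the overfitting guard, reduced cohorts (n = 96, whole-ROI
family) for the dose–response property at three effect sizes, n = 60
single-phase cohorts at enlarged tumor sizes for the ROI-specificity
property, and volumes of at most 8^3 voxels for the brute-force oracle
comparisons (50 random masked volumes). These sizes were chosen so each
property is measured where it is statistically meaningful while the whole
suite stays comfortably rerunnable.

## Known limitations

- No MRI physics: no coil inhomogeneity, motion, registration error or
  bias field; phases are perfectly aligned by construction.
- The wavelet "ratio" semantics are a declared band-weighting convention,
  not a certified reproduction of any particular implementation; likewise
  the 64-feature roster is a fixed standard canon, not a verbatim copy of
  any specific software's list.
- The desert-vs-excluded endpoint rests on a small excluded class
  (16.5% prevalence, ~7 validation patients at n = 182), so its
  validation AUC is intrinsically noisy; under a null cohort the same
  small class makes a fixed AUC bound uninformative for this endpoint,
  which is why the overfitting guard is asserted on the whole-tumor
  fusion model.
- Survival analysis and histology image processing are out of scope; the
  CD8+ densities enter only as generated covariates.
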