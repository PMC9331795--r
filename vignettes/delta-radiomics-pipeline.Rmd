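---
title: "Early prediction of adaptive-replanning need from CBCT delta-radiomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Early prediction of adaptive-replanning need from CBCT delta-radiomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

During fractionated head-and-neck radiotherapy, tumours and organs at risk
change shape and volume from week to week. When the clinical target volume
(CTV) or the parotid glands (PG) change by more than about 20 %, the original
dose plan may no longer conform to the anatomy and the plan should be adapted
(adaptive radiotherapy, ART). Replanning every patient is prohibitively
expensive, so the clinically useful question is *triage*: can the patients
who will need adaptation be identified from the imaging already acquired in
the first treatment week?

`artpredict` implements a complete, testable pipeline for that question.
Patients are labelled by their ROI volume trajectory — Class 1 if the CTV
and/or PG voxel volume at week 4 differs from the week-1 baseline by strictly
more than 20 % (in absolute value; shrinkage and growth both count), Class 2
otherwise — and a classifier is asked to predict that label from
*delta-radiomics* features of the week-2 acquisition alone: the percentage
change of each radiomic feature relative to its week-1 value,
`100 * (f_w - f_1) / f_1`.

Cone-beam CT gray values are not calibrated Hounsfield units, which has two
consequences baked into the design: all discretization settings are explicit
and recorded, and features enter the model only as within-patient relative
changes, never as absolute values.

## The feature bank

Each patient-week yields 104 features per ROI (CTV and PG, hence 208 columns
per patient): 12 shape, 17 first-order and 75 second-order features (14 GLDM,
24 GLCM, 16 GLRLM, 16 GLSZM, 5 NGTDM). Feature ids are
`"{roi}_{family}_{name}"` and column order is fixed by `feature_registry()`.

Conventions, chosen once and used everywhere (`extraction_settings()`):

* **Discretization**: fixed bin width of 25 intensity units, with level 1
  anchored at the bin containing the in-mask minimum; a fixed-bin-count mode
  is available. Empty interior bins between 1 and Ng are retained rather than
  compacted, because level arithmetic in the GLCM marginals and the NGTDM
  depends on level spacing.
* **GLCM/GLRLM**: voxel distance 1, the 13 unique 3D direction offsets,
  features computed per direction and averaged. GLCMs are symmetrized and
  normalized per direction.
* **GLSZM**: zones are 26-connected components of equal level. **GLDM**:
  distance 1, dependence tolerance `alpha = 0`; the dependence index is
  stored as (count + 1) so small-dependence emphasis terms stay defined.
  **NGTDM**: distance 1; a voxel with no in-mask neighbour contributes zero
  difference but is still counted, so level counts always sum to the mask
  size.
* **Neighbourhoods are defined in voxel space**; anisotropic spacing is
  deliberately not resampled away (no interpolation is performed), and users
  of real data should be aware that neighbour distances are voxel distances.
* **Shape** is intensity-free: surface area and mesh volume come from a
  marching-tetrahedra triangulation of the 0.5 isosurface of the lightly
  smoothed (Gaussian, sigma 0.8 voxel) binary mask, which removes the
  staircase bias a binary midpoint mesh would add to the surface area (a
  sphere's sphericity converges to ~0.99 instead of plateauing near 0.8);
  axis lengths are `4 * sqrt(eigenvalue)` of the physical-coordinate
  covariance. Masks too small to support the isosurface fall back to
  voxel-face geometry, flagged.
* The 17-member first-order set is energy, total energy, entropy, minimum,
  10th/90th percentile, maximum, mean, median, interquartile range, range,
  mean absolute deviation, robust MAD, root mean squared, skewness, kurtosis
  (plain fourth standardized moment, not excess) and population variance.
  Where reference texts print inconsistent formulas for
  long-run-low-gray-level emphasis, the standard LRLGLE definition
  (`sum P j^2 / i^2`) is used.
* **Degenerate regions** (single gray level) make several expressions 0/0;
  rather than dropping patients, documented fallbacks keep the vectors
  finite and are flagged in the vector's `flags` attribute: GLCM correlation
  and MCC fall back to 1, skewness/kurtosis and variance-type terms to 0,
  NGTDM coarseness to 1e6.

Every matrix family is verified in the test suite against an independent
brute-force enumeration on random volumes, and the formula set against
direct per-entry summation at 1e-9 relative tolerance.

## Feature selection: SVM-RFE with correlation bias reduction

Features (z-scored with training-fold statistics) are ranked by backward
elimination with a linear soft-margin SVM (cost 1, class-frequency-inverse
weights): at each iteration the squared hyperplane-normal components `w_i^2`
score the surviving features and the single worst feature is eliminated;
ties eliminate the larger column index, making the ranking deterministic.
The final ranking is the reverse elimination order.

Correlated feature groups dilute each other's SVM weights, so plain RFE
tends to discard an informative feature merely because a near-duplicate
shares its weight. The correlation-bias-reduction step counteracts this: at
every iteration, single-linkage clusters of surviving features with pairwise
`|r| >= 0.7` are formed (the correlation matrix is computed once per fold),
and each cluster member's criterion is recomputed from a refit that excludes
its cluster-mates. Setting the threshold to 1 disables the correction. The
test suite demonstrates the intended behaviour: with an informative feature
duplicated at r = 0.99, the worse-ranked copy sits markedly lower without
CBR than with it.

## Cross-validated subset search and evaluation

The study design is leave-one-out cross-validation (LOOCV) over the n = 40
patients. For every fold, RFE-CBR is run on the 39 training rows only,
giving 40 fold rankings; a consensus ranking orders the universe by (1) the
number of folds placing the feature in the top K = 25, (2) mean rank, (3)
feature id. Subset sizes 1..30 are scanned by adding one ranked feature at a
time, and the smallest size maximizing LOOCV *weighted accuracy* — read as
balanced accuracy, the mean of sensitivity and specificity, with Class 1
(significant change) as the positive class — is the optimal size. The
reported subset is the consensus top at that size.

One design point was genuinely open: *which* ranking drives the size scan.
Scanning the global consensus subset in every fold looks natural but leaks
information — the consensus pools rankings from folds whose training data
include the held-out row, and on effect-free data the "optimal" accuracy
then lands far above chance. The default
(`curve_mode = "fold"`) therefore scans each fold's own ranking, so the
held-out row never influences the subset it is scored on; on null data the
optimal accuracy falls back near 0.5 (the residual upward drift is the
expected maximum-over-sizes optimism), which the acceptance suite checks.
The leaky variant is retained as `curve_mode = "consensus"` for sensitivity
analysis.

The supporting statistics mirror the rest of the design: the confusion-based
metrics include F1 and a trapezoidal AUC over pooled LOOCV decision values
(pooling, rather than per-fold averaging, was chosen because single held-out
decisions carry no ROC of their own); significance comes from label
permutations, `p = #(perm accuracy >= observed) / n_perm`, with the
conservative `>=` by default and the strict `>` available. The default
permutation mode keeps the selected subset fixed; a `"full"` mode reruns
ranking, consensus and search per permutation for when the selection step
itself must be under the null. Per-week stability refits the fixed reported
subset on each week's delta table; because that subset was selected on the
week-2 table, the week-2 stability row is an apparent (selection-biased)
accuracy and can exceed the nested headline estimate — the comparison
across weeks, not the absolute level, is the informative part. Post-hoc
tools compute per-feature one-way ANOVA between the classes (uncorrected,
as a descriptive screen) and Pearson correlations between selected features
and the ROI volume changes, to check the features carry information beyond
volume itself.

## The synthetic cohort generator

No patient data ship with the package; `simulate_cohort()` generates the
study conditions instead. Defaults: 40 patients, class-1 fraction 19/40,
5 weekly volumes on a 36 x 36 x 24 grid at 2 x 2 x 3 mm. The CTV is an
ellipsoid and the PG a two-lobe union treated as one ROI; weekly shrinkage
rescales semi-axes so the fractional volume loss follows a ramp reaching its
class target at week 4 (Class 1 mean 0.35, clamped ≥ 0.26; Class 2 mean
0.08, clamped ≤ 0.15 — margins that keep voxelization noise from crossing
the 20 % rule, which is asserted per patient). Texture drift is a
class-scaled interior mean shift plus a change in noise correlation length,
ramping with week; `texture_effect_size` scales it and 0 disables it. The
intensity scale (background ~60, ROI contrast +35 to +55, noise sd 20) is
arbitrary by design, giving roughly 6-10 gray levels at bin width 25. No
effect-size information for week-2 deltas exists to copy, so these defaults
are calibration choices made once.

`simulate_feature_table()` is the table-level stand-in used for selection
and evaluation experiments: 208 registry columns of exchangeable noise
(percentage units, sd 10) with `n_informative` planted columns shifted by
`texture_effect_size` standard deviations between classes (alternating
sign), optionally duplicated at a stated correlation to exercise CBR.

What the generator does *not* emulate — and hence what passing tests do not
establish about real data: registration and contour-propagation error,
scanner- and FOV-dependent intensity artefacts, scatter, correlated
multi-feature drift beyond the planted mean/correlation-length changes, and
irregular (non-ellipsoidal) anatomy. A null regime (equal sub-threshold
volume drops, zero texture effect) exists purely for calibration
experiments.

## Numerical choices and problem sizes

All randomness flows from explicit integer seeds; a fixed configuration
reproduces cohorts bit-identically. The heavy experiments in the test suite
run at sizes chosen to probe the properties without excess: matrix oracles
on 50 random volumes up to 6^3; planted-recovery over 20 seeds at the full
n = 40 x 208 table; null calibration over 50 replicates at n = 40 with 60
columns (accuracy centring) and n = 20 with 100 permutations (p-value
uniformity, against a pre-specified subset so the statistic is genuinely
pivotal under the null).

## Known limitations

* With 19 planted columns at a 1.5 SD shift, LOOCV accuracy saturates at
  1.0 well before 19 features have been added, and the smallest-size
  tie-break then fixes small optimal subsets (typically 3-10 features).
  The optimal subset is therefore nearly noise-free (precision ~1) but
  recovers only part of the planted set (median recall ~0.45 in the
  recovery experiment) — an intrinsic property of accuracy-maximizing
  subset selection under strong signal, recorded honestly by the
  corresponding acceptance test rather than hidden.
* Surface area of very small or thin masks falls back to voxel-face
  geometry; sub-voxel accuracy is not attempted.
* The per-feature ANOVA is a descriptive screen without multiplicity
  correction; with 208 features, individual p-values near 0.05 are not
  evidence.
* Runtimes are dominated by the per-fold RFE (one SVM refit per eliminated
  feature); the packaged trainer is libsvm invoked directly through its
  compiled interface, with equivalence to `e1071::svm()` asserted in the
  suite.
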