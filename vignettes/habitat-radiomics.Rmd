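---
title: "Habitat radiomics for tumor grade prediction: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Habitat radiomics for tumor grade prediction: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The analysis

`habitomics` implements a complete habitat-radiomics workflow for predicting
binary tumor grade (WHO/ISUP low I–II vs. high III–IV) from 3-D
contrast-enhanced images with tumor masks:

1. **Preprocessing** — bias-field correction, resampling to isotropic
   1 × 1 × 1 mm³, and z-score intensity normalization, in that fixed order.
2. **Region geometry** — peritumoral rings at 1–5 mm outward physical
   distance from the tumor margin, computed with an exact Euclidean distance
   transform on the physical grid.
3. **Habitat segmentation** — a 5 × 5 × 5 sliding window maps every tumor
   voxel to 19 local first-order statistics; K-means is fitted on the pooled,
   z-scored voxels of the training patients, with the cluster count k chosen
   by maximizing the Calinski–Harabasz (CH) index over k = 2–10.
4. **Feature extraction** — 1,015 radiomic features per region: 14 shape
   descriptors plus 91 intensity features (18 first-order, 22 GLCM, 16
   GLRLM, 16 GLSZM, 5 NGTDM, 14 GLDM) on each of 11 image types (original,
   8 stationary 3-D Haar wavelet sub-bands, Laplacian-of-Gaussian at two
   scales). The integrated habitat vector concatenates the three per-habitat
   vectors (3 × 1,015 = 3,045).
5. **Feature selection** — ICC(2,1) ≥ 0.75 reliability filtering against a
   second reader (habitat features are exempt: unsupervised regions have no
   second-reader counterpart), z-score standardization, Shapiro-gated
   t / Mann–Whitney univariate filtering at α = 0.05, greedy |r| > 0.9
   correlation pruning, and LASSO logistic regression with 10-fold
   cross-validated λ.
6. **Modeling** — five classifiers (logistic regression, SVM, random
   forest, extremely randomized trees, gradient-boosted trees) tuned by
   5-fold CV per region; one model per region (intratumoral, five rings,
   three habitats, integrated habitat); clinical covariates screened by
   univariate → multivariate logistic regression; a final nomogram fuses
   the independent clinical predictor with the intratumoral, 2-mm
   peritumoral and integrated-habitat radscores (predicted probabilities).
7. **Evaluation** — ROC/AUC with DeLong confidence intervals and paired
   DeLong tests, Youden-threshold confusion metrics, equal-frequency
   calibration curves with Brier scores, decision-curve net benefit, and
   permutation-sampling Shapley attributions.

Every stage is driven by `run_pipeline()`, which derives all stage seeds
from one master seed and writes per-stage artifacts (CSV/JSON, optionally
NIfTI) plus a manifest, so reruns are bit-identical.

## The synthetic cohort

No patient data ships with the package. `generate_cohort()` emulates
corticomedullary-phase kidney-tumor MRI at the level the pipeline consumes:

* a deformed ellipsoidal tumor (radii 19–24 mm low-grade, 21–28 mm
  high-grade, matching typical renal-tumor sizes) inside a parenchyma slab
  on a 72³ grid at 1 mm spacing;
* three concentric subregions mirroring the radiological reading of renal
  tumor habitats — an enhancing rim (outer 30% of the radius), a necrotic
  core, and a transitional shell — with smooth random boundary deformation;
* voxel intensities built from a per-habitat mean plus a spatially
  correlated texture field plus white noise. The defaults place the three
  habitats at distinct positions in *both* intensity and texture: the core
  is darkest and most heterogeneous, the transitional shell intermediate in
  level and most homogeneous, the rim brightest. This joint contrast is
  what makes the three habitats a genuine three-cluster structure for the
  19-channel window statistics: subregions that differed in mean intensity
  alone would be collinear in feature space, where the between-cluster
  variance captured by a 2-cluster split is large enough that the CH index
  systematically prefers k = 2. Radiologically the joint contrast is the
  realistic description as well — necrosis is both hypo-enhancing and
  heterogeneous. Voxel-level distributions of neighboring habitats overlap
  (gaps of 25–30 intensity units against within-habitat SDs of 10–55), so
  single-voxel classification is impossible and the window statistics are
  genuinely needed;
* a smooth multiplicative bias field (log-amplitude 0.15) removed later by
  preprocessing;
* a second reader's mask obtained by jittering the boundary with a smooth
  signed-distance offset of up to 1 mm (Dice against reader 1 typically
  0.95–0.99, so reliability filtering is exercised without being
  saturated);
* grade-linked clinical covariates: high-grade prevalence 27%, larger and
  more necrotic high-grade tumors, and a strong association between high
  grade and a "low corticomedullary enhancement" rating
  (P(low | high) = 0.65 vs. P(low | low) = 0.20), plus neutral covariates
  (age, sex, diabetes history) for the screening stage to reject.

What the generator does **not** emulate: MRI physics (k-space, partial
volume, motion), organ anatomy, multi-sequence acquisitions, or
histopathologically validated habitat biology. Passing tests therefore
demonstrate that the pipeline's statistical machinery behaves correctly on
data with known structure — not that the defaults reproduce any clinical
cohort's effect sizes.

## Parameters that matter

| Parameter | Default | Rationale |
|---|---|---|
| voxel spacing | 1 mm isotropic | resampling target; rings and windows are defined in physical mm |
| sliding window | 5 × 5 × 5 | local feature support; voxels with < 8 in-mask neighbors are invalid |
| habitat k range | 2–10 | CH-maximizing selection range |
| K-means restarts | 10 | multi-start stability |
| voxel subsample | 2 × 10⁴ | pooled-voxel cap for fitting; CH rankings are stable at this size and fits stay desk-scale on one CPU |
| ring distances | 1–5 mm | peritumoral candidate extents |
| bin width | 25 | gray-level discretization, on the ×100 normalized scale (z-score alone would collapse a width-25 bin grid to one bin) |
| LoG scales | 2, 3 mm | band-pass scales of the filter bank |
| ICC threshold | 0.75 | standard adequate-reliability cut |
| correlation threshold | \|r\| = 0.9 | redundancy pruning |
| univariate α | 0.05 | retention threshold |
| LASSO CV | 10-fold, deviance-minimizing λ | the 1-SE rule is available via `rule = "1se"` |
| tuning CV | 5-fold, AUC-maximizing | per-algorithm grid search |

## Numerical and design choices

* **Cohort-level clustering.** One habitat model is fitted on pooled
  training voxels and applied to every patient (training and test alike),
  so labels H1..Hk are comparable across patients — a precondition for
  per-habitat models. Channels are z-scored with pooled training statistics;
  per-patient clustering and raw channels remain available as options.
* **Label ordering.** Clusters are relabeled H1..Hk by descending
  windowed-mean-intensity center, so H1 is always the strongest-enhancing
  habitat.
* **Window support.** The model is fitted on all valid voxels, but direct
  nearest-center assignment is restricted to complete-window voxels;
  mask-edge voxels, whose truncated windows sample asymmetrically inward
  and whose sum-type channels (Energy, TotalEnergy) scale with the support
  count, inherit the label of their nearest interior neighbor by
  breadth-first propagation. Ties propagate in deterministic queue order.
* **Pipeline k floor.** The downstream model set (HabitatH1–H3 and the
  3,045-feature integrated region) is defined on three habitats. When the
  CH selection over the configured range lands below 3, `run_pipeline()`
  refits with the range clipped to k ≥ 3 and records both selections in the
  manifest. The unconstrained selection remains available through
  `fit_habitat_model()`.
* **Bias correction.** The default backend fits a degree-≤3 polynomial to
  log intensities over the body region (on an evenly strided 2 × 10⁴-voxel
  subsample) and divides out the exponentiated field, normalized to mean
  one. An external N4 implementation can be substituted via the `backend`
  argument. Non-positive intensities trigger a shift-then-fit with a
  warning.
* **Normalization region.** Z-scoring uses the whole body (non-air,
  Otsu-thresholded) region rather than the tumor, so habitat intensity
  contrasts remain comparable across patients; the result is scaled by 100.
* **Ring definition.** A ring holds voxels outside the tumor whose
  center-to-nearest-tumor-center Euclidean physical distance is ≤ d mm
  (ties included), clipped at the image boundary; an optional body-mask
  clip exists but rings are not restricted to parenchyma by default.
* **Shape features.** Surface area uses the co-area formula on a
  Gaussian-smoothed indicator (accurate to ~1% on spheres; voxel-face
  counting would overestimate by ~50%); mesh volume is the smoothed
  indicator's integral; axis lengths come from the principal components of
  the voxel coordinates.
* **Missing habitats.** A habitat with fewer than 10 voxels in a patient
  yields a missing-flagged 1,015-vector, which flows into KNN imputation
  (k = 5, fitted on training rows only, distances on standardized
  mutually-observed features). Observed cells are never altered.
* **Degenerate data.** Constant features are dropped with a warning at
  z-scoring; a single LASSO candidate passes through (the L1 path needs two
  columns); classes smaller than three observations skip cross-validated
  LASSO with a warning; SVM probability fitting falls back to a logistic
  sigmoid on decision values when the internal Platt CV cannot run; empty
  predicted classes report NaN PPV/NPV, flagged.
* **Selection policy.** `select_best_algorithm()` defaults to the
  leakage-free CV policy. The `paper_faithful` policy — picking the highest
  test-set AUC per region, as in the workflow this package operationalizes —
  is provided but emits an explicit selection-bias warning. Ties break by
  the fixed order LR < SVM < RF < ExtraTrees < GBM.
* **Radscore.** Defined as the predicted probability of high grade, so all
  model outputs live on [0, 1]; the nomogram is a logistic regression on
  the clinical predictor plus three radscores, with a 0–100 points mapping
  per input.
* **Thresholds.** Youden-optimal on training scores, frozen and applied
  unchanged to the test cohort.
* **Attributions.** Shapley values are estimated by sampled feature
  permutations against a background set; because each permutation's
  marginal contributions telescope, local accuracy (attributions + base
  value = prediction) holds exactly for any number of permutations.

## Problem sizes used by the tests

The packaged experiments are sized for a single CPU: unit tests use 32–40³
phantom grids; the habitat-recovery experiment uses 20 replicates of
20-patient cohorts at the default 72³ grid (k = 3 expected in ≥ 90% of
replicates, mean adjusted Rand index vs. the planted truth ≥ 0.8); the
end-to-end demonstration runs 40 patients on a 48³ grid with 9–16 mm tumor
radii, which keeps the full 12-model analysis (Clinic, Intra, Peri1–5mm,
HabitatH1–H3, Habitat, Combined) within a few minutes. At the demo scale
the miniature tumors under-resolve the transitional shell, which is why the
pipeline's k floor exists; the recovery experiment at the default scale
needs no such floor.

## Known limitations

* The extractor follows the standard 7-class/11-image-type layout and its
  counts, but individual texture values are not calibrated against any
  external radiomics implementation; analyses mixing extractors should not
  assume numerical interchangeability.
* Habitat ARI against planted truth is bounded by the window's spatial
  averaging: voxels within ~1 voxel of a habitat interface carry mixed
  windows and a fraction of them are inevitably misassigned.
* The nomogram's points table is emitted as data; graphical rendering is
  out of scope.
* DeLong intervals are normal-approximation and degenerate under perfect
  separation (flagged rather than bootstrapped).
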