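# habitomics

Habitat radiomics for noninvasive tumor grading. The package implements a
complete, tested pipeline for predicting binary WHO/ISUP nuclear grade
(low I–II vs. high III–IV) of renal tumors from 3-D contrast-enhanced
images and tumor masks, organized around three complementary feature
sources:

* **intratumoral** radiomics of the segmented tumor volume;
* **peritumoral** radiomics of rings grown 1–5 mm outward from the tumor
  margin (exact Euclidean distance transform on the physical grid);
* **habitat** radiomics of tumor subregions found by K-means clustering of
  voxel-level feature vectors — each voxel is summarized by 19 first-order
  statistics over a 5×5×5 window, clusters are fitted cohort-wide on the
  training set, and the cluster count k maximizes the Calinski–Harabasz
  index CH(k) = [B/(k−1)] / [W/(n−k)] over k = 2–10.

Each region yields 1,015 radiomic features (14 shape + 91 intensity
features × 11 image types: original, 8 stationary 3-D Haar wavelet
sub-bands, LoG at σ = 2 and 3 mm); the integrated habitat region
concatenates its three subregions (3,045 features). Features pass through a
selection cascade — ICC(2,1) ≥ 0.75 inter-reader reliability (habitat
features exempt), z-scoring, Shapiro-gated t / Mann–Whitney filtering at
α = 0.05, |r| > 0.9 correlation pruning, LASSO logistic regression with
10-fold cross-validated λ — and into five classifiers (LR, SVM, RF,
ExtraTrees, gradient-boosted trees) tuned by 5-fold CV. A final nomogram
fuses the independent clinical predictor with the intratumoral, 2-mm
peritumoral and integrated-habitat radscores. Evaluation covers DeLong
AUC inference (CIs and paired tests), Youden-threshold confusion metrics,
calibration curves with Brier scores, decision-curve net benefit, and
exactly locally-accurate Shapley attributions.

Because no patient data ships with the package, a seeded synthetic cohort
generator (`generate_cohort()`) produces 3-D kidney-tumor volumes with
three planted intensity/texture-distinct habitats, dual-reader mask
variability, a multiplicative bias field, and grade-linked covariates at
27% high-grade prevalence. Every stage of the pipeline is exercised and
tested against this generator. See the methods vignette
(`vignettes/habitat-radiomics.Rmd`) for the models, parameter rationale and
limitations.

## Worked example

```r
library(habitomics)

cfg <- run_config(master_seed = 7, out_dir = "demo_run")
res <- run_pipeline(cfg, verbose = TRUE)

res$habitat_model$k
#> [1] 3

res$clinical_screen$independent
#> [1] "enhancement_low"

head(res$report$test$metrics[, c("model", "auc", "accuracy", "sensitivity",
                                 "specificity")], 5)
#>     model       auc  accuracy sensitivity specificity
#> 1  Clinic 0.5857143 0.5833333         0.6   0.5714286
#> 2   Intra 0.8000000 0.6666667         0.6   0.7142857
#> 3 Peri1mm 0.7714286 0.6666667         0.2   1.0000000
#> 4 Peri2mm 0.8571429 0.6666667         0.2   1.0000000
#> 5 Peri3mm 0.8285714 0.7500000         0.8   0.7142857
```

This runs the full analysis on the 40-patient demonstration cohort (48³
grid): simulation, preprocessing, rings, habitat fitting and assignment,
extraction of all 12 region/reader tables, imputation, ICC filtering, the
selection cascade, five-algorithm training per region, the clinical screen
(here correctly recovering the planted low-enhancement predictor), the
nomogram, and the two-cohort evaluation report of all 12 models (Clinic,
Intra, Peri1–5mm, HabitatH1–H3, Habitat, Combined). Artifacts — clinical
table, habitat fractions, ICC report, per-cohort metrics, DeLong matrices
and a manifest — are written to `out_dir`; the run is bit-identical under a
fixed `master_seed`. Training-set AUCs on the demo cohort are near 1
because the miniature synthetic tumors separate grade strongly; the test
columns above show the usual small-cohort shrinkage.

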