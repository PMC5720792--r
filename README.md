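# tumortex

Slice-wise CT texture analysis for predicting 2-year survival in
pancreatic ductal adenocarcinoma (PDAC), for imaging researchers who want
the full pipeline — feature extraction, feature selection, and nested
cross-validated classification — as tested, reusable R functions.

PDAC on portal-venous CT spans a continuum from homogeneously
isoattenuating to heterogeneously hypovascular tumors, and that
heterogeneity plausibly encodes outcome-relevant biology. `tumortex`
quantifies it with a 255-feature tumor descriptor computed per axial slice
on the segmented tumor and averaged over slices:

| Block | Features | Family |
|---|---|---|
| G1–G19 | 19 | gray-level co-occurrence matrix (d = 2 px, N = 16 levels, four directions): 14 Haralick statistics + inertia, cluster shade, cluster prominence, Renyi entropy (q = 8), Tsallis entropy (r = 2) |
| R1–R11 | 11 | run-length matrix statistics, direction-averaged |
| L1–L128 | 128 | local binary patterns: ULBP histogram, RI-ULBP histogram, histogram statistics, LBP histogram-Fourier magnitudes |
| F1_1–F1_48 | 48 | segmentation-based fractal texture analysis (8 multi-Otsu thresholds → 16 binary images × border FD, mean gray, size) |
| F2_1–F2_6 | 6 | differential box-counting FD image (7×7 windows): max/mean of per-slice mean, sd, lacunarity |
| I1–I5 | 5 | intensity histogram: mean, sd, skewness, kurtosis, entropy |
| A1–A19, M1–M19 | 38 | angle co-occurrence matrices of Sobel gradient orientations (l = 1, 8 bins), count-weighted (ACM1) and magnitude-weighted (ACM2), same 19 statistics as the GLCM |

Features are ranked by fuzzy minimum-redundancy maximum-relevance
selection — incremental maximization of
`MI(f; c) − mean MI(f; selected)` with fuzzy mutual information — and the
subset size is chosen by forward selection on the leave-one-out error of a
Gaussian naive Bayes classifier (equal priors, 0.5 posterior threshold).
Evaluation uses leave-one-image-out and repeated stratified 3-fold
cross-validation with the entire selection pipeline re-run inside every
training fold. Results report AUC, accuracy, sensitivity, and specificity,
with survival ≥ 2 years as the positive class.

Because no clinical cohort ships with the package, a deterministic
synthetic tumor-volume generator emulates the study conditions (20 short
vs 15 long survivors, 1–4 cm³ ellipsoidal tumors at CT voxel spacing):
short survivors carry oriented band-limited texture with necrosis-like
hypointense blobs, long survivors a near-isotropic smooth texture, with a
`texture_effect` dial from exchangeable classes (0) to fully expressed
regimes (1). See the methods vignette
(`vignettes/texture-survival-pipeline.Rmd`) for the model, conventions,
and design rationale.

## Worked example

```r
library(tumortex)
cohort   <- generate_cohort(cohort_spec(seed = 11))   # 20 + 15 tumors
features <- build_cohort_table(cohort)                # 35 x 257 tibble
features[1:4, 1:5]
#> # A tibble: 4 × 5
#>   patient_id label glcm.G1_energy glcm.G2_contrast glcm.G3_correlation
#>   <chr>      <int>          <dbl>            <dbl>               <dbl>
#> 1 P001           0        0.0127              8.24               0.617
#> 2 P002           0        0.0127             10.9                0.427
#> 3 P003           0        0.0112              9.03               0.473
#> 4 P004           0        0.00923            11.6                0.543

cv <- loo_cv(features, family = "acm2")               # nested selection per fold
cv
#> <tumortex_cv> leave-one-image-out | family=acm2
#>   AUC 0.893 | Ac 88.6% | Sn 0.87 | Sp 0.90
glance(cv)
#> # A tibble: 1 × 6
#>     auc accuracy sensitivity specificity protocol            family
#> 1 0.893    0.886       0.867         0.9 leave-one-image-out acm2
autoplot(cv)                                          # ROC curve
```

Each row of `features` is one tumor; the per-patient posterior scores are
available via `tidy(cv)`. The AUC of 0.893 says the magnitude-weighted
angle co-occurrence family alone separates the two synthetic texture
regimes almost perfectly at full `texture_effect`; intensity-histogram
features (`family = "ih"`) do markedly worse on the same cohort, mirroring
the edge-versus-intensity ordering the method was built around.

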