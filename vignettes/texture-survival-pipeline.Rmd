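---
title: "CT texture analysis for two-year survival prediction: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{CT texture analysis for two-year survival prediction: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tumortex)
```

## The problem

Pancreatic ductal adenocarcinoma (PDAC) on portal-venous CT ranges from
homogeneously isoattenuating masses to heterogeneously hypovascular tumors,
and that heterogeneity plausibly reflects histologic or genetic differences
that correlate with outcome. `tumortex` implements a slice-wise texture
pipeline for segmented tumors: a 255-feature descriptor per tumor, fuzzy
minimum-redundancy maximum-relevance (fMRMR) feature ranking, forward
selection of the subset size, and a Gaussian naive Bayes classifier
evaluated under leave-one-image-out (LOO) and repeated stratified 3-fold
cross-validation, with selection nested inside every training fold. The
binary endpoint is 2-year overall survival (label 1 = survival of at least
2 years).

Because no clinical imaging cohort is distributed with the package, a
synthetic tumor-volume generator stands in for the data: it is first-class,
tested code, and the package's empirical claims are claims about these
synthetic cohorts, not about patients.

## The descriptor

Features are computed per axial slice on the tumor region of interest
(cropped to the mask bounding box) and averaged over all qualifying slices;
only the fractal-dimension-image family uses its own cross-slice max/mean
rule. The registry order is fixed: G1–G19, R1–R11, L1–L128, F1_1–F1_48,
F2_1–F2_6, I1–I5, A1–A19, M1–M19.

* **GLCM (G1–G19).** Gray levels are quantized per slice into `N = 16`
  equal-width bins over the in-mask range (the range-relative convention
  makes every co-occurrence feature invariant to intensity shifts). Pairs
  at distance `d = 2` pixels are counted symmetrically along 0/45/90/135
  degrees; each directional matrix is normalized and the four are averaged.
  Nineteen statistics follow: the 14 Haralick features, inertia, cluster
  shade, cluster prominence, Renyi entropy of order `q = 8`, and Tsallis
  entropy of order `r = 2`. The Tsallis value is computed as
  `sum(P^r) / (1 - r)`; the conventional `(1 - sum(P^r)) / (r - 1)` form is
  available behind `tex_config(tsallis_conventional = TRUE)` — the default
  follows the method description as printed rather than silently
  correcting it. All entropies are base-2 with `0 log 0 = 0`. The maximal
  correlation coefficient is numerically fragile; on degenerate marginals
  it falls back to 0, the one documented exception to the package's exact
  invariance claims.
* **Run-length matrix (R1–R11).** Maximal constant-level runs along the
  four directions, broken at the mask boundary; the classical eleven
  statistics (SRE, LRE, GLN, RLN, RP, LGRE, HGRE, SRLGE, SRHGE, LRLGE,
  LRHGE), averaged over directions. The source method cites eleven
  features without naming them; this is the standard eleven-feature set
  matching that count.
* **LBP (L1–L128).** 3×3 local binary patterns with `neighbor >= center`
  setting the bit, neighbors ordered circularly starting east. The block
  is the normalized 59-bin uniform-pattern histogram, the 10-bin
  rotation-invariant uniform histogram, 21 histogram statistics, and 38
  histogram-Fourier values (`|H(n, u)|` for the seven non-constant uniform
  rows at `u = 0..4`, plus the three rotation-invariant singleton bins —
  the only decomposition that yields exactly 38 for eight neighbors). The
  described arithmetic requires 21 statistics while the enumerated recipe
  (standard deviation, skewness, kurtosis, entropy over the LBP, ULBP,
  RI-ULBP, RI-LBP, rotated-LBP histograms) yields 20; the 21st is defined
  here, explicitly, as the entropy of the normalized histogram-Fourier
  magnitude spectrum. The rotated-LBP alignment rule shifts the code so
  the neighbor with the largest absolute difference from the center sits
  at bit 0 (ties to the first such neighbor). Both choices are isolated in
  the registry so they could be swapped without touching the other 127
  features.
* **SFTA (F1_1–F1_48).** The slice is min-max normalized and 8 multi-level
  Otsu thresholds are computed on the in-mask histogram by dynamic
  programming (128 bins). Sixteen binary images follow: 8 band images
  whose boundaries `{-inf, t1..t7, max}` partition the gray range (every
  in-mask pixel lies in exactly one band) and 8 upper-threshold images.
  Each image contributes its border box-counting fractal dimension (dyadic
  box sizes 1–8, least-squares slope), its mean normalized gray level, and
  its pixel count; empty images contribute zeros. Borders are foreground
  pixels with an in-mask background 4-neighbor — out-of-mask pixels never
  count as background.
* **DBC FD image (F2_1–F2_6).** A per-pixel differential box-counting
  estimate over each fully in-mask 7×7 window: the window is divided into
  `floor(7/s)` blocks per axis for `s = 2, 3, 7`, boxes of height
  `s·G/7` (G = window gray range) are stacked, and the FD is the
  least-squares slope of log total boxes against log blocks-per-axis.
  This grid convention makes a flat surface yield exactly 2. Per slice,
  the mean, standard deviation, and lacunarity (`E[X^2]/E[X]^2 - 1`) of
  the valid FD values are taken; the block reports their maximum and mean
  across slices.
* **Intensity histogram (I1–I5).** Mean, standard deviation, skewness,
  excess kurtosis of in-mask intensities, and the entropy of a 16-bin
  histogram over the in-mask range (matching the co-occurrence
  quantization depth). Zero-variance regions report 0 for the shape
  statistics.
* **ACM1/ACM2 (A1–A19, M1–M19).** Sobel gradients are computed only at
  pixels whose full 3×3 neighborhood is in-mask, so boundary pixels never
  contaminate the field. Orientations are quantized into `n_theta = 8`
  bins of 45 degrees over [0, 360); zero-magnitude pixels fall in bin 1 by
  convention. Pairs of valid pixels at displacement `l = 1` along the four
  directions are accumulated as counts (ACM1) or weighted by the sum of
  the two gradient magnitudes (ACM2, the literal reading of "sum of
  gradient magnitude responses"); matrices are normalized per direction
  and averaged, and the same 19 statistics as for the GLCM are extracted.
  A field with uniform magnitudes makes ACM2 equal ACM1; a field with all
  magnitudes zero carries no weight, and ACM2 falls back to occurrence
  counts — the uniform-weight limit.

Aggregation over slices is an unweighted mean ("averaged over the slices"
read literally); `tex_config(area_weighted = TRUE)` switches to
area-weighted means. Slices need `min_pixels = 9` in-mask pixels (a 3×3
operator footprint) to qualify. Non-finite feature values are zero-filled
with a warning rather than dropping patients, keeping cohort tables
complete for cross-validation.

## What is and is not invariant

Intensity-shift invariance holds for every feature except the
intensity-histogram mean, by construction (range-relative quantization,
normalized SFTA input, relief-based DBC, difference-based LBP and
gradients). Rotation by 90 degrees on square fully-masked regions leaves
the four-direction-averaged GLCM/RLM statistics, the intensity histogram,
RI-ULBP, and the LBP histogram-Fourier magnitudes unchanged to 1e-9. Three
families are *not* exactly rotation invariant, and the tests assert their
true behavior instead: raw uniform-LBP histogram bins permute under
rotation (that is why the rotation-invariant variants exist); ACM
orientation bins shift cyclically by two positions, so the matrix is
equivariant rather than invariant; and the corner-anchored box grids of
SFTA and DBC make the fractal features approximately invariant only.

## Feature selection

Each feature is fuzzified with three triangular membership functions over
its empirical ranks, centered at the 10th/50th/90th rank percentiles and
forming a partition of unity; the class vector uses crisp two-set
membership. Rank-based membership makes the selection invariant to
strictly monotone transforms of any feature and robust to outliers at the
cohort sizes involved (n around 35); the set count is exposed as `n_sets`.
Fuzzy mutual information is computed from the fuzzy joint frequencies with
base-2 logs, clipped at zero.

The incremental fMRMR criterion picks first the feature with maximal class
MI, then repeatedly the feature maximizing class relevance minus mean MI
with the already-selected set; ties break to the lowest index so ranking
is deterministic. Forward selection walks the nested prefixes and scores
each with the leave-one-out misclassification rate of the Gaussian naive
Bayes classifier (equal priors, 0.5 threshold), returning the smallest
size attaining the minimum. The subset-size cap defaults to
`min(D, n - 2)` so the per-class leave-one-out variance estimates stay
defined. The internal LOO sees only the data handed to it; the
cross-validation drivers guarantee held-out patients never reach
fuzzification, ranking, selection, or fitting (a test corrupts a held-out
row and verifies the fold's selection is unchanged).

## Classification and evaluation

The Gaussian naive Bayes model stores per-class feature means and
variances, floored at `1e-9` times the overall feature variance, with
equal priors regardless of fold imbalance. Posteriors are computed in the
log domain. The positive class is survival ≥ 2 years; scores at the 0.5
threshold classify positive. AUC is the trapezoidal area, which equals the
Mann-Whitney rank statistic with ties counted one half — both facts are
tested against an exhaustive pair-counting oracle.

Leave-one-image-out repeats the *entire* selection pipeline on each
training set of n − 1 patients. Repeated stratified 3-fold
cross-validation (20 repeats by default) deals shuffled class members
round-robin into folds, continuing the deal across classes so every fold
is populated; metrics are computed on the pooled out-of-fold scores of
each repeat and then averaged over repeats. With k = n this reduces
exactly to leave-one-image-out, which is also the package's equivalence
test. Stratification is not part of the original description (its
randomization is unspecified); it is the default here because unstratified
3-fold partitions of a 20/15 cohort can produce single-class training
folds.

## The synthetic cohort generator

`generate_cohort()` emulates the study conditions: 20 short survivors
(label 0) and 15 long survivors (label 1) by default, ellipsoidal tumors
with in-plane diameters of 14–20 mm and 3–5 axial slices at the CT voxel
spacing (0.7324, 0.7324, 2.5) mm — roughly 1–4 cm³, matching the reported
tumor-volume range — with pseudo-HU intensities in the portal-venous
soft-tissue band [20, 120].

Both classes share a smooth isotropic base texture (Gaussian field,
correlation length about 2.5 px, sd 8) plus white noise (`noise_sd = 2`)
and label-independent patient-level variation: a global attenuation offset
(sd 6) and a texture amplitude factor (0.85–1.15), emulating contrast
timing and vascularity differences. The `texture_effect` parameter scales
a label-specific component: short survivors receive band-limited oriented
noise — a smooth 1-D profile (correlation length 1.2 px) evaluated along a
randomized direction, so gradients concentrate on one orientation axis
while the intensity marginal stays Gaussian — plus a small isotropic
rough term and 1–3 hypointense necrosis-like blobs; long survivors receive
extra isotropic low-frequency structure of matched variance. At
`texture_effect = 0` the label branches contribute nothing and the classes
are exchangeable; at 1 the oriented regime is fully expressed. The design
makes the directional edge features (the angle co-occurrence families) the
discriminative axis, the first-order intensity statistics nearly matched
between classes, and the generator deterministic: per-tumor RNG streams
derive from the spec seed and patient index, so cohorts are
bit-reproducible and individual tumors can be regenerated alone.

What the generator does **not** emulate: CT physics (beam hardening,
reconstruction-kernel noise correlation), contrast kinetics, scanner
variation, segmentation error, or any validated model of PDAC biology.
Passing tests show the pipeline recovers planted texture structure at
clinically plausible geometry and cohort sizes — not that it predicts
survival in patients.

## Numerical choices and degenerate inputs

* Constant regions: quantize to level 1; LBP code 255; skewness/kurtosis
  0; histogram entropy 0; DBC FD exactly 2; ACM falls back to counts.
* Co-occurrence matrices must sum to 1 within 1e-9 (tested); directions
  with no valid pair are dropped from the average, and a region with no
  valid pair at all raises a typed degenerate-ROI error that the pipeline
  converts to NA-then-averaged (zero-filled with a warning if every slice
  degenerates).
* Box counts use a 1e-9 guard inside ceilings so floating-point jitter at
  box boundaries cannot flip counts between otherwise identical inputs.
* Ties: fMRMR breaks ranking ties by ascending feature index; forward
  selection returns the smallest size attaining the minimal error;
  classification ties at the threshold go to the positive class.
* Multi-Otsu collapses duplicate thresholds with a warning when the ROI
  has fewer distinct values than thresholds; empty binary images yield
  zero triples.

## Problem sizes used by the tests and the acceptance script

The shipped checks run on 32×32×8 volumes (the geometry above). The
calibration suite uses 20 null cohorts (LOO over all 255 features each);
the acceptance script recomputes the same quantity over 10 derived seeds,
its chosen problem size, alongside the high-effect cohort under both
protocols and 20 planted-selection replicates. The planted-selection
fixture (criterion: recover both planted indices with O = 2) uses a
complementary pair sharing an anti-symmetric nuisance factor, because with
independent Gaussian shifts a jointly-perfect pair forces one
near-perfect singleton, making exact-size recovery impossible at n = 40 —
a design observation, not a tuning artifact.

## Known limitations

* The 255-name registry is reconstructed from the per-family counts and
  orderings of the method description; the original supplementary list is
  not reproduced, so individual L/F1 indices may not align with the
  original numbering even though every family's count and order convention
  does.
* The maximal correlation coefficient falls back to 0 on singular
  marginals rather than propagating instability.
* Fuzzy mutual information uses a fixed three-set rank partition; the
  original fuzzification is cited but not restated in the source, so other
  membership shapes are plausible readings.
* Clinical performance numbers cannot be reproduced without the patient
  CTs; all empirical statements in this package are about its synthetic
  cohorts.

## A worked run

```{r example, eval = FALSE}
library(tumortex)
cohort <- generate_cohort(cohort_spec(seed = 11))
features <- build_cohort_table(cohort)
cv <- loo_cv(features, family = "acm2")
glance(cv)
autoplot(cv)
```
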