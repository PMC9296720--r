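---
title: "Methods: texture-based breast-density classification in breast CT"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: texture-based breast-density classification in breast CT}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The problem

Breast density — the relative amount of fibroglandular versus fatty tissue —
is graded on a four-level ordinal scale (*a* fatty … *d* extremely dense). On
dedicated photon-counting breast CT the grading is done visually and is
observer-dependent. This package replicates a radiomics workflow that asks
whether quantitative texture features of coronal breast-CT slices can stand in
for the human grading: extract 19 first- and second-order texture features per
examination, select the informative and mutually independent ones, classify
density with multinomial logistic regression, and quantify how reproducible
both the human grading and the features themselves are across readers.

Because the patient images behind the original study are not publicly
deposited, the package has two kinds of inputs:

* **synthetic phantom examinations** that emulate the relevant structure of
  breast-CT stacks, so every pipeline stage is testable end to end, and
* the **published summary tables** of the original study (shipped under
  `inst/extdata/`), used as worked-example inputs for the arithmetic that
  *is* reproducible at the desk: confusion-matrix recalls, reader agreement,
  and the feature-selection replay.

# The phantom generator

One examination is a stack of `n_slices = 50` coronal slices (25 per breast in
the original protocol; left/right are pooled into one analysis there, so we
model a single 50-slice stack) of 256×256 pixels at 0.3 mm isotropic spacing —
the reconstruction grid of the scanner protocol being emulated. Within a
disk-shaped breast support (radius 0.9 of the half-width) tissue is
two-component:

1. a per-slice Gaussian random field is smoothed with a Gaussian kernel of
   sigma `correlation_length_px = 10` pixels (3 mm — the scale of fatty
   septae and gland lobules);
2. the field is thresholded at its `1 - gland_fraction` quantile within the
   support: pixels above the threshold are gland, the rest fat. This yields
   connected gland regions interleaved with fat septae at an exactly
   controllable volume fraction;
3. gland pixels take intensity `gland_mean = 70`, fat pixels `fat_mean = 30`
   (arbitrary units — the grey-level normalisation step makes all features
   invariant to affine intensity changes), plus independent Gaussian noise of
   sd `noise_sd = 5`; pixels outside the support are 0.

The class anchors `gland_fraction_by_class = c(a = 0.10, b = 0.35, c = 0.60,
d = 0.85)` are invented plumbing: the published study gives no generative
model, only the qualitative picture of bimodal fat/gland histograms whose
peak ratio shifts with density. Only the strict ordering of the anchors is
load-bearing; they were chosen once to straddle the four-level scale
symmetrically and are config-overridable. With these settings the pooled
masked histogram of a class-*b* or *c* exam is clearly bimodal (peaks ≥ 20
units apart) and the class-mean skewness decreases strictly from *a* to *d*,
sign-consistent with the strong negative skewness–density correlation the
original study reports.

What the phantom does **not** model: X-ray physics, reconstruction kernels,
anatomy (skin, pectoralis, calcifications), intra-class biological
variability beyond field randomness, and left/right asymmetry. Consequently,
phantom-based tests demonstrate that the *pipeline machinery* behaves
correctly (monotone trends, above-chance classification, permutation
controls), not that the specific published feature values or accuracies are
recovered — those depend on patient images.

```{r}
library(bcttexture)
cfg <- phantom_config()
exam <- generate_phantom_exam(cfg, "c", seed = 42)
exam$true_gland_fraction   # realized within-support gland fraction, ~0.60
```

# Region of interest and grey-level preprocessing

A freehand ROI is modelled as a polygon in 0-based (x = column, y = row)
pixel coordinates; a pixel belongs to the raster mask iff its center
satisfies the even-odd rule (`polygon_to_mask()`; coordinates at pixel
centers make the operation oracle-checkable by brute force). The "5 mm margin
from the skin" of the original protocol is formalized as morphological
erosion with a disk structuring element of radius
`round(margin_mm / pixel_spacing_mm)` pixels — 17 px at the defaults — and
the eroded mask is propagated unchanged to every analysed slice, exactly as
one drawn ROI was reused across the 50 images. Slices to exclude (bone,
pectoralis in real data) are an explicit index list in `roi_spec()`, not an
anatomy detector.

Grey-level normalisation pools all masked pixels of an examination, clips to
mean ± 3 sd, and maps the clipped range linearly onto `N_g = 64` integer
levels. The original study says only that normalisation "minimises
intrascanner effects"; μ±3σ clipping with uniform binning is the standard
choice in the texture-analysis literature this feature set comes from, and it
makes every downstream feature exactly invariant to affine intensity changes
(asserted by tests). `N_g = 64` is likewise a documented default — the study
never states its quantisation — and is configurable; oracle tests use small
`N_g` so brute-force enumeration stays exact. Degenerate contract: a
constant region maps to level 1 and returns zero variance/skewness/kurtosis/
entropy rather than `NaN`.

# The 19 features

First order (pooled level histogram): variance, skewness, excess kurtosis,
Shannon entropy (bits), all with population (1/N) moments. Kurtosis is
*excess* kurtosis; the study's printed values are consistent with either
convention, so the choice is documented rather than inferred.

GLCM: distance 1, four in-plane directions (0°, 45°, 90°, 135°), both pixels
masked, counts accumulated over slices and directions, symmetrized, then
normalized; contrast, correlation, energy, homogeneity. GLCM correlation of
a single-cell matrix is defined as 1.

GLRLM: maximal runs of equal levels along the same four directions, an
unmasked pixel terminating a run, counts accumulated over slices and
directions; the eleven run statistics SRE … LRHGE, plus run percentage
`RP = N_r / N_p` with `N_p` = masked pixels × number of directions.

The original study states neither its offset distance, direction set nor
aggregation; accumulation (rather than per-direction averaging) is chosen
because it degrades gracefully on sparse masks, and all three choices are
exposed as arguments. Histograms and matrix *counts* are pooled across all
slices before features are computed — one value per examination — matching
the study's multislice analysis and its pooled histogram figure. The
accumulation kernels are implemented in C++ (as radiomics toolkits
customarily do); an independent brute-force R implementation in the test
suite must agree to 1e-9 on random masked images.

# Feature selection

The cascade mirrors the study's three steps:

1. **ANOVA + Bonferroni.** One-way ANOVA of each feature on class, then
   pooled-variance two-sample t-tests for all 6 class pairs with p × 6
   (capped at 1); a feature survives iff all six adjusted p < 0.05. The study
   says only "Bonferroni correction for pairwise comparison"; per-pair pooled
   t-tests are the plain reading, and a Welch variant would be a one-line
   change in `anova_with_bonferroni()`.
2. **Spearman versus density** (ordinal a = 1 … d = 4, average ranks).
   Survivors need p < 0.05 *and* |rho| > 0.50 — the study's own "moderate"
   boundary, consistent with its rejection of all weak-correlation features
   and of SRLGE (p = 0.363). Significance uses the raw p (the study applies
   no correction here). The p-value uses exact permutation enumeration for
   n ≤ 7 and the t-approximation beyond; the pipeline's own tables (n ≥ 40,
   heavily tied) always take the t-branch.
3. **Redundancy rejection.** Among any surviving pair with inter-feature
   |rho| ≥ 0.80, the member with the larger mean absolute correlation to all
   other step-1 candidates — the less independent one — is rejected
   (tie-breaks: lower |rho| versus density, then alphabetical; every
   rejection is logged machine-readably). This formalizes the study's
   narrative reasoning that kept GLN (independent, moderately correlated)
   over RLN (more strongly correlated with density but entangled with the
   first-order block). Replayed on the published summary tables the cascade
   yields exactly 11 step-1 candidates and retains {skewness, GLN}.

Qualitative statements in the published tables ("moderate to strong negative
correlation") are encoded with representative magnitudes (−0.6 / −0.7) in the
shipped fixture; the replay outcome is insensitive to the exact values — any
moderate magnitude gives the same rejection — and the fixture's `basis`
column separates stated from encoded entries.

# Classifier

Multinomial logistic regression with a softmax link, reference class *a*,
features standardized on training statistics, and a small L2 ridge
(`1e-4`) for separable-data stability (phantom classes separate almost
perfectly, so the unpenalized MLE diverges). The fit is delegated to
`nnet::multinom` (the tool the original analysis used), wrapped behind the
package's standardization/serialization contract; prediction is an explicit
softmax over the stored coefficients with ties broken by class order.
Evaluation uses a per-class stratified 70/30 split with the remainder row
assigned to training, confusion matrices with rows = true class, per-class
recall and overall accuracy in percent. Training and test metrics are
reported separately and labelled, since the original study quotes a training
accuracy (80.0%) but prints a test-set confusion matrix.

# Reader agreement

`percent_agreement()` and `cohens_kappa()` operate on K×K rating confusion
matrices; kappa uses marginal-product chance agreement and the Landis–Koch
verbal scale. `icc_absolute()` is ICC(2,1) — two-way random effects, absolute
agreement, single rater — from the mean-square decomposition with the
standard F-based interval; the variant is unstated in the original study, so
the choice is explicit output metadata. The per-feature inter-reader
coefficient of variation is computed per item as 100·sd/mean (sign carried,
so negative-valued features such as skewness can yield negative CVs, as in
the published range −6.9% … 10.9%) and averaged over items; zero-mean items
are flagged and excluded. Applying the standard kappa formula to the
published reader tables gives 0.866 and 0.844 where the study prints 0.86
and 0.83; the unrounded values are reported as-is since the study's rounding
cannot be reconciled from its text.

# Numerical and scale choices

* Problem sizes: the monotonicity suite uses 10 exams per class (40
  examinations) and the classifier suite 50 per class (200 examinations —
  the evaluated cohort size of the original study), both at the full default
  geometry. These sizes were fixed a priori as the package's study
  conditions.
* Memory: `generate_cohort()` materializes ~26 MB per default examination;
  `build_feature_table()` therefore streams (generate → extract → discard),
  so 200-exam cohorts need the memory of a single exam.
* Determinism: every stochastic step takes a seed; per-exam seeds derive
  from the master seed by a fixed affine map below 2^31. Identical inputs
  give bit-identical stacks, tables and fits.
* Degenerate inputs have fixed, tested contracts rather than NaNs: constant
  regions (levels → 1, moments → 0, GLCM correlation → 1), empty eroded
  masks (error naming the margin), constant features in selection (flagged,
  rho = 0, p = 1) and in the classifier (dropped with a warning).

# Known limitations

* Phantom realism ends at the two-component texture model; absolute feature
  magnitudes of the original study (its Table of descriptives) are not
  reproduction targets anywhere.
* The published homogeneity descriptives are internally inconsistent in
  print and are not used.
* The single-value published ICC (0.91, three readers) cannot be recomputed
  from the printed pairwise tables; the package reports pairwise ICCs from
  the reconstructed rating pairs instead.
* Higher-order texture matrices (GLSZM, NGTDM, wavelets) are out of scope by
  design.
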