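---
title: "Segmentation-free coronary stenosis grading: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Segmentation-free coronary stenosis grading: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stenomics)
```

## The problem and the modelling idea

Coronary artery disease (CAD) is graded from coronary CT angiography by the
degree of lumen narrowing. Clinically, the decisive stratification is into
three groups: no CAD (0% stenosis), nonobstructive CAD (<50%) and
obstructive CAD (>=50%). Manual CAD-RADS reading is slow and shows
inter-observer variability, and most automated radiomics approaches depend
on lesion segmentation, which is itself the bottleneck.

`stenomics` implements a segmentation-free alternative that operates on
straightened-vessel (multiplanar-reconstruction style) 2D images. Each
vessel is imaged in up to eight rotational views; each view is reduced to a
fixed rectangle around the straightened centerline; the rectangle is
characterised by two complementary feature domains:

* **Radiomic features** — 18 first-order statistics plus 75 texture
  features (24 GLCM, 16 GLRLM, 16 GLSZM, 5 NGTDM, 14 GLDM), computed on the
  original crop and on its four single-level 2D wavelet bands (LL, LH, HL,
  HH): 93 features x 5 image types = 465 values per image.
* **Learned features** — the bottleneck activations of a dense autoencoder
  trained to reconstruct the crops (mean-squared error, Adam), giving a
  64-dimensional latent vector at the reference scale.

The domains are fused column-wise and classified per image by a two-stage
random-forest cascade — (a) no CAD vs. any CAD, then (b) nonobstructive vs.
obstructive — and the patient label is the majority vote of the patient's
image-level decisions. Each stage runs its own z-scaling, a three-step
feature-selection chain (Spearman redundancy filter at |rho| > 0.95;
two-sided Wilcoxon rank-sum screen at alpha = 0.05, uncorrected; LASSO
logistic selection with seeded 5-fold cross-validation at the
one-standard-error penalty) and SMOTE minority oversampling, all fitted on
training rows only.

## The region of interest

The delineation is a 41-column rectangle — the centerline column plus 20
columns on each side, reconciling a "40-pixel-wide" band with the model's
854 x 41 input — whose lower boundary is the inferior image margin and
whose upper boundary excludes the ventricular-muscle band. Delineation is
performed on one view per vessel and propagated unchanged to the other
views. Vessels of different lengths are harmonised to exactly 854 rows
(107 in the downscaled configuration) by top-padding with the crop's median
intensity or symmetric center-cropping with the excess removed from the
top; both choices are recorded per image (`padRows`). Intensities are then
min-max normalized per image to [0, 1] — the autoencoder's sigmoid output
presupposes inputs on that scale — with the degenerate zero-range crop
mapping to all zeros. Padding/cropping to a fixed height and per-image
normalization are declared conventions: several harmonisation and
normalization conventions are defensible, and these particular choices
keep the bookkeeping deterministic and invertible.

## Radiomic extraction choices

* **Discretization**: 25 fixed-width bins spanning each image's own
  intensity range, re-discretized independently per image type; the
  maximum intensity falls in the top bin and a constant image maps to
  level 1.
* **Wavelet kernel**: Coiflet-1, the common radiomics default, applied as
  an undecimated single-level separable transform with periodic boundaries
  so every band keeps the crop's spatial shape. Filters are normalized so
  the four band energies sum to the input energy exactly (a property the
  test suite checks by Parseval identity).
* **Texture matrices**: distance 1; GLCM and GLRLM use the four 2D
  directions with per-direction normalized (GLCM) or count (GLRLM)
  matrices averaged — matrix averaging, not count merging, a documented
  convention. GLSZM zones, NGTDM neighbourhoods and GLDM dependences use
  8-connectivity; GLDM uses alpha = 0 (a neighbour is dependent when its
  level is identical) with dependence size counted as 1 + the number of
  dependent neighbours.
* **Mask**: the full rectangle. No lesion mask exists anywhere in the
  pipeline — that is the design point — so the feature count and names are
  identical for every image (the frozen registry, `featureRegistry()`).
* Degenerate-case conventions (zero variance, single occupied gray level)
  follow the conventions of widely used radiomics extractors: correlation-type
  features return 1, entropy-type features 0, NGTDM coarseness caps at
  1e6.

## The autoencoder

The three reference architectures share the halving width progression:
AE256 (35014-512-256), AE128 (35014-512-256-128) and AE64
(35014-512-256-128-64), each with the mirrored decoder, ReLU hidden
layers, a linear bottleneck and a sigmoid output. Counted over the encoder
(input to latent), the closed-form layer sum gives 18,100,160 / 18,091,904
/ 18,059,008 parameters for AE64/AE128/AE256 — a maximum pairwise gap of
41,152, under 0.23% — which is why `countParams()` defaults to
`scope = "encoder"`.

Training uses mean-squared error, Adam (default learning rate 0.001, the
lower end of the swept 0.1-0.001 range), batch size 48, up to 300 epochs at
full scale, no early stopping. Initialization is seeded Glorot-uniform;
shuffling and the validation split are seeded, so identical data + seed
reproduce the loss history exactly. Inputs are flattened row-major (a declared convention;
column-major flattening would work equally, but the choice must be fixed).
Reconstruction quality is scored by single-scale SSIM (11 x 11 Gaussian
window, sigma 1.5, data range 1), computed on the crop.

## What the synthetic generator emulates — and what it does not

Clinical CCTA cohorts of this kind are rarely publicly shareable, so the
package ships a seeded generator whose defaults are the study conditions
used throughout the tests:

* class mix 40/80/100 over no CAD / nonobstructive / obstructive (the
  referral-population proportions), three vessels per patient, eight
  rotational views per vessel, 10% of views missing at random (at least
  one view per vessel always survives);
* a bright, soft-edged lumen running down the image with per-row width
  following a raised-cosine stenosis profile; lesion maxima drawn from
  Uniform(0.05, 0.45) for nonobstructive and Uniform(0.50, 0.95) for
  obstructive vessels — margins away from the 0.50 boundary keep
  desk-scale tests stable;
* diffuse disease: every vessel of a diseased patient carries lesions from
  the patient's class range, so the patient label is recoverable by
  per-image majority voting (with focal single-vessel disease, two healthy
  vessels would out-vote the diseased one — a property of majority voting
  itself, not of the features);
* hyperdense (calcified-like) and hypodense (soft-plaque-like) blobs
  adjacent to lesions with class-dependent frequencies, giving texture
  features signal beyond pure geometry;
* a ventricular-muscle-like bright band above the ROI upper boundary, so
  the boundary-exclusion rule is exercised; additive white Gaussian pixel
  noise (sd 0.03); small per-view width/intensity jitter standing in for
  the 45-degree rotations, which cannot be rendered without 3D volumes.

What it does **not** emulate: real CT noise correlation (reconstruction
kernels produce spatially correlated noise; the generator's noise is
white), anatomical variability of real vessels, calcium blooming,
motion artifacts, and eccentric lesions whose apparent severity varies
across rotational views. Consequences for interpretation: passing tests
demonstrate that the pipeline's machinery is correct and that the cascade
recovers a class structure that is genuinely encoded in the images; they
do not certify real-data accuracy. One concrete instance: because white
pixel noise is unlearnable, the SSIM between a reconstruction and a noisy
target is capped near 0.72 at the default noise level (the noise variance
is comparable to SSIM's C2 constant), so the reconstruction-quality test
uses a low-noise fixture (noise sd 0.01), where the scaled autoencoder
reaches mean SSIM 0.90 on held-out patients — the level the full-scale
system reports on real images.

## Scaled-down study conditions

Desk-scale experiments (the test suite and the worked examples) use a
downscaled geometry chosen once: 107 x 41 crops (one eighth of the 854-row
height), a scaled AE64 analogue (4387-256-128-64, the same halving
progression from a proportionally smaller first width), 50 training
epochs, and a 60-patient cohort (~1,300 images) split 85/15 by patient
with label stratification. The autoencoder trains on a 400-image subsample
of the training partition. Under these conditions the combined
radiomic + latent model reaches held-out patient balanced accuracy >= 0.85
and is non-inferior (within 0.05) to the better single domain over five
cascade seeds, mirroring the qualitative full-scale finding that the
combined model outperforms either domain alone; label-permuted training
collapses to chance (balanced accuracy ~ 1/3), confirming the evaluation
is leak-free.

## Numerical and procedural conventions

* **Correlation filter order**: redundant pairs are processed in
  descending |rho| with lexicographic tie-breaks; the member with the
  higher mean absolute Spearman correlation to all original features is
  dropped (ties: the later name). The drop rule alone does not fix an
  ordering; this one makes the filter deterministic.
* **Rank-sum filter**: exact enumeration when both groups have <= 20
  samples and no ties; otherwise the normal approximation with tie and
  continuity correction. Alpha 0.05, uncorrected, both configurable;
  uncorrected per-feature screening is common radiomics practice when the
  screen feeds a subsequent multivariate selector.
* **LASSO**: logistic (the sub-tasks are binary classifications), penalty
  by seeded 5-fold cross-validation at one standard error, falling back to
  the minimum-deviance penalty and then to the top univariate feature if
  shrinkage empties the model.
* **SMOTE after selection**: the stage order follows the listing order of
  the processing steps (scaling, selection, balancing); balancing in the
  selected low-dimensional space also avoids interpolating hundreds of
  irrelevant coordinates.
* **Voting semantics**: per-stage patient majority, as the worked patient
  examples depict (a stage-A majority of healthy image votes stops the
  cascade); exact ties go to the more severe class at both stages — a
  clinically conservative convention.
* **Patient-level AUC**: the cascade emits no native 3-class probability,
  so one-vs-rest AUC uses chained pseudo-probabilities: P(noCAD) = 1 - pA,
  P(nonobstructive) = pA (1 - pB), P(obstructive) = pA pB, with pA and pB
  the patient means of the stage forests' class probabilities.
* **Clinical association**: latent features are aggregated per patient by
  the mean over images (median available), tested against binary
  covariates by two-sided Mann-Whitney and against age by Spearman
  correlation, uncorrected by default with an adjustable correction flag.
* **Seeding**: every stochastic stage derives its own 32-bit seed
  deterministically from the global seed and a stage tag, so any stage can
  be reproduced in isolation and the end-to-end run is bit-reproducible.

## Known limitations

The generator's realism bounds what desk-scale results can claim; the
autoencoder is a fully connected architecture by design (no convolutional
inductive bias), so its latent space is sensitive to global intensity
structure; stage B never sees stage-A mistakes during training (true-label
cascade training, the standard choice); and
the three-class output deliberately stops short of the six CAD-RADS
grades.
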