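---
title: "Quantifying crypt architecture in CLE images: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying crypt architecture in CLE images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cryptocad)
```

## The problem

Confocal laser endomicroscopy (CLE) images the colonic mucosa en face at
roughly 1000x magnification during endoscopy, producing grey-scale
micrographs in which the glandular crypts of healthy tissue appear as dark,
round, quasi-regularly spaced structures. Malignant transformation destroys
this order: crypts elongate, fuse and fragment until the tissue reads as an
amorphous texture. `cryptocad` quantifies that difference with seven
per-image parameters and classifies images with a small feed-forward
network. This vignette records the models behind each stage, the tunable
parameters and their defaults, the numerical conventions, and the limits of
what the package's phantom-based validation can show.

## Per-image parameters

### Binarization

Most of the pipeline operates on a binary pattern. The default is a global
Otsu threshold: the cut over a 256-bin histogram (spanning the image's own
intensity range) that maximizes the between-class variance, with the mask
taken as *intensity > threshold*. A fixed threshold (`"fixed:<t>"`) is
available for calibrated imagery. Constant images are rejected everywhere
rather than silently producing degenerate statistics: a constant CLE frame
is an acquisition failure, not a datum.

By default one Otsu pass on the smoothed image feeds both the fractal
estimators and the contour module (`pipeline$share_binarization = TRUE`);
this avoids a second pass that, in practice, lands within a bin of the
first. Setting it to `FALSE` re-binarizes the raw image for the fractal
stage using `fractal$binarization`.

### Fractal dimension

The box-counting dimension is the least-squares slope of log *N(s)* against
log(1/*s*), with *N(s)* the number of *s* x *s* boxes (anchored at the
top-left corner, partial edge boxes included) containing at least one
foreground pixel. Defaults use dyadic scales {2, 4, ..., side/4}; at least
three scales are required for a meaningful fit, and the fit's R^2 is
reported alongside the slope. Including partial edge boxes avoids
discarding up to *s* - 1 pixel margins; the brute-force oracle in the test
suite counts boxes the same way, so the two agree exactly. The slope is
clipped into [0, 2], the admissible range for planar patterns; with the
dyadic defaults the unclipped slope already lies in that range because a
box of side 2*s* contains at most four boxes of side *s*.

### Lacunarity

For each window size *r*, an *r* x *r* box glides over all
(H - r + 1)(W - r + 1) positions; with *M1* and *M2* the first two moments
of the box-mass distribution, Lambda(r) = M2/M1^2 >= 1. The reported
scalar is the mean of Lambda(r) - 1 over *r* in {2, 4, 8, 16}, so any
translation-invariant mass — a full mask, or a window covering the whole
image — scores exactly 0. The "- 1" convention keeps the statistic on the
same near-zero scale on which crypt-architecture lacunarity values are
conventionally reported; box masses are computed with a summed-area table,
which is exact integer arithmetic on masks of this size.

### GLCM texture statistics

Intensities are quantized into `glcm$levels` equal-width bins spanning the
image's own [min, max] (8 levels by default; per-image scaling makes the
statistics invariant to exposure), and ordered pixel pairs at offset
`glcm$offset` (default (0, 1), one step to the right) are tabulated into
the co-occurrence matrix *P*. Contrast, correlation, energy and homogeneity
follow the classical Haralick-style definitions on grey-level indices
0..L-1. The defaults — 8 levels, single offset, no symmetrization — mirror
the long-standing defaults of the standard toolbox implementation of the
grey-level co-occurrence matrix, and a single offset matches the
convention of reporting one scalar per statistic per image. Correlation is
undefined when a marginal variance vanishes (constant image upstream);
this raises an error rather than emitting a sentinel.

### Round-crypt counting

The contour stage runs, in order: isotropic Gaussian smoothing,
thresholding, marching-squares isocontour extraction, and
roundness scoring.

* **Smoothing.** `features$sigma` is expressed at a 1024 px reference side
  (default 2 px) and scaled proportionally to the analyzed image's side, so
  the same setting denoises comparably across resolutions. Kernel weights
  are bin-integrated Gaussians truncated at 5 sigma, and boundaries are
  handled by symmetric reflection; this conserves total intensity exactly
  and reproduces the error-function step response to better than 1e-6.
* **Marching squares.** Each 2 x 2 pixel cell is classified by which
  corners exceed the iso-level; crossing points are placed on cell edges by
  linear interpolation; directed segments (foreground kept on the left)
  are chained into polylines. Saddle cells are disambiguated by comparing
  the cell mean to the level, and grid values exactly equal to the level
  are nudged up by a relative 1e-10 — both deterministic tie-breaks that
  keep chains closed. Contours that run into the image frame stay open and
  are flagged `touches_border`; closed contours are normalized to
  counter-clockwise orientation. By default contouring runs on the binary
  mask at level 0.5 (matching the stated order smooth -> threshold ->
  contour); `features$contour_on = "smoothed"` contours the smoothed
  grayscale at the threshold intensity instead.
* **Roundness.** Each closed, non-border contour is scored by
  area/perimeter (shoelace area; perimeter includes the closing edge). For
  a disk of radius *r* the ratio is *r*/2, so it acts as an effective
  radius in pixels; elongated or fragmented shapes score low. Features
  with ratio above `features$ratio_threshold` (default 4, i.e. crypts of
  effective radius >= 8 px at 1024 px) are counted. Border-touching
  contours are excluded because their truncated geometry is meaningless.
  The ratio is resolution-dependent by construction, so the threshold is
  documented at the 1024 px scale and, with
  `features$rescale_threshold = TRUE` (default), rescaled by side/1024.

The area/perimeter ratio rather than a dimensionless isoperimetric
quotient (4 pi A / P^2) is a deliberate choice: it is the field's stated
roundness score for this application, and its pixel units are what make
the "effective radius" threshold interpretable. The consequence — a large
blob passes the threshold even if moderately elongated — is real and is
discussed under limitations.

## The classifier

`cad_mlp()` fits a feed-forward network with one hidden layer of 100
logistic-sigmoid units and a two-unit softmax output. Choices that matter:

* **Loss.** Mean natural-log cross-entropy per sample over the two one-hot
  outputs. Published cross-entropy figures for comparable pipelines do not
  always state their convention (per-sample vs summed); ours is documented
  so numbers are comparable.
* **Standardization.** Inputs are centred and scaled using the mean and
  standard deviation of the *training split only*. Permuting
  validation/test rows provably cannot change the fit; the test suite
  checks this.
* **Optimizer.** Full-batch iRprop- (resilient backpropagation with sign
  changes zeroed): deterministic, step sizes adapt per weight
  (eta+ = 1.2, eta- = 0.5, steps clipped to [1e-12, 1]), and it needs no
  learning-rate tuning on standardized inputs. Weights initialize uniform
  in +/- sqrt(6/(fan_in + fan_out)) under the given seed.
* **Early stopping.** After each epoch the validation loss is evaluated;
  training stops once it has failed to improve for `patience = 6`
  consecutive epochs (cap 1000), and the weights from the best validation
  epoch are returned. The evaluation report is computed at those weights.
* **Splitting.** `split_dataset()` sizes the train/validation/test parts
  by largest-remainder rounding of n x (0.70, 0.15, 0.15) — for n = 1035
  this gives exactly 725/155/155 — with remainder ties going to the
  earlier-listed split. Assignment is a seeded shuffle, unstratified:
  images are treated as exchangeable. When several images come from the
  same patient this ignores within-patient correlation, which inflates
  apparent test performance on clinical data; phantom images are genuinely
  independent, so the caveat applies to clinical use only.
* **Class imbalance.** The loss is unweighted: with a 679/356 imbalance
  the majority class dominates the gradient slightly, which matches the
  plain pattern-recognition treatment this pipeline follows.
* **Ties.** Exact softmax ties are called *cancer* — the conservative
  direction for a diagnostic screen — and documented in
  `predict.cad_mlp()`.

## The phantom generator

The generator exists so every stage can be tested against known ground
truth; it is a stylized geometric stand-in, not a biophysical simulation.

**Normal phantoms** place dark, near-circular crypts (radius ~ N(14, 2^2)
px, clipped at 3; slight random eccentricity up to ~1.18) on a hexagonal
lattice of spacing side/4 with +/- 6 px jitter, over a brighter stroma
(plateaus 0.30/0.65). Placements overlapping an existing crypt by more
than 20% of the smaller crypt's area (exact lens-area computation) are
resampled. At the default 512 px side this yields about 20 crypts — the
low-tens count typical of a healthy 1024 px CLE field reported at half
resolution. Speckle noise (sd 0.05) and a mild linear illumination
gradient (0.08 across the field) are the modeled nuisances. With both set
to zero the image has exactly two intensity plateaus, which several exact
tests rely on.

**Tumor phantoms** threshold a warped anisotropic Gaussian random field
(correlation lengths 64 x 3 px, random orientation, displacement field of
amplitude 12 px smoothed at 64 px) at its 45% quantile into elongated dark
ridges, soften the edges with a 2 px Gaussian, and add weaker speckle
(sd 0.025). Two of these numbers deserve comment:

* The *ridge correlation length* (64 px) keeps ridges comparable to the
  field of view. Shorter ridges fragment into isolated blobs that read as
  spurious "round" features; at 64 px nearly all dark structure stays
  border-connected and the round-feature count lands near 1-3 per image,
  the near-zero regime expected of disorganized mucosa.
* The *edge softening* (2 px) models the blurred, thickened epithelial
  borders of malignant tissue. It also matters numerically: with a single
  GLCM offset of (0, 1), hard ridge edges contribute to contrast only when
  ridges run across the offset direction, making contrast strongly
  orientation-dependent between seeds. Softening the edges leaves speckle
  as the dominant contrast source, so the tumor contrast distribution is
  stable and sits below the normal one — the class signature the seven
  parameters are meant to carry.

With these defaults the phantom classes separate the way clinical groups
do on the discriminative parameters: normal phantoms have many round
features and higher contrast; tumor phantoms have almost none and lower
contrast (and, incidentally, higher homogeneity). The absolute values of
the other parameters do not track clinical magnitudes — the phantoms'
fractal dimension is higher and their lacunarity contrast between classes
larger than in real tissue — and no test asserts that they should.

**What phantom validation shows, and what it does not.** Passing the
phantom benchmark establishes that the geometry pipeline measures what it
claims (verified against closed forms and brute-force oracles), that the
classifier learns a genuinely separable representation without leakage,
and that the whole chain is deterministic and reproducible. It does not
establish clinical performance: real CLE images carry fluorescein
kinetics, vascular patterns, motion and pressure artifacts, and
within-patient correlation, none of which the phantoms model. Phantom
error rates near zero should be read as "the pipeline is not the
bottleneck", not as a clinical accuracy claim.

## Numerical conventions and degenerate inputs

* Images are unit-interval float matrices regardless of source bit depth
  (8/16-bit PNG/TIFF); multi-channel files are rejected unless ITU-R 601
  luminance conversion is requested explicitly.
* Coordinates: origin at the top-left pixel center, x = column - 1,
  y = row - 1; contour vertices are sub-pixel points in this frame.
* Feature tables are CSV with a fixed column order and 12 significant
  digits — enough to round-trip doubles at the precision any downstream
  statistic uses. Model files are JSON with plain nested arrays.
* Zero-variance groups in `compare_groups()` follow the documented
  convention: equal means give p = 1, unequal means p = 0 (with a
  message). No multiple-testing correction is applied; each parameter is
  tested at its own alpha, matching the per-parameter reporting style of
  the application area.
* Empty masks, constant images, undersized grids and single-class training
  splits all raise informative errors rather than propagating NaNs.

## Problem sizes used in validation

The test suite exercises the geometry oracles at 16-64 px, phantoms at
128-512 px, and one full surrogate benchmark: 356 normal + 679 cancer
phantoms at 512 px, split 725/155/155, trained with 100 hidden units —
the published clinical study geometry at half resolution, which keeps the
complete run in the minutes range on a single core. `scripts/acceptance.R`
repeats that benchmark from scratch under any seed.

## Known limitations

* The area/perimeter roundness score is scale-dependent and admits large
  non-round blobs; an isoperimetric variant would be scale-free but would
  no longer reproduce the established pipeline.
* A single GLCM offset makes the texture statistics orientation-sensitive;
  rotation-averaged GLCMs are deliberately out of scope.
* The box-counting and lacunarity estimators run on a binarized pattern;
  grayscale (differential) box counting is not implemented.
* The classifier is a fixed two-layer architecture; it is the decision
  module of this pipeline, not a general-purpose learner.
* Phantoms do not model vasculature, goblet-cell morphology beyond
  speckle, fluorescein leakage, or motion artifacts.
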