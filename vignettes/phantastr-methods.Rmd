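---
title: "Methods: PCM segmentation, halo correction and culture quantification"
author: "phantastr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: PCM segmentation, halo correction and culture quantification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phantastr)
```

## The problem

Phase contrast microscopy (PCM) is the workhorse imaging mode for adherent
cell culture because it needs no labels, but its images are hard to segment
automatically: cell interiors have nearly the same mean intensity as the
cell-free background, and every cell is surrounded by a bright optical
artifact — the halo — typically 10 to 30 pixels wide at 10x magnification.
Any segmentation that simply finds "bright" or "textured" pixels includes
the halo, inflating area measurements and destroying object outlines.

phantastr implements a two-stage pipeline: (1) local-contrast thresholding
to find textured (cell-containing) regions, and (2) an iterative correction
that removes the halo flank by tracking intensity gradients.  On top of the
resulting masks it computes confluency with precision statistics,
morphometrics, a packing-corrected confluency (PCC) for cell density
estimation, and augmented fluorescence images (AFIs).

## Local contrast segmentation

Local contrast is defined as the standard deviation of the intensity within
a soft Gaussian window divided by the mean within the same window:

$$C = \frac{\sqrt{(I^2 * w) - (I * w)^2}}{I * w}$$

with $w$ a unit-sum Gaussian kernel of scale $\sigma$ and $*$ denoting
convolution.  Dividing by the windowed mean makes $C$ invariant to
multiplicative illumination changes, which is why uneven lamp settings and
menisci shading do not wreck the segmentation.  A single global threshold
$\varepsilon$ applied to $C$ yields the binary image $G$; holes smaller
than $F_{max}$ are filled and objects smaller than $R_{max}$ removed.

Numerical choices:

* the Gaussian window is truncated at $4\sigma$ and renormalized; borders
  are handled by replicate padding so that dark frames are not
  hallucinated at the image edge;
* windowed variance is clamped at zero before the square root
  (floating-point residuals can be slightly negative);
* where the windowed mean falls below $10^{-6}$ the contrast is defined as
  0 — such pixels are effectively unilluminated and are classified
  background;
* foreground objects use 8-connectivity and background holes
  4-connectivity, the standard complementary pair;
* hole filling never fills background regions touching the image border,
  since their full extent is unknown.

Defaults (`segParams()`): $\sigma = 1.2$ px (about the width of a cell
edge at 10x), $\varepsilon = 0.03$ (above the local contrast of a clean
background, below that of speckled cytoplasm), $F_{max} = R_{max} = 200$
px (well below one cell footprint at 10x), halo correction on with
$A_{ratio} = 0.5$.  All of these interact with magnification and camera
noise, and are meant to be tuned per setup with `gridSearchParams()`,
which scores candidate parameter sets by the segmentation error
$\Delta_s = 1 - \mathrm{MCC}$ under leave-one-out cross validation
(selection on the training images, scoring on the held-out image; ties
broken by lexicographic parameter order).

## Halo correction

The thresholded mask includes the halo because the halo's flank is itself
a high-contrast structure.  The correction exploits the one property that
separates halo from cell: moving inward across the halo, intensity rises
to the halo crest and then falls abruptly at the cell edge — a reversal of
the gradient direction.

A direction map is computed once per image with the eight 3x3 Kirsch
kernels (N, NE, ..., NW; the north kernel carries its +5 coefficients on
the top row, so the argmax direction points toward increasing intensity;
ties go to the smallest index).  A FIFO queue is seeded with boundary cell
pixels (cell pixels with a background 4-neighbour; the image border counts
as background).  For each dequeued pixel the three pixels reached by
stepping one pixel along its gradient direction and the two adjacent
(±45°) directions are inspected:

* if at least one of the three is currently a cell pixel, the current
  pixel is halo flank: it is relabelled background and those of the three
  that are cell pixels are enqueued;
* otherwise the gradient points out of the mask — the current pixel is at
  the interface and is confirmed as cell.

Each pixel is decided at most once (a confirmed pixel is never
re-enqueued, a removed pixel is final), which bounds the iteration count
by the mask size and yields breadth-first, layer-by-layer peeling of the
flank.  Steps leaving the image are treated as background; diagonal steps
move one pixel in each axis.  Per connected component of the input mask
the removed area is tracked and removal stops as soon as it would exceed
$A_{ratio}$ times the original component area; remaining queued pixels of
a capped component are confirmed.  The output is therefore always a
subset of the input and every component keeps at least a $1 - A_{ratio}$
fraction of its area.

$A_{ratio}$ is a safety budget, not a tuning knob for accuracy: it should
exceed the expected halo share of a thresholded object, which for a cell
of radius $r$ with halo width $h$ is about $1 - r^2/(r+h)^2$ (up to ~0.8
for small colonies with wide halos).  If it is set below that share the
correction stops early and leaves flank remnants; the conservative package
default of 0.5 protects irregular objects at the cost of residual halo on
small round ones.

## Confluency and its precision

Image confluency is the fraction of pixels labelled cell; culture
confluency averages at least 20 images taken at random locations
(`cultureConfluency()` warns below 20).  Given estimates $\hat x_i$ and
ground truths $x_i$, `estimationPrecision()` decomposes the error into

$$\mathrm{RMSE}^2 = \mathrm{bias}^2 + \mathrm{precision}^2,$$

with bias the mean signed difference.  Survey data (images x raters) are
summarized by `surveyStats()`: the combined variability is the pooled
standard deviation of estimates about per-image means; the intra-rater
component comes from repeat pairs, $v_{intra} = \sqrt{\sum (r_1 -
r_2)^2 / 2n}$ (the standard repeatability estimator); the inter-rater
component follows by subtraction in quadrature, clamped at zero.
Independent error components combine in quadrature
(`combinePrecision()`).

## Morphometry

Objects are 8-connected components; objects touching the image border are
excluded from morphometry (their shape is truncated) but still count
toward confluency.  Per object:

* **perimeter** — length of the 8-connected boundary chain obtained by
  Moore-neighbour tracing, weighting axial steps 1 and diagonal steps
  $\sqrt 2$.  This estimator is simple and deterministic but biased:
  it overestimates smooth contours by ~5% (so rasterized disks score a
  form factor slightly below 1) and underestimates the perimeter of
  objects only a few pixels across (an isolated pixel is assigned
  perimeter 1 by convention).  Form-factor values are comparable only
  within one estimator, which is why the estimator is fixed and
  documented rather than configurable.
* **form factor** — $4\pi A / P^2$: 1 for an ideal circle, lower for
  irregular outlines.
* **solidity** — $A / A_{hull}$, where the convex hull is taken over the
  four corner points of every object pixel (pixels treated as unit
  squares) and $A_{hull}$ is the polygon area.  This convention makes
  filled rectangles score exactly 1 and guarantees solidity $\le 1$; a
  hull over pixel centers was considered and rejected because it assigns
  solidity 1 to plainly non-convex thin shapes (e.g. a plus sign of five
  pixels).

## Packing-corrected confluency and cell density

For colony-forming cells, confluency is a poor predictor of cell density
because area per cell changes several-fold during a culture.  PCC divides
confluency by the mean spacing of nucleus-like texture features:

1. basic image features (BIF) classify every pixel into
   flat / slope / bright blob / dark blob / bright line / dark line /
   saddle from scale-normalized Gaussian-derivative responses
   $s_{ij} = \sigma^{i+j} (\partial^{i+j} G_\sigma * I)$, using class
   scores $\{\varepsilon s_{00},\; 2\sqrt{s_{10}^2 + s_{01}^2},\;
   \pm\lambda,\; (\gamma \pm \lambda)/\sqrt 2,\; \gamma\}$ with
   $\lambda = s_{20} + s_{02}$,
   $\gamma = \sqrt{(s_{20} - s_{02})^2 + 4 s_{11}^2}$.  Defaults
   $\sigma = 4$, $\varepsilon = 0$; at $\varepsilon = 0$ the flat class
   can never win (its score is 0 and flat requires a strictly dominant
   score), so no pixel is flat even on constant images;
2. bright-blob components are reduced to centroids (rounded to the
   nearest pixel) and centroids outside the segmentation mask are
   discarded;
3. the mean of the exact Euclidean distance transform of the centroid
   image — averaged over **all** pixels, not only cell pixels — is the
   spacing term; PCC = confluency / spacing (units 1/px; the calibration
   absorbs units).

Density estimation fits `density = slope * PCC + intercept` by ordinary
least squares (`calibrateDensity()`), reporting the adjusted $r^2$ and
the NRMSE (RMSE over the observed density range; the range is the only
normalizer that is well-defined without distributional assumptions).

A caveat the phantom studies make explicit: with **constant** cell size
the PCC grows faster than linearly in cell count (confluency is linear
but the spacing term shrinks roughly as $n^{-1/2}$), so PCC/count is not
constant.  The strong linearity observed with real colony-forming cells
arises because area per cell falls as cultures pack.  On phantom series
the linear fit remains excellent (adjusted $r^2 \approx 0.97$) and the
rotating calibration generalizes (NRMSE well under 15%), which is the
operationally relevant property; exact proportionality is not claimed.

## Augmented fluorescence images

`makeAFI()` gates a same-field fluorescence image with the PCM mask:
background where the mask is false; among cell pixels, negative at or
below `tLow`, low expression in `(tLow, tHigh]`, high above `tHigh`.
Thresholds live in normalized [0, 1] units so they are independent of
acquisition bit depth (defaults 0.094 and 0.24, i.e. about 24/255 and
60/255 on 8-bit data; boundary values are assigned to the lower class,
a convention fixed here since either choice is defensible).
`afiSummaries()` reports the fraction of expressing cell pixels and the
mean cell-pixel fluorescence; with no cell pixels these are flagged
undefined rather than raising an error, since empty fields are a normal
occurrence early in a culture.

## The phantom generator

`generatePhantom()` builds PCM-like images with pixel-exact ground truth
so that every stage is testable without external data.  Cells are disks
perturbed by radial harmonics of orders 2-4 (amplitudes up to 10%, giving
mildly non-convex outlines for solidity tests), placed uniformly at
random without overlap (halo band included; an unplaceable spec raises an
error rather than silently packing fewer cells).  The image is assembled
as: background at 0.45 ± 0.01 noise; interiors speckled at SD 0.10 around
the background mean (low mean contrast, high local variance — the
property local contrast detection relies on); a bright halo band around
each cell with a half-cosine profile peaking at the cell edge (gain 0.35)
and decaying to background at the outer rim, so a genuine gradient
reversal exists at the halo/cell interface; a Gaussian nucleus-like bump
at each center (the bright-blob feature PCC uses); optional linear
shading and a defocus blur (default 0.8 px).  The truth mask contains
the cell shapes only — the halo is background.  All randomness flows
from the spec's seed and the global RNG state is restored, so identical
specs give bit-identical bundles.

The halo gain is set so that the band's local contrast exceeds the
default threshold across the full 10-30 px width range: the premise of
the correction step is that thresholding captures the entire halo, and a
phantom whose halo were invisible to the first stage would not exercise
the second.

What the phantoms do *not* emulate: real PCM optics (no Zernike phase
model), cell-to-cell texture variation, touching or overlapping cells,
debris, and condensation artifacts.  Passing phantom suites therefore
demonstrates correctness of the algorithms under controlled conditions,
not performance on any particular microscope.

## Validation studies and problem sizes

The test suite and `scripts/acceptance.R` run three studies, sized to
keep a full run within a few minutes on one CPU:

* **segmentation suite** — 20 phantoms of 512 x 512 px, 5 cells each with
  radius 25-45 px (colony scale at 10x) and halo widths spanning
  10-30 px.  Suite parameters: defaults except $F_{max} = 2500$ px and
  $A_{ratio} = 0.85$.  $F_{max}$ must fill the enclosed ring of
  sub-threshold pixels at the halo crest (where the gradient vanishes, so
  local contrast dips); 2500 px is above those gap rings and below the
  smallest cell footprint.  $A_{ratio} = 0.85$ exceeds the geometric halo
  share of these objects (~0.8 worst case).  Typical outcome: mean
  F-score ≈ 0.95, mean precision ≈ 0.92 with correction vs ≈ 0.46
  without, mean boundary displacement ≈ 1.7 px.
* **density series** — 12 phantoms of 720 x 960 px with planted counts
  10-400.  Cells are small (radius 4-7 px, halo 6-9 px), emulating a
  dense culture of individual cells; 400 cells with 10-30 px halos
  cannot physically be placed without overlap on a realistic field.
  Segmentation uses $F_{max} = R_{max} = 30$ px (below these small cell
  footprints) and $A_{ratio} = 0.85$.  Typical outcome: adjusted
  $r^2 \approx 0.97$, rotating-calibration NRMSE ≈ 6%.
* **analytic statistics** — survey variability components and the overall
  confluency precision recomputed from their printed inputs through
  `surveyStats()` and `combinePrecision()`.

## Known limitations

* No instance segmentation: touching cells form one object, so
  morphometry describes colonies, not single cells, at high confluency.
* The chain-code perimeter bias makes form factors comparable only within
  this package.
* Halo correction assumes the halo is included in the thresholded mask
  and that a gradient reversal exists at the cell edge; heavily defocused
  images weaken both premises.
* PCC requires a per-setup calibration; a calibration does not transfer
  across cell lines or imaging conditions.
* Processing is single-threaded, pure R; a 1280 x 960 image takes a few
  seconds end to end rather than the sub-second times of optimized
  native implementations.
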