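---
title: "Five pathways to breast density: models, parameters and validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Five pathways to breast density: models, parameters and validation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(breastdens)
```

## The measurement problem

Mammographic breast density — the fraction of the breast occupied by
fibroglandular rather than adipose tissue — is one of the stronger image-based
markers of breast cancer risk. It can be measured several ways, and the ways
do not trivially agree: 2D mammography sees a compressed projection,
3D MRI sees the uncompressed volume, and header-based estimates see only the
exposure physics. `breastdens` implements five measurement pathways in one
toolkit, each producing the same four outcomes — percent glandular tissue
(%-G), glandular volume (GV), fat volume (FV) and total volume (TV, all in
mL) — plus the agreement statistics needed to compare pathways on the same
subjects.

The five pathways:

* **HSM** (histogram segmentation): threshold the intensity histogram of the
  breast region of a raw digital mammogram; glandular area is the bright
  class. Volumes follow from areas, the compression thickness, and a unit
  correction factor:
  $$\%\text{-G} = \frac{G_{AREA}}{G_{AREA}+F_{AREA}}, \qquad
    GV = c \cdot G_{AREA} \cdot t, \quad FV = c \cdot F_{AREA} \cdot t,
    \quad TV = GV + FV,$$
  with $t$ the pre-exposure compression thickness and $c$ the
  pixel-area-to-mL factor (default 9.96; see below).
* **MATH**: a fixed linear model mapping eleven acquisition-control variables
  recorded in the mammogram's DICOM header (doses, thicknesses, kVp, mean
  signal, a header threshold, compression force, detector sensitivity, and
  the filter and anode materials coded molybdenum = 1 / rhodium = 0) directly
  to %-G. The intercept is 481.33; the coefficients ship as versioned
  configuration because the fit is hardware-specific.
* **FFDM**: the mammography unit's own header estimate of percent density
  ("Raddose"), passed through unchanged.
* **3DGRE / STIR MRI**: the voxel-intensity histogram of a masked 3D breast
  model is decomposed into two Gaussians — the two-compartment assumption
  that breast tissue is adipose plus fibroglandular and nothing else. The
  gland fraction is the gland component's share of the analytic area
  $A\sigma\sqrt{2\pi}$; total volume is the masked voxel count times the
  voxel volume (voxel ratio × reconstructed voxel size³, mm³).

MATH and FFDM predict only the *percent*; their volumes come from
$GV = TV\cdot\%\text{-G}/100$, $FV = TV - GV$ with TV supplied explicitly
(typically the HSM total). Making the TV source an explicit argument, rather
than an implicit default, keeps that dependence visible.

## Tunable parameters that matter

| Parameter | Default | Units | Why this default |
|---|---|---|---|
| `pixel_to_ml_factor` | 9.96 | mL per (pixel-area × thickness-unit) | An opaque composite constant valid for one imaging geometry; it absorbs pixel pitch and any residual unit conversion. It must be recalibrated per imager, which is why it is an argument everywhere it appears. |
| threshold `strategy` | `"otsu"` | — | The interactive analyst-chosen threshold of clinical practice (~30 min per image) is not reproducible in software; Otsu's between-class-variance maximiser is the standard programmatic stand-in. `fixed:<value>` supports calibrated workflows. |
| `glandular_bright` | `TRUE` | — | On raw (for-processing) mammograms dense tissue attenuates more and reads brighter. Presentation-intent images can invert this; the flag accommodates them without touching the pipeline. |
| `chest_margin`, `chest_side` | 0, `"none"` | px | Chest-wall exclusion is scanner- and positioning-dependent; there is no principled default beyond "off". |
| `n_bins` | 256 | bins | Native integer bins are used for integer images; 256 uniform bins otherwise — fine enough to resolve two peaks separated by a few within-class SDs, coarse enough that bins are well populated at typical breast-mask sizes (10⁴–10⁶ voxels). |
| fit `init` | `"auto"` | — | Means at the histogram-weighted 25th/75th percentiles, widths range/8, amplitudes from local histogram height. These land inside each peak's basin for any two-peaked histogram with roughly balanced mass. |
| `max_restarts` | 5 | — | Jittered (seeded, deterministic) restarts after a failed convergence; failures after that are reported honestly via `converged = FALSE`, never silently. |
| `clamp` (MATH) | `TRUE` | — | A linear score is unbounded; out-of-range values are truncated to [0, 100] with a warning. Downstream volume decomposition refuses out-of-range percents instead of clamping, so truncation can only happen — visibly — at the estimate. |

Thicknesses are millimetres throughout; a metadata sidecar declaring
centimetres is converted on read and the conversion is flagged. Whether the
9.96 factor "expects" mm or cm is unknowable from its definition — it is
treated as an opaque composite with the unit convention documented at the
argument, which is also why HSM volumes on synthetic phantoms are on an
arbitrary scale unless the factor is calibrated to the phantom's geometry.

## Numerical choices

* **Otsu on a level→count map.** The implementation maximises
  $\omega_0\omega_1(\mu_0-\mu_1)^2$ by cumulative moments over all cut points
  of the observed levels; ties break toward the lowest cut; the returned
  threshold is the midpoint between the two levels flanking the winning cut,
  so it is strictly interior and classification at it is unambiguous. The
  test suite checks it against an independent exhaustive variance scan on
  every histogram it generates.
* **Tie-break at the threshold.** Pixels exactly equal to the threshold are
  glandular (a closed lower bound on the gland class), in both polarities.
* **Mixture fit.** Bounded Levenberg–Marquardt least squares on the binned
  histogram — curve fitting, as peak-fitting software does — rather than
  per-voxel EM: it is faithful to how such histograms are analysed in
  practice and is deterministic on fixed bins. No baseline term is included;
  the two-compartment assumption says there is nothing else, and any residual
  shows up in `rss`. Components are reported sorted by mean; which one is
  gland is a separate, protocol-driven step (fat is bright without fat
  suppression, dark under STIR), overridable with a warning.
* **Degenerate inputs.** Single-level histograms refuse thresholding; fewer
  than six occupied bins refuse a six-parameter fit; a near-single-Gaussian
  histogram yields either a flagged non-convergence or a fit whose minor
  component area is near zero, with a degradation warning below 1% area
  share. Zero-variance paired differences give a point confidence interval at
  the observed difference. Correlation cells with fewer than three complete
  pairs are `NA`, never extrapolated.
* **Agreement statistics.** Pairwise contrasts are paired-t on per-subject
  differences with Benjamini–Hochberg FDR across the pair family. A Tukey
  HSD construction was considered and rejected: the design is repeated
  measures (every method on every subject), paired contrasts use that
  structure, and FDR control across the family is applied either way.

## What the synthetic generators emulate — and what they do not

The generators reproduce the *statistical* structure the pathways assume:
a breast ROI (ellipse/ellipsoid) on empty background containing exactly two
intensity compartments with Gaussian within-class spread; acquisition
metadata whose header-model predictions land in the valid percent range
(as they do on the real hardware the model was fitted to, which is how the
plausible ranges were chosen); and multi-method measure tables built from an
equicorrelated latent subject effect with method-level offsets — the
structure of a method-comparison study.

Class assignment within the ROI is exact-count rather than Bernoulli, so the
planted fraction is exact at pixel resolution and recovery tests are sharp.
All generation is a pure function of (spec, seed), run on a private RNG
stream that leaves the caller's `.Random.seed` untouched.

Deliberately **not** emulated: anatomic texture and parenchymal pattern,
projection and scatter physics, breast-edge thickness falloff, pectoral
muscle, Rician MRI noise and coil inhomogeneity, analyst variability in
threshold choice, and partial-volume voxels. Passing the recovery tests
therefore demonstrates that the algorithms are correct on data satisfying
their own assumptions — two separable compartments, clean masks — not that
they are robust to real clinical images. On real data the binding constraints
are mask quality and compartment separation, both of which degrade the
two-class picture gracefully: mixture recovery is excellent at ≥ 3σ peak
separation and degrades below ~2σ, where the two-Gaussian decomposition
becomes ill-posed regardless of optimizer.

## Problem sizes used in validation

The shipped tests and the acceptance script use phantom sizes chosen to make
the statistics meaningful while keeping the full suite quick to run on a
laptop: 110×110 mammogram phantoms (≈ 6.7k-pixel ROI) across 100 planted
fractions from 0.05 to 0.95 at ≥ 6σ class separation; 32³ MRI volumes
(≈ 10k masked voxels); 50 simulated histograms of 10⁵ voxels for mixture
recovery; 200 replicates of n = 100 subjects for confidence-interval
coverage; and 300–500 subjects for correlation calibration. Every tolerance
asserted (1 percentage point for HSM recovery, 0.02 mean absolute fraction
error for the mixture fit, [0.92, 0.98] coverage at nominal 0.95) is the
level the corresponding design is expected to meet, not a fitted constant.

## Known limitations

* The HSM volume scale is only as good as the calibration of the 9.96-type
  factor; uncalibrated, %-G is trustworthy and absolute volumes are not.
* The MATH coefficients are hardware-specific and shipped as defaults, not
  truths; refitting them is out of scope by design.
* Breast-mask generation from raw MRI is out of scope; masks are inputs.
* One MRI volume is analysed at a time; averaging repeated acquisitions is
  left to the caller.
* The DICOM layer is a minimal explicit-VR little-endian reader sufficient
  for header metadata and uncompressed 16-bit pixel data; it is not a general
  DICOM implementation, and the JSON sidecar route is the primary metadata
  path for non-DICOM rasters.
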