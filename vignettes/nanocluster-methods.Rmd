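---
title: "Methods: STED nanocluster localization and distribution comparison"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: STED nanocluster localization and distribution comparison}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stednano)
```

## Scope and model

`stednano` analyzes 2D single-channel STED images of membrane-receptor
nanoclusters, one image per cell, with a condition label per cell. The
pipeline has four stages:

1. **Localization** — binarize the cell, zero the outside, band-pass with a
   difference of Gaussians (sigma 0/100 nm), clip negatives, smooth with a
   15 nm Gaussian, standardize intensities by the cell's mean + sd, and
   detect clusters as thresholded local maxima with adjacent (plateau)
   peaks merged.
2. **Per-cell statistics** — (a) local cluster density as the peak
   intensities of a 2D Gaussian kernel map (bandwidth 200 nm, unit-peak
   kernels, so intensities read as kernel-weighted cluster counts); (b)
   k-nearest-neighbor distances (k = 4, self excluded, pooled to k x n
   values per cell); (c) cluster sizes as the minimum FWHM (2 gamma) of
   Lorentzian fits `offset + A / (1 + ((x - x0)/gamma)^2)` to four 400 nm
   line profiles (0/45/90/135 degrees) whose fit reaches R^2 > 0.9.
3. **Condition comparison** — per cell, a Gaussian KDE of each statistic on
   a shared grid; per condition, the pointwise mean curve with a Student-t
   83.4% confidence band; regions where two conditions' bands do not
   overlap are flagged significant (approximately a 5% two-sided t-test
   when standard errors are comparable); crossover points maximize the
   cumulative difference of mean curves; pooled samples are additionally
   compared with one-sided two-sample Kolmogorov-Smirnov tests.
4. **Simulation** — a generator producing STED-like images with known
   ground truth, used throughout the tests and for threshold calibration.

All distances and sizes are handled in nanometers; pixels appear only
inside image operations. Pixel centers sit at `(index - 0.5) * pixel_size`
with the origin at the image corner.

## Assumptions

* Clusters are point-like or near point-like emitters; their apparent size
  (50–150 nm FWHM) reflects the STED point-spread function and true
  cluster extent jointly. We model spot profiles as 2D Lorentzians,
  consistent with the Lorentzian sizing model fitted downstream (a
  Gaussian profile is available for robustness checks).
* Cells are the single largest bright connected region per image.
* Photon noise is Poisson at the pixel level; no drift, afterpulsing, or
  3D effects are modeled.
* Cells are exchangeable within a condition; the confidence band treats
  the per-cell curves as i.i.d. samples.

## Tunable parameters

| Parameter | Default | Units | Notes |
|---|---|---|---|
| `dog_sigma1`, `dog_sigma2` | 0, 100 | nm | band-pass scales; sigma 0 = identity |
| `smooth_sigma` | 15 | nm | post-clip smoothing |
| `binarize_sigma` | 50 | nm | cell-outline smoothing (see below) |
| `peak_threshold` | — | standardized units | batch-level, required; see calibration |
| `density_bandwidth` | 200 | nm | 2D density-map kernel |
| `k` | 4 | — | neighbors per cluster |
| `profile_length` | 400 | nm | sizing line profiles |
| `r2_threshold` | 0.9 | — | Lorentzian fit acceptance |
| `ci_level` | 0.834 | — | band level; non-overlap ~ 5% t-test |
| `kde_bw` | Scott | analysis units | per-cell KDE bandwidth |

**Peak threshold.** The global threshold has no universal default: it
depends on acquisition settings and is meant to be set once per imaging
batch. `suggest_peak_threshold()` derives a value from blank (cluster-free)
calibration images rendered at the batch's photon levels: 1.25 times the
largest standardized local-maximum intensity that background noise alone
produces. On the default synthetic photon levels (300-photon spot peaks
over a 20-photon in-cell background) this lands near 3, while true spots
standardize to roughly 10–15, so detection is insensitive to the margin.

## Numerical choices

* **Boundary mode.** All Gaussian filtering uses mirror reflection,
  implemented by reflective padding before convolution. Reflection
  conserves the total intensity of the interior exactly, which the
  clip-and-smooth stage's mass-conservation contract relies on. Whether
  the original analysis renormalized at the mask boundary is unknowable
  from the text; we fix and document reflection.
* **Binarization.** The segmentation operator behind "binarization of the
  raw image" is not specified by the source method, so it is a design
  choice. Plain Otsu thresholding of a heavily smoothed copy fails when
  bright clusters stretch the intensity histogram: the threshold lands at
  the in-cell background level and the mask erodes badly. We therefore
  smooth at 50 nm (enough to suppress shot noise without rounding off the
  cell outline), take Otsu's threshold on log-compressed intensities for a
  rough mask, and refine the threshold to the midpoint of the median
  smoothed intensity inside versus outside the rough mask — i.e. the
  half-height of the cell's intensity step, which is where an edge
  blurred symmetrically should be cut. The test suite requires Jaccard
  overlap of at least 0.9 against the generating mask.
* **Peak merging.** "Adjacent" detected peaks are merged with
  8-connectivity at their intensity-weighted centroid. Equal-valued
  plateaus are the only way adjacent pixels can both be local maxima under
  a `>=` neighbor rule, so merging reduces to plateau handling. A peak
  region must additionally have at least one strictly smaller neighbor
  outside it, so constant regions produce no peaks.
* **Line-profile sampling.** Profiles are sampled by bilinear
  interpolation. The sampling step defaults to one pixel rather than half
  a pixel: interpolated midpoints systematically under-read a concave
  peak, and at half-pixel steps this inflates fitted FWHMs by up to ~14%
  for 50 nm spots at 20 nm pixels, while at one-pixel steps the
  axis-aligned profiles pass exactly through pixel centers and the
  estimator is unbiased to ~1% (the property the test suite enforces).
  The step remains configurable.
* **Lorentzian fits.** Levenberg-Marquardt (via `minpack.lm::nls.lm`)
  with starts `A = max - min`, `x0 = argmax`, `gamma = 50` nm,
  `offset = min(y)`, and `gamma` bounded to (5, 400) nm. Non-convergence
  is returned as a flagged failure, never an error. The fit includes a
  constant offset: the standardized images retain a smooth background
  pedestal, and omitting the offset folds it into the width. R^2 is
  `1 - SS_res/SS_tot`.
* **Per-cell KDE.** Exact (unbinned) Gaussian KDE with Scott's rule
  `sd(x) * n^(-1/5)` per cell by default; a fixed bandwidth can be set to
  make curves directly comparable across cells. The evaluation grid spans
  the pooled range padded by three pooled-sample bandwidths with 512
  points, clipped at zero for intrinsically non-negative quantities
  (distances, sizes, density intensities), and each curve is renormalized
  to unit mass over the grid so boundary truncation does not deflate it.
  A zero-variance sample falls back to a bandwidth of 1% of the grid span.
* **Density-map normalization.** "Number of clusters per kernel" is
  ambiguous between a scaled probability density and an unnormalized
  kernel sum; we use unit-peak kernel sums (an isolated cluster peaks at
  exactly 1, m coincident clusters at m), which makes the map directly
  interpretable and differs from the density convention only by a
  constant factor. Kernels are truncated at 4 bandwidths, identically per
  point, preserving exact additivity over unions of point sets.
* **Crossover ties.** The crossover point maximizes the absolute
  cumulative difference of mean curves; ties break toward smaller x. If
  the curves never cross, the result is flagged absent rather than
  reported.
* **KS direction.** `ks_one_sided(a, b)` tests the alternative that `a`
  is stochastically larger, via `D+ = sup(ECDF_b - ECDF_a)`; p-values are
  exact for small tie-free samples and asymptotic otherwise. The pipeline
  reports both directions for every pair.

## The 83.4% band and its limits

Two 83.4% t intervals for group means fail to overlap when
`|m_a - m_b| > t_{0.917}(se_a + se_b)`; with equal standard errors this
threshold coincides with a 5% two-sided t-test's
(`2 x 1.39 ~ 1.96 x sqrt(2)`). The test suite verifies the calibration by
simulation (non-overlap rate within 0.01 of 5% at 10,000 null
replicates, 24 cells per group). The equivalence degrades when standard
errors differ: `se_a + se_b` exceeds `sqrt(se_a^2 + se_b^2)` by less than
the critical-value ratio compensates, so the rule becomes
*anti-conservative* (measured ~8% at a threefold SE ratio). Comparisons
between conditions with very different cell-to-cell variability should
lean on the KS tests instead.

## What the simulator emulates — and what it does not

The generator draws star-convex cell outlines (low-order Fourier
perturbation of an ellipse, 20–70% frame coverage), places cluster centers
by one of four point processes (complete spatial randomness; Thomas
parent–offspring clustering; isolated pairs at an exact design spacing
with isotropic orientation, emulating ligand geometries of 13.6, 43.5 or
202.3 nm; coincident multiplets), draws per-cluster apparent FWHMs from a
truncated normal (mean 80 nm, sd 20 nm, lower bound 40 nm), renders
unit-peak-scaled Lorentzian spots sampled at pixel centers plus in-cell
and out-of-cell background, and applies Poisson noise. Default photon
levels (300 peak / 20 in-cell / 2 outside) give spots a standardized
contrast comfortably above noise; cluster intensities default to
1.2 per square micrometer for testability — the real per-cell cluster
densities are not reported by the source study, so no fidelity claim is
attached to that number.

Not emulated: vectorial PSF physics, depletion-beam shape, detector
afterpulsing, scan drift, 3D sectioning, pixel-area integration (profiles
are sampled at pixel centers, adequate at 20 nm pixels), or spatially
varying background. Passing tests therefore demonstrate correctness of
the *analysis chain* under controlled imaging physics, not robustness to
every real-microscope artifact.

The default study configuration mirrors the source experiment's design
scale: 3 conditions x 24 cells. The test suite runs it at 192 x 192
pixels per cell and the pair-recovery studies at 128 x 128, sizes chosen
so the whole suite completes in about half a minute while every contract
is still exercised at full parameter defaults.

## Known limitations

* Localization coordinates are quantized to pixel centers (no sub-pixel
  refinement); at 20 nm pixels this adds ~6 nm RMS per coordinate, which
  the 202.3 nm pair-recovery test shows averages out over images.
* The DoG + smoothing chain slightly broadens apparent sizes relative to
  the raw spots; FWHM distributions are comparable across conditions but
  are not deconvolved instrument-free sizes.
* Pairs below the resolution limit (13.6 nm) are intentionally detected
  as single clusters; the pipeline measures apparent, not molecular,
  multiplicity.
* The per-cell KDE bandwidth rule (Scott) and the 512-point grid are
  package choices; region endpoints shift by a few grid steps under other
  defensible rules, so reported significance-region boundaries carry that
  granularity.
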