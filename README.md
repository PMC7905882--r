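# stednano

Nanocluster analysis for STED super-resolution microscopy: from raw
single-channel images of membrane-receptor clusters to per-cell spatial
statistics and between-condition significance calls.

Ligand-geometry experiments (e.g. DNA-nanostructure "flat sheets"
presenting ligands at designed spacings of 13.6, 43.5 or 202.3 nm) ask
whether receptor nanoclusters change their local density, spacing or size
between stimulation conditions. `stednano` implements the image-analysis
side of that question for 2D STED data, one image per cell, at 20–25 nm
pixels, plus a synthetic-image generator with known ground truth so the
entire chain is testable without microscope data.

## What it computes

**Cluster localization.** Per image: cell binarization → background
removal (multiplication by the binary cell map) → difference-of-Gaussians
band-pass (σ₁ = 0, σ₂ = 100 nm) → negative clipping and Gaussian smoothing
(σ = 15 nm) → intensity standardization by (mean + sd) of the cell →
local-peak detection above a global batch-level threshold, with adjacent
peaks merged. Result: cluster coordinates in nm.

**Three per-cell statistics** (`density_map()` + `density_peak_intensities()`,
`knn_distances()`, `cluster_fwhm()`):

* local cluster density: peak intensities of a 2D Gaussian kernel map
  (bandwidth 200 nm, unit-peak kernels — intensities are kernel-weighted
  cluster counts);
* k-nearest-neighbor distances, k = 4 excluding self;
* cluster sizes: FWHM = 2γ from Lorentzian fits
  L(x) = offset + A / (1 + ((x − x₀)/γ)²) to four 400 nm line profiles
  (0°, 45°, 90°, 135°), keeping fits with R² > 0.9 and taking the minimum.

**Condition comparison** (`per_cell_kde()`, `mean_kde_with_ci()`,
`significance_regions()`, `crossover_point()`, `ks_one_sided()`): mean
kernel-density curve across cells with a pointwise 83.4% Student-t
confidence band per condition; regions where two bands do not overlap mark
significant differences at ≈ 5% (two-sided t-test equivalence, valid for
comparable standard errors); crossover points locate the maximum
cumulative difference between mean curves; one-sided two-sample
Kolmogorov–Smirnov tests compare pooled distributions in both directions.

**Simulation** (`make_cell_mask()`, `sample_cluster_points()`,
`render_sted_image()`, `generate_dataset()`): cell-shaped masks, CSR /
Thomas / fixed-pair / coincident point processes, Lorentzian or Gaussian
spots with per-cluster FWHM, Poisson photon noise, full ground truth.

## Worked example

Simulate a three-condition study (control = random clusters, plus isolated
pairs at 13.6 nm and 202.3 nm spacings), calibrate the batch threshold
from blank cells, and run the full pipeline:

```r
library(stednano)

spec   <- render_spec()                      # 20 nm px, Lorentzian spots
blank  <- ground_truth(matrix(numeric(0), 0, 2), numeric(0))
blanks <- lapply(1:5, function(s)
  render_sted_image(blank, spec, make_cell_mask(c(192, 192), 20, seed = s),
                    seed = s + 500))
thr <- suggest_peak_threshold(blanks, preprocess_params(1))   # -> 3.86

ds    <- generate_dataset(default_study_config(n_cells = 8,
                                               shape_px = c(192, 192),
                                               seed = 42))
study <- run_full_pipeline(ds, preprocess_params(thr))
summary(study)
plot(study, analysis = "nn_distance")
```

```
STED nanocluster study: 24 cells, 156 localizations
  clusters/cell: median 6 (range 2-12)
  skipped: 5 cells for k-NN, 0 edge clusters, 0 unfit clusters
  ...
  nn_distance control vs pairs200: 1 significant region(s) [0-280 nm]; crossover 444; KS p(a>b)=1.4e-06, p(b>a)=0.607
  nn_distance pairs13 vs pairs200: 2 significant region(s) [0-502, 1441-1459 nm]; crossover 805; KS p(a>b)=1.62e-06, p(b>a)=1
  fwhm control vs pairs13: 1 significant region(s) [49-60 nm]; crossover 66; KS p(a>b)=0.891, p(b>a)=0.468
  ...
```

Reading the output: the 202.3 nm pair condition shifts nearest-neighbor
distances toward short values — its band separates from the control's over
0–280 nm, and the one-sided KS test confirms the control's distances are
stochastically larger (p ≈ 1.4e-06). Pairs at 13.6 nm are below STED
resolution: each pair merges into one localization, halving the cluster
density (longer neighbor distances) and enlarging apparent cluster sizes —
visible as the band separation at small FWHM (49–60 nm) where the control
has more mass. `write_study(study, "out/")` saves localizations,
distributions, statistics JSON and figures; a command-line front end for
the same flow is in `inst/scripts/stednano-cli.R`.

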