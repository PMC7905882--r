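# Shared fixtures built in code: small rendered images with known truth.

px_nm <- 20

# Noise-free rendering spec with (near-)fixed spot FWHM.
fixed_spec <- function(fwhm = 60, peak = 300, noise = "none", bg = 20,
                       out_bg = 2, profile = "lorentzian") {
  render_spec(pixel_size = px_nm, psf_profile = profile,
              fwhm_mean = fwhm, fwhm_sd = 1e-6, fwhm_min = fwhm - 1e-3,
              peak_photons = peak, background_photons = bg,
              outside_background = out_bg, noise = noise)
}

# One cell mask reused across tests (deterministic).
fixture_mask <- function(shape = c(128L, 128L), seed = 5L)
  make_cell_mask(shape, px_nm, seed = seed)

# Render an image holding the given points (rows of (x, y) nm, or a flat
# c(x1, y1, x2, y2, ...) vector) at a common FWHM.
render_points <- function(pts, fwhm = 60, mask = fixture_mask(),
                          spec = fixed_spec(fwhm), seed = 1L) {
  if (!is.matrix(pts)) pts <- matrix(pts, ncol = 2L, byrow = TRUE)
  gt <- ground_truth(pts, rep(fwhm, nrow(pts)))
  render_sted_image(gt, spec, mask, seed = seed)
}

# Isolated pair at a given spacing, random orientation, near the mask center.
pair_image <- function(spacing, seed, fwhm = 60, mask = fixture_mask(),
                       noise = "poisson", peak = 300) {
  force(mask)  # mask construction seeds the RNG; settle it first
  set.seed(seed)
  ctr <- dim(mask) / 2 * px_nm + stats::runif(2, -60, 60)
  ang <- stats::runif(1, 0, 2 * pi)
  half <- spacing / 2 * c(cos(ang), sin(ang))
  pts <- rbind(ctr + half, ctr - half)
  list(image = render_points(as.vector(t(pts)), fwhm = fwhm, mask = mask,
                             spec = fixed_spec(fwhm, peak = peak,
                                               noise = noise),
                             seed = seed),
       points = pts)
}

# Exhaustive O(n^2) k-NN oracle: per point, sort all pairwise distances.
knn_oracle <- function(pts, k) {
  n <- nrow(pts)
  out <- numeric(0)
  for (i in seq_len(n)) {
    d <- sqrt((pts[, 1] - pts[i, 1])^2 + (pts[, 2] - pts[i, 2])^2)
    out <- c(out, sort(d[-i])[seq_len(k)])
  }
  out
}

# Discrete normalized 2D Gaussian kernel peak value (matches the blur's
# sampled-Gaussian kernel of half-width ceiling(3*sigma) + 1).
discrete_gauss_peak <- function(sigma_px) {
  hw <- ceiling(3 * sigma_px) + 1
  g <- exp(-((-hw:hw)^2) / (2 * sigma_px^2))
  k2 <- outer(g, g)
  max(k2 / sum(k2))
}

# Batch threshold used across synthetic-image tests: calibrated once from
# blank cells rendered with the default photon levels (value frozen from
# suggest_peak_threshold; recomputed in test-preprocess.R).
default_threshold <- 3.1
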