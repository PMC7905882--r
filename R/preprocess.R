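# Preprocessing and cluster localization: raw STED image -> cluster
# coordinates. Chain: binarize cell -> remove out-of-cell background ->
# difference-of-Gaussians band-pass -> clip negatives + smooth ->
# standardize by (mean + sd) of the cell -> thresholded local-peak
# detection with adjacent-peak merging.

#' Preprocessing parameters
#'
#' All length scales are physical (nm) and are converted to pixels through
#' the image's pixel size, so the same parameters apply across acquisition
#' settings. The peak threshold is a global, batch-level value in
#' standardized intensity units; it has no universal default and must be
#' set per batch (see [suggest_peak_threshold()] for a data-driven
#' suggestion from blank calibration images).
#'
#' @param peak_threshold global peak threshold, standardized units (> 0).
#' @param dog_sigma1,dog_sigma2 difference-of-Gaussians sigmas in nm
#'   (defaults 0 and 100; `sigma1 = 0` means no first blur).
#' @param smooth_sigma post-clip Gaussian smoothing sigma in nm (default 15).
#' @param binarize_sigma smoothing sigma (nm) used inside [binarize_cell()].
#' @return object of class `preprocess_params`.
#' @export
preprocess_params <- function(peak_threshold, dog_sigma1 = 0, dog_sigma2 = 100,
                              smooth_sigma = 15, binarize_sigma = 50) {
  if (missing(peak_threshold) || !is.numeric(peak_threshold) ||
      peak_threshold <= 0)
    stop("'peak_threshold' (> 0, standardized units) is a required batch-level setting")
  if (dog_sigma1 < 0 || dog_sigma2 <= dog_sigma1)
    stop("need dog_sigma2 > dog_sigma1 >= 0")
  if (smooth_sigma < 0) stop("'smooth_sigma' must be >= 0")
  structure(list(peak_threshold = peak_threshold, dog_sigma1 = dog_sigma1,
                 dog_sigma2 = dog_sigma2, smooth_sigma = smooth_sigma,
                 binarize_sigma = binarize_sigma),
            class = "preprocess_params")
}

#' Binarize a raw STED image into a cell mask
#'
#' Two-pass segmentation of the cell outline. A smoothed copy (sigma
#' `binarize_sigma` nm) is first thresholded with Otsu's method on
#' log-compressed intensities, which keeps bright nanoclusters from
#' stretching the histogram and swallowing the dim in-cell background. The
#' threshold is then refined to the midpoint between the median smoothed
#' intensity inside and outside that rough mask, placing the boundary at
#' the half-height of the cell's intensity step. Finally the largest
#' connected component is kept and its holes filled. The raw image itself
#' is untouched.
#'
#' @param img a [sted_image()].
#' @param binarize_sigma smoothing sigma in nm (default 50; large enough to
#'   suppress shot noise, small enough not to round off the cell outline).
#' @return a [cell_mask()].
#' @export
binarize_cell <- function(img, binarize_sigma = 50) {
  stopifnot(inherits(img, "sted_image"))
  p <- img$pixels
  if (diff(range(p)) == 0) stop("constant image: no cell foreground found")
  sm <- blur_gaussian(p, binarize_sigma / img$pixel_size)
  lg <- log1p(sm - min(sm))
  rng <- range(lg)
  norm <- (lg - rng[1L]) / (rng[2L] - rng[1L])
  rough <- norm > EBImage::otsu(norm, range = c(0, 1))
  if (!any(rough) || all(rough)) stop("no cell foreground found")
  thr <- (stats::median(sm[rough]) + stats::median(sm[!rough])) / 2
  bin <- sm > thr
  if (!any(bin)) stop("no cell foreground found")
  lab <- EBImage::imageData(EBImage::bwlabel(bin))
  sizes <- tabulate(lab[lab > 0L])
  keep <- lab == which.max(sizes)
  keep <- EBImage::imageData(EBImage::fillHull(keep)) > 0
  cell_mask(keep, img$pixel_size)
}

#' Zero the image outside the cell
#'
#' @param img a [sted_image()].
#' @param mask a [cell_mask()] of matching shape.
#' @return a [sted_image()] with out-of-mask pixels exactly 0 and in-mask
#'   pixels unchanged.
#' @export
mask_background <- function(img, mask) {
  stopifnot(inherits(img, "sted_image"))
  if (!all(dim(img$pixels) == dim(mask)))
    stop("image and mask shapes differ")
  p <- img$pixels
  p[!mask] <- 0
  sted_image(p, img$pixel_size)
}

#' Difference-of-Gaussians band-pass filter
#'
#' `G(sigma1) * img - G(sigma2) * img` with sigmas in nm (`sigma = 0` is the
#' identity blur). Enhances spot-like features between the two scales.
#' Boundary handling is mirror reflection.
#'
#' @param img a [sted_image()].
#' @param sigma1,sigma2 Gaussian sigmas in nm, `sigma2 > sigma1 >= 0`.
#' @return filtered image (values may be negative).
#' @export
dog_filter <- function(img, sigma1 = 0, sigma2 = 100) {
  stopifnot(inherits(img, "sted_image"))
  if (sigma1 < 0 || sigma2 <= sigma1) stop("need sigma2 > sigma1 >= 0")
  px <- img$pixel_size
  out <- blur_gaussian(img$pixels, sigma1 / px) -
    blur_gaussian(img$pixels, sigma2 / px)
  structure(list(pixels = out, pixel_size = px), class = "sted_image")
}

#' Clip negative values and smooth
#'
#' Negative pixels are set to 0, then a Gaussian smoothing of sigma
#' `smooth_sigma` nm (reflective boundary) is applied. The smoothing kernel
#' is normalized, so the total intensity of the clipped image is conserved.
#'
#' @param img a [sted_image()] (possibly with negative values).
#' @param smooth_sigma sigma in nm; 0 means clip only.
#' @return non-negative smoothed image.
#' @export
clip_and_smooth <- function(img, smooth_sigma = 15) {
  stopifnot(inherits(img, "sted_image"))
  p <- pmax(img$pixels, 0)
  p <- blur_gaussian(p, smooth_sigma / img$pixel_size)
  sted_image(pmax(p, 0), img$pixel_size)
}

#' Standardize intensities by the cell's mean plus standard deviation
#'
#' Divides every pixel by `mean + sd` of the in-mask pixels, bringing images
#' acquired with different settings to a common intensity scale (the result
#' is invariant under global intensity scaling). Out-of-mask pixels are set
#' to 0.
#'
#' @param img a [sted_image()].
#' @param mask a [cell_mask()].
#' @return standardized image.
#' @export
standardize <- function(img, mask) {
  stopifnot(inherits(img, "sted_image"))
  if (!all(dim(img$pixels) == dim(mask)))
    stop("image and mask shapes differ")
  if (!any(mask)) stop("mask is empty")
  v <- img$pixels[mask]
  divisor <- mean(v) + stats::sd(v)
  if (!is.finite(divisor) || divisor <= 0)
    stop("degenerate cell: mean + sd of in-mask intensities is not positive")
  p <- img$pixels / divisor
  p[!mask] <- 0
  sted_image(p, img$pixel_size)
}

#' Detect cluster localizations as merged local intensity peaks
#'
#' Finds local maxima (8-neighborhood) of the standardized, smoothed image
#' that exceed the global threshold and lie inside the mask. Maxima in
#' touching pixels (equal-valued plateaus) are merged into one localization
#' at their intensity-weighted centroid, so one cluster never yields
#' multiple localizations. Coordinates are returned in nm with pixel centers
#' at `(index - 0.5) * pixel_size`.
#'
#' @param img the standardized [sted_image()].
#' @param threshold global peak threshold in standardized units (> 0).
#' @param mask a [cell_mask()].
#' @return a `cluster_locs` data.frame with columns `x_nm`, `y_nm`,
#'   `intensity`, carrying `pixel_size` and `extent` (frame size in nm,
#'   `c(x, y)`) attributes. May have zero rows.
#' @export
localize_clusters <- function(img, threshold, mask) {
  stopifnot(inherits(img, "sted_image"))
  if (!is.numeric(threshold) || threshold <= 0)
    stop("'threshold' must be > 0 (standardized units)")
  if (!all(dim(img$pixels) == dim(mask)))
    stop("image and mask shapes differ")
  px <- img$pixel_size
  pk <- find_peaks(img$pixels, threshold = threshold, mask = mask)
  cluster_locs(data.frame(x_nm = (pk$j - 0.5) * px,
                          y_nm = (pk$i - 0.5) * px,
                          intensity = pk$value),
               pixel_size = px,
               extent = c(ncol(img$pixels), nrow(img$pixels)) * px)
}

#' Cluster localization container
#'
#' @param df data.frame with at least `x_nm` and `y_nm` columns.
#' @param pixel_size source pixel size in nm.
#' @param extent frame extent in nm, `c(x, y)`.
#' @param cell_id,condition optional provenance labels.
#' @return `cluster_locs` data.frame.
#' @export
cluster_locs <- function(df, pixel_size = NULL, extent = NULL,
                         cell_id = NULL, condition = NULL) {
  stopifnot(is.data.frame(df), all(c("x_nm", "y_nm") %in% names(df)))
  structure(df, pixel_size = pixel_size, extent = extent,
            cell_id = cell_id, condition = condition,
            class = c("cluster_locs", "data.frame"))
}

#' Full preprocessing and localization chain
#'
#' Runs binarize -> mask -> DoG -> clip + smooth -> standardize -> localize
#' on one raw image.
#'
#' @param raw a raw [sted_image()] (at least 64 x 64 pixels).
#' @param params a [preprocess_params()].
#' @return object of class `sted_localization`: list with `localizations`
#'   (a `cluster_locs` data.frame), `mask`, `image` (the standardized image
#'   used for sizing) and `params`.
#' @export
run_preprocessing <- function(raw, params) {
  stopifnot(inherits(raw, "sted_image"), inherits(params, "preprocess_params"))
  if (any(dim(raw$pixels) < 64)) stop("image must be at least 64 x 64 pixels")
  mask <- binarize_cell(raw, params$binarize_sigma)
  masked <- mask_background(raw, mask)
  band <- dog_filter(masked, params$dog_sigma1, params$dog_sigma2)
  smooth <- clip_and_smooth(band, params$smooth_sigma)
  std <- standardize(smooth, mask)
  locs <- localize_clusters(std, params$peak_threshold, mask)
  structure(list(localizations = locs, mask = mask, image = std,
                 params = params), class = "sted_localization")
}

#' @export
print.sted_localization <- function(x, ...) {
  cat(sprintf("<sted_localization> %d clusters in %.2f um^2 cell (threshold %.3g)\n",
              nrow(x$localizations), mask_area_um2(x$mask),
              x$params$peak_threshold))
  invisible(x)
}

#' Suggest a global peak threshold from blank calibration images
#'
#' Runs the preprocessing chain on cluster-free (blank) calibration images
#' and returns `margin` times the largest standardized local-maximum value
#' observed inside the cells, i.e. a level just above what background noise
#' alone produces. Synthetic blanks with the acquisition's photon levels can
#' be generated with [render_sted_image()] and an empty [ground_truth()].
#'
#' @param blanks list of raw [sted_image()] objects without clusters.
#' @param params a [preprocess_params()] (its `peak_threshold` is ignored
#'   here and may be any positive placeholder).
#' @param margin multiplicative safety margin (default 1.25).
#' @return suggested threshold in standardized units.
#' @export
suggest_peak_threshold <- function(blanks, params, margin = 1.25) {
  stopifnot(is.list(blanks), length(blanks) >= 1L)
  vals <- unlist(lapply(blanks, function(raw) {
    mask <- binarize_cell(raw, params$binarize_sigma)
    masked <- mask_background(raw, mask)
    band <- dog_filter(masked, params$dog_sigma1, params$dog_sigma2)
    smooth <- clip_and_smooth(band, params$smooth_sigma)
    std <- standardize(smooth, mask)
    pk <- find_peaks(std$pixels, threshold = 0, mask = mask)
    pk$value
  }))
  if (!length(vals)) stop("no background peaks found in calibration images")
  margin * max(vals)
}
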