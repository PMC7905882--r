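# Per-cell cluster statistics: local density-peak intensities from 2D KDE
# maps, k-nearest-neighbor distances, and cluster sizes from Lorentzian
# line-profile fits.

#' 2D kernel density map of cluster localizations
#'
#' Evaluates `sum_i exp(-||p - x_i||^2 / (2 bw^2))` on a regular grid. Each
#' Gaussian kernel has unit peak amplitude (not unit mass), so the map reads
#' directly as the kernel-weighted number of clusters around each position:
#' an isolated cluster contributes a peak of exactly 1, m coincident
#' clusters a peak of m. Kernels are truncated at 4 bandwidths
#' (`exp(-8) ~ 3e-4`), identically for every point, which preserves exact
#' additivity of maps under unions of point sets.
#'
#' @param locs a `cluster_locs` data.frame (>= 1 localization).
#' @param bandwidth Gaussian kernel bandwidth in nm (default 200).
#' @param grid_spacing grid step in nm; defaults to the source pixel size
#'   (or `bandwidth / 10` when unknown).
#' @param extent frame extent in nm `c(x, y)`; defaults to the `extent`
#'   attribute of `locs`, else the points' bounding box padded by 3
#'   bandwidths.
#' @return object of class `density_map`: list with `grid` (matrix, rows =
#'   y), `grid_spacing`, `bandwidth`.
#' @export
density_map <- function(locs, bandwidth = 200, grid_spacing = NULL,
                        extent = NULL) {
  if (!is.data.frame(locs) || nrow(locs) == 0L)
    stop("need at least one localization")
  if (!is.numeric(bandwidth) || bandwidth <= 0) stop("'bandwidth' must be > 0")
  pts <- cbind(locs$x_nm, locs$y_nm)
  grid_spacing <- grid_spacing %||% attr(locs, "pixel_size") %||% (bandwidth / 10)
  offset <- c(0, 0)
  if (is.null(extent)) extent <- attr(locs, "extent")
  if (is.null(extent)) {
    lo <- apply(pts, 2L, min) - 3 * bandwidth
    hi <- apply(pts, 2L, max) + 3 * bandwidth
    offset <- lo
    extent <- hi - lo
  }
  nx <- max(1L, ceiling(extent[1L] / grid_spacing))
  ny <- max(1L, ceiling(extent[2L] / grid_spacing))
  xg <- offset[1L] + (seq_len(nx) - 0.5) * grid_spacing
  yg <- offset[2L] + (seq_len(ny) - 0.5) * grid_spacing
  m <- matrix(0, ny, nx)
  cut <- 4 * bandwidth
  for (s in seq_len(nrow(pts))) {
    jr <- which(abs(xg - pts[s, 1L]) <= cut)
    ir <- which(abs(yg - pts[s, 2L]) <= cut)
    if (!length(jr) || !length(ir)) next
    r2 <- outer((yg[ir] - pts[s, 2L])^2, (xg[jr] - pts[s, 1L])^2, `+`)
    m[ir, jr] <- m[ir, jr] + exp(-r2 / (2 * bandwidth^2))
  }
  structure(list(grid = m, grid_spacing = grid_spacing, bandwidth = bandwidth,
                 origin = offset), class = "density_map")
}

#' @export
print.density_map <- function(x, ...) {
  cat(sprintf("<density_map> %d x %d @ %.3g nm, bandwidth %g nm, max %.3g\n",
              nrow(x$grid), ncol(x$grid), x$grid_spacing, x$bandwidth,
              max(x$grid)))
  invisible(x)
}

#' Intensities of local density peaks
#'
#' Detects local maxima of the density map (8-neighborhood, plateaus
#' merged) and returns their intensities: the cell's distribution of local
#' cluster-density peak values. A flat map yields an empty distribution.
#'
#' @param map a [density_map()].
#' @return numeric vector of peak intensities (kernel-weighted cluster
#'   counts).
#' @export
density_peak_intensities <- function(map) {
  stopifnot(inherits(map, "density_map"))
  pk <- find_peaks(map$grid, threshold = sqrt(.Machine$double.eps))
  pk$value
}

#' k-nearest-neighbor distances of a localization set
#'
#' For every localization, the Euclidean distances to its `k` nearest other
#' localizations (self excluded), pooled into one vector of length
#' `k * n`. With the default `k = 4` the distribution covers essentially all
#' neighbors within ~200 nm of a cluster while excluding those beyond
#' ~800 nm, for typical cluster densities.
#'
#' @param locs a `cluster_locs` data.frame with more than `k` rows.
#' @param k neighbors per localization (default 4).
#' @return numeric vector of length `k * nrow(locs)`; per point the k
#'   distances are in increasing order.
#' @export
knn_distances <- function(locs, k = 4L) {
  if (!is.data.frame(locs)) stop("'locs' must be a data.frame")
  n <- nrow(locs)
  if (n <= k) {
    id <- attr(locs, "cell_id")
    stop(sprintf("need more than k = %d localizations (got %d)%s", k, n,
                 if (is.null(id)) "" else sprintf(" in cell '%s'", id)))
  }
  d <- as.matrix(stats::dist(cbind(locs$x_nm, locs$y_nm)))
  diag(d) <- Inf
  as.vector(apply(d, 2L, function(col)
    sort.int(sort.int(col, partial = k)[seq_len(k)])))
}

#' Extract radial line profiles through a point
#'
#' Samples the image by bilinear interpolation along lines of the given
#' length through `center`, one per angle, at a fixed step (default one
#' pixel). At the default step, axis-aligned profiles through pixel centers
#' read exact pixel values, which keeps peak shapes undistorted; finer
#' steps interpolate between pixels and slightly flatten sharp peaks.
#' Profiles that would leave the image are not extracted.
#'
#' @param img a [sted_image()].
#' @param center `c(x_nm, y_nm)`.
#' @param length profile length in nm (default 400).
#' @param angles line angles in degrees (default 0, 45, 90, 135).
#' @param step sampling step in nm; default `pixel_size`.
#' @return named list (one element per angle) of data.frames with columns
#'   `offset_nm` (signed distance from the center) and `value`, or `NULL`
#'   when the profile would exit the image.
#' @export
extract_line_profiles <- function(img, center, length = 400,
                                  angles = c(0, 45, 90, 135), step = NULL) {
  stopifnot(inherits(img, "sted_image"), length(center) == 2L)
  px <- img$pixel_size
  step <- step %||% px
  w <- ncol(img$pixels) * px; h <- nrow(img$pixels) * px
  half <- length / 2
  # bilinear support needs half a pixel of margin on every side
  if (center[1L] - half < px / 2 || center[1L] + half > w - px / 2 ||
      center[2L] - half < px / 2 || center[2L] + half > h - px / 2)
    return(NULL)
  t <- seq(-half, half, by = step)
  out <- lapply(angles, function(a) {
    th <- a * pi / 180
    data.frame(offset_nm = t,
               value = bilinear_at(img$pixels,
                                   center[1L] + t * cos(th),
                                   center[2L] + t * sin(th), px))
  })
  names(out) <- paste0("deg", angles)
  out
}

# Bilinear interpolation at nm coordinates; pixel centers at (k - 0.5) * px.
bilinear_at <- function(m, x, y, px) {
  fi <- y / px + 0.5
  fj <- x / px + 0.5
  i0 <- pmin(pmax(floor(fi), 1L), nrow(m) - 1L)
  j0 <- pmin(pmax(floor(fj), 1L), ncol(m) - 1L)
  di <- pmin(pmax(fi - i0, 0), 1)
  dj <- pmin(pmax(fj - j0, 0), 1)
  m[cbind(i0, j0)] * (1 - di) * (1 - dj) +
    m[cbind(i0 + 1L, j0)] * di * (1 - dj) +
    m[cbind(i0, j0 + 1L)] * (1 - di) * dj +
    m[cbind(i0 + 1L, j0 + 1L)] * di * dj
}

#' Fit a Lorentzian to a 1D line profile
#'
#' Least-squares fit of `L(x) = offset + A / (1 + ((x - x0)/gamma)^2)`
#' (Levenberg-Marquardt). The spot size is `FWHM = 2 * gamma`. Fit quality
#' is `R^2 = 1 - SS_res / SS_tot` against the fitted curve. A fit that does
#' not converge is returned flagged (`ok = FALSE`), never as an error.
#'
#' Initialization: `A = max - min`, `x0 = argmax`, `gamma = 50` nm,
#' `offset = min`, with `gamma` bounded to (5, 400) nm.
#'
#' @param x sample positions (nm), at least 8.
#' @param y profile values.
#' @return object of class `lorentz_fit` with elements `amplitude`,
#'   `center`, `gamma`, `offset`, `fwhm`, `r_squared`, `ok`, `fitted`.
#' @export
fit_lorentzian <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 8L) stop("profile must have at least 8 samples")
  fail <- structure(list(amplitude = NA_real_, center = NA_real_,
                         gamma = NA_real_, offset = NA_real_,
                         fwhm = NA_real_, r_squared = NA_real_,
                         ok = FALSE, fitted = rep(NA_real_, length(x)),
                         x = x, y = y),
                    class = "lorentz_fit")
  ss_tot <- sum((y - mean(y))^2)
  if (ss_tot == 0) return(fail)
  start <- list(offset = min(y), A = max(y) - min(y), x0 = x[which.max(y)],
                g = 50)
  fit <- tryCatch(
    suppressWarnings(minpack.lm::nls.lm(
      par = start,
      fn = function(p) y - (p$offset + p$A / (1 + ((x - p$x0) / p$g)^2)),
      lower = c(offset = -Inf, A = 0, x0 = min(x), g = 5),
      upper = c(offset = Inf, A = Inf, x0 = max(x), g = 400),
      control = minpack.lm::nls.lm.control(maxiter = 100))),
    error = function(e) NULL)
  # info codes 1-4 signal Levenberg-Marquardt convergence
  if (is.null(fit) || !fit$info %in% 1:4) return(fail)
  p <- unlist(fit$par)
  yhat <- p[["offset"]] + p[["A"]] / (1 + ((x - p[["x0"]]) / p[["g"]])^2)
  structure(list(amplitude = unname(p[["A"]]), center = unname(p[["x0"]]),
                 gamma = unname(p[["g"]]), offset = unname(p[["offset"]]),
                 fwhm = 2 * unname(p[["g"]]),
                 r_squared = 1 - sum((y - yhat)^2) / ss_tot,
                 ok = TRUE, fitted = yhat, x = x, y = y),
            class = "lorentz_fit")
}

#' @export
print.lorentz_fit <- function(x, ...) {
  if (!x$ok) cat("<lorentz_fit> failed fit\n")
  else cat(sprintf("<lorentz_fit> FWHM %.1f nm (gamma %.1f), R^2 %.4f\n",
                   x$fwhm, x$gamma, x$r_squared))
  invisible(x)
}

#' @export
coef.lorentz_fit <- function(object, ...) {
  c(amplitude = object$amplitude, center = object$center,
    gamma = object$gamma, offset = object$offset)
}

#' Per-cluster FWHM sizes from line-profile fits
#'
#' For every localization, extracts up to four 400 nm line profiles (0, 45,
#' 90, 135 degrees) from the standardized image, fits a Lorentzian to each,
#' keeps fits with `R^2 > r2_threshold`, and takes the minimum passing FWHM
#' as the cluster size (the minimum over orientations approximates the short
#' axis for elongated spots). Clusters too close to the image edge for a
#' full profile, and clusters with no passing fit, are dropped and counted.
#'
#' @param img the standardized [sted_image()].
#' @param locs the matching `cluster_locs`.
#' @param r2_threshold minimum fit R^2 (default 0.9).
#' @param profile_length profile length in nm (default 400).
#' @param angles profile angles in degrees.
#' @return list with `values` (cluster FWHMs, nm), `n_clusters`,
#'   `n_edge_skipped`, `n_no_fit`.
#' @export
cluster_fwhm <- function(img, locs, r2_threshold = 0.9, profile_length = 400,
                         angles = c(0, 45, 90, 135)) {
  stopifnot(inherits(img, "sted_image"), is.data.frame(locs))
  values <- numeric(0)
  n_edge <- 0L; n_nofit <- 0L
  for (s in seq_len(nrow(locs))) {
    prof <- extract_line_profiles(img, c(locs$x_nm[s], locs$y_nm[s]),
                                  length = profile_length, angles = angles)
    if (is.null(prof)) { n_edge <- n_edge + 1L; next }
    fw <- vapply(prof, function(pr) {
      f <- fit_lorentzian(pr$offset_nm, pr$value)
      if (f$ok && f$r_squared > r2_threshold) f$fwhm else NA_real_
    }, numeric(1))
    fw <- fw[!is.na(fw)]
    if (!length(fw)) { n_nofit <- n_nofit + 1L; next }
    values <- c(values, min(fw))
  }
  list(values = values, n_clusters = nrow(locs),
       n_edge_skipped = n_edge, n_no_fit = n_nofit)
}
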