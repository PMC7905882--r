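# Synthetic STED image generator: cell-shaped masks, spatial point processes
# for cluster centers, and spot rendering with photon noise. Ground truth is
# kept alongside every image so the localization chain can be validated.

#' Spatial point-process specification for cluster centers
#'
#' Defines how synthetic cluster centers are laid out inside a cell mask.
#' Four kinds are supported:
#' \describe{
#'   \item{csr}{complete spatial randomness (homogeneous Poisson) at
#'     `intensity` clusters per um^2.}
#'   \item{thomas}{Thomas cluster process: Poisson parents at
#'     `parent_intensity` per um^2, each with Poisson(`offspring_per_parent`)
#'     offspring displaced by an isotropic Gaussian of sd `offspring_sd` nm.}
#'   \item{fixed_pairs}{isolated pairs with exact separation `pair_spacing`
#'     nm and random isotropic orientation; emulates ligands presented at a
#'     designed spacing. `intensity` still counts single clusters per um^2,
#'     so the expected number of pairs is `intensity * area / 2`.}
#'   \item{coincident}{groups of `multiplicity` clusters at identical
#'     coordinates; `intensity` counts groups per um^2. Useful for testing
#'     additivity of density maps.}
#' }
#'
#' @param kind one of `"csr"`, `"thomas"`, `"fixed_pairs"`, `"coincident"`.
#' @param intensity clusters (or groups) per um^2; must be > 0.
#' @param pair_spacing pair separation in nm (`fixed_pairs` only).
#' @param parent_intensity,offspring_per_parent,offspring_sd Thomas-process
#'   parameters (parents per um^2, mean offspring per parent, offspring
#'   displacement sd in nm).
#' @param multiplicity group size for `coincident`.
#' @return object of class `point_process`.
#' @export
point_process <- function(kind = c("csr", "thomas", "fixed_pairs", "coincident"),
                          intensity = 1, pair_spacing = NULL,
                          parent_intensity = NULL, offspring_per_parent = NULL,
                          offspring_sd = NULL, multiplicity = NULL) {
  kind <- match.arg(kind)
  if (!is.numeric(intensity) || intensity <= 0)
    stop("'intensity' must be > 0 (clusters per um^2)")
  if (kind == "fixed_pairs") {
    if (is.null(pair_spacing) || pair_spacing <= 0)
      stop("'pair_spacing' (nm) must be > 0 for kind = 'fixed_pairs'")
  }
  if (kind == "thomas") {
    if (is.null(parent_intensity) || parent_intensity <= 0)
      stop("'parent_intensity' must be > 0 for kind = 'thomas'")
    if (is.null(offspring_per_parent) || offspring_per_parent <= 0)
      stop("'offspring_per_parent' must be > 0 for kind = 'thomas'")
    if (is.null(offspring_sd) || offspring_sd <= 0)
      stop("'offspring_sd' (nm) must be > 0 for kind = 'thomas'")
  }
  if (kind == "coincident") {
    if (is.null(multiplicity) || multiplicity < 2 ||
        multiplicity != round(multiplicity))
      stop("'multiplicity' must be an integer >= 2 for kind = 'coincident'")
  }
  structure(list(kind = kind, intensity = intensity,
                 pair_spacing = pair_spacing,
                 parent_intensity = parent_intensity,
                 offspring_per_parent = offspring_per_parent,
                 offspring_sd = offspring_sd,
                 multiplicity = if (!is.null(multiplicity)) as.integer(multiplicity)),
            class = "point_process")
}

#' Rendering specification for synthetic STED spots
#'
#' Controls how ground-truth cluster centers are turned into an image. Each
#' cluster is rendered as a radially symmetric spot sampled at pixel centers:
#' a 2D Lorentzian `A / (1 + (r/gamma)^2)` by default (self-consistent with
#' the Lorentzian FWHM estimator applied downstream) or a Gaussian for
#' robustness checks. Per-cluster apparent sizes (FWHM, nm) are drawn from a
#' truncated normal. Expected photon counts are `peak_photons` at a spot
#' center, `background_photons` per in-cell pixel and `outside_background`
#' per pixel outside the cell; Poisson noise is applied when
#' `noise = "poisson"`.
#'
#' @param pixel_size pixel size in nm; must lie in `[10, 50]` (STED images in
#'   this regime are acquired at 20-25 nm).
#' @param psf_profile `"lorentzian"` or `"gaussian"` spot shape.
#' @param fwhm_mean,fwhm_sd,fwhm_min truncated-normal parameters (nm) for
#'   per-cluster apparent FWHM; the truncation point must exceed
#'   `2 * pixel_size` so spots stay resolvable.
#' @param peak_photons expected counts at a spot center.
#' @param background_photons expected counts per in-cell pixel.
#' @param outside_background expected counts per pixel outside the cell.
#' @param noise `"poisson"` or `"none"`.
#' @return object of class `render_spec`.
#' @export
render_spec <- function(pixel_size = 20, psf_profile = c("lorentzian", "gaussian"),
                        fwhm_mean = 80, fwhm_sd = 20, fwhm_min = 40,
                        peak_photons = 300, background_photons = 20,
                        outside_background = 2, noise = c("poisson", "none")) {
  psf_profile <- match.arg(psf_profile)
  noise <- match.arg(noise)
  if (pixel_size < 10 || pixel_size > 50)
    stop("'pixel_size' must be within [10, 50] nm")
  if (fwhm_min < 2 * pixel_size)
    stop("'fwhm_min' must be at least 2 * pixel_size for resolvable spots")
  if (fwhm_sd < 0 || fwhm_mean <= 0) stop("invalid FWHM distribution")
  if (peak_photons <= 0 || background_photons < 0 || outside_background < 0)
    stop("photon levels must be non-negative (peak > 0)")
  structure(list(pixel_size = pixel_size, psf_profile = psf_profile,
                 fwhm_mean = fwhm_mean, fwhm_sd = fwhm_sd, fwhm_min = fwhm_min,
                 peak_photons = peak_photons,
                 background_photons = background_photons,
                 outside_background = outside_background, noise = noise),
            class = "render_spec")
}

#' Ground truth for one synthetic cell
#'
#' @param points n x 2 matrix of cluster centers (x_nm, y_nm).
#' @param fwhm length-n vector of true apparent spot FWHMs (nm).
#' @param process the [point_process()] that generated the points (optional).
#' @param seed the seed used (optional, for provenance).
#' @return object of class `ground_truth`.
#' @export
ground_truth <- function(points, fwhm, process = NULL, seed = NULL) {
  points <- matrix(as.numeric(points), ncol = 2L,
                   dimnames = list(NULL, c("x_nm", "y_nm")))
  if (length(fwhm) != nrow(points))
    stop("'points' and 'fwhm' must have equal length")
  if (nrow(points) && any(fwhm <= 0)) stop("'fwhm' must be positive")
  structure(list(points = points, fwhm = as.numeric(fwhm),
                 process = process, seed = seed), class = "ground_truth")
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("<ground_truth> %d clusters (%s process)\n", nrow(x$points),
              if (is.null(x$process)) "unspecified" else x$process$kind))
  invisible(x)
}

# Truncated-normal FWHM draws (simple rejection; truncation keeps spots
# resolvable at the rendering pixel size).
rtrunc_fwhm <- function(n, mean, sd, lower) {
  if (n == 0L) return(numeric(0))
  out <- numeric(0)
  while (length(out) < n) {
    cand <- stats::rnorm(n, mean, sd)
    out <- c(out, cand[cand >= lower])
  }
  out[seq_len(n)]
}

# Uniform sampling over the mask: pick an in-mask pixel, then a uniform
# position within it (exactly uniform over the mask's area).
sample_in_mask <- function(n, mask, px) {
  idx <- which(mask)
  if (!length(idx)) stop("mask is empty")
  pick <- idx[sample.int(length(idx), n, replace = TRUE)]
  i <- (pick - 1L) %% nrow(mask) + 1L
  j <- (pick - 1L) %/% nrow(mask) + 1L
  cbind(x_nm = (j - 1L) * px + stats::runif(n) * px,
        y_nm = (i - 1L) * px + stats::runif(n) * px)
}

point_in_mask <- function(x, y, mask, px) {
  j <- ceiling(x / px); i <- ceiling(y / px)
  ok <- i >= 1 & i <= nrow(mask) & j >= 1 & j <= ncol(mask)
  ok[ok] <- mask[cbind(i[ok], j[ok])]
  ok
}

#' Generate a cell-shaped binary mask
#'
#' Draws a star-convex blob (a smoothly perturbed ellipse whose radius is
#' modulated by a low-order random Fourier series) roughly centered in the
#' frame, emulating the outline of an adherent cell. The region is connected
#' by construction and occupies 20-70% of the frame.
#'
#' @param shape_px frame size in pixels, `c(rows, cols)`; each must be >= 64.
#' @param pixel_size pixel size in nm.
#' @param seed integer seed; the mask is a pure function of
#'   `(shape_px, pixel_size, seed)`.
#' @return a [cell_mask()].
#' @examples
#' m <- make_cell_mask(c(128, 128), 20, seed = 1)
#' mean(m)
#' @export
make_cell_mask <- function(shape_px = c(512L, 512L), pixel_size = 20, seed = 1L) {
  if (length(shape_px) != 2L || any(shape_px < 64))
    stop("'shape_px' must be two integers >= 64")
  set.seed(seed)
  nr <- shape_px[1L]; nc <- shape_px[2L]
  cy <- nr / 2 + stats::runif(1, -0.05, 0.05) * nr
  cx <- nc / 2 + stats::runif(1, -0.05, 0.05) * nc
  r0 <- 0.38 * min(nr, nc)
  k <- 2:5
  amp <- stats::runif(length(k), 0, 0.18) / seq_along(k)
  phs <- stats::runif(length(k), 0, 2 * pi)
  jj <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  ii <- matrix(seq_len(nr), nr, nc)
  theta <- atan2(ii - cy, jj - cx)
  rad <- sqrt((ii - cy)^2 + (jj - cx)^2)
  rmod <- r0 * (1 + Reduce(`+`, Map(function(a, kk, p) a * cos(kk * theta + p),
                                    amp, k, phs)))
  m <- rad <= rmod
  if (mean(m) < 0.2 || mean(m) > 0.7)  # guarded by construction
    stop("generated mask outside the 20-70% area-fraction envelope")
  cell_mask(m, pixel_size)
}

#' Sample cluster centers inside a cell mask
#'
#' Realizes the [point_process()] inside the mask and draws a per-cluster
#' apparent FWHM from the truncated normal given by `fwhm_mean`, `fwhm_sd`
#' and `fwhm_min`. For `fixed_pairs`, anchors are placed uniformly and the
#' partner at exactly `pair_spacing` nm in a uniform random direction; a pair
#' is re-drawn when the partner leaves the mask, and placement fails with an
#' error after a bounded number of retries.
#'
#' @param process a [point_process()].
#' @param mask a [cell_mask()].
#' @param seed integer seed.
#' @param fwhm_mean,fwhm_sd,fwhm_min truncated-normal FWHM parameters (nm).
#' @param max_tries retry bound per pair placement.
#' @return a [ground_truth()].
#' @export
sample_cluster_points <- function(process, mask, seed = 1L,
                                  fwhm_mean = 80, fwhm_sd = 20, fwhm_min = 40,
                                  max_tries = 1000L) {
  stopifnot(inherits(process, "point_process"), inherits(mask, "cell_mask"))
  if (!any(mask)) stop("mask is empty")
  px <- attr(mask, "pixel_size")
  area <- mask_area_um2(mask)
  set.seed(seed)
  pts <- switch(process$kind,
    csr = {
      n <- stats::rpois(1L, process$intensity * area)
      sample_in_mask(n, mask, px)
    },
    coincident = {
      ng <- stats::rpois(1L, process$intensity * area)
      centers <- sample_in_mask(ng, mask, px)
      centers[rep(seq_len(ng), each = process$multiplicity), , drop = FALSE]
    },
    thomas = {
      np <- stats::rpois(1L, process$parent_intensity * area)
      parents <- sample_in_mask(np, mask, px)
      noff <- stats::rpois(np, process$offspring_per_parent)
      if (sum(noff) == 0L) matrix(numeric(0), 0L, 2L) else {
        ctr <- parents[rep(seq_len(np), noff), , drop = FALSE]
        off <- ctr + matrix(stats::rnorm(2L * nrow(ctr), 0, process$offspring_sd),
                            ncol = 2L)
        off[point_in_mask(off[, 1L], off[, 2L], mask, px), , drop = FALSE]
      }
    },
    fixed_pairs = {
      npairs <- stats::rpois(1L, process$intensity * area / 2)
      out <- matrix(numeric(0), 0L, 2L)
      tries <- 0L
      placed <- 0L
      while (placed < npairs) {
        tries <- tries + 1L
        if (tries > max_tries)
          stop("pair placement failed after ", max_tries,
               " retries; intensity or spacing too high for this mask")
        a <- sample_in_mask(1L, mask, px)
        ang <- stats::runif(1L, 0, 2 * pi)
        b <- a + process$pair_spacing * c(cos(ang), sin(ang))
        if (point_in_mask(b[1L], b[2L], mask, px)) {
          out <- rbind(out, a, b)
          placed <- placed + 1L
        }
      }
      out
    })
  colnames(pts) <- c("x_nm", "y_nm")
  fwhm <- rtrunc_fwhm(nrow(pts), fwhm_mean, fwhm_sd, fwhm_min)
  ground_truth(pts, fwhm, process = process, seed = seed)
}

# Radial spot profile sampled on squared distance; unit peak amplitude.
spot_profile_r2 <- function(r2, fwhm, profile) {
  if (profile == "lorentzian") {
    g <- fwhm / 2
    1 / (1 + r2 / g^2)
  } else {
    s <- fwhm / (2 * sqrt(2 * log(2)))
    exp(-r2 / (2 * s^2))
  }
}

#' Render a synthetic STED image from ground truth
#'
#' The noiseless image is the sum of per-cluster spot profiles (peak
#' amplitude `peak_photons`, per-cluster FWHM from the ground truth) sampled
#' at pixel centers, plus `background_photons` inside the mask and
#' `outside_background` outside. With `noise = "poisson"` every pixel is
#' replaced by a Poisson draw with that expectation. Spots are evaluated out
#' to the radius where the profile falls below 1e-3 (Lorentzian) or 1e-6
#' (Gaussian) of its peak.
#'
#' @param gt a [ground_truth()]; all points must lie inside the frame.
#' @param spec a [render_spec()].
#' @param mask a [cell_mask()] defining the background region.
#' @param seed seed for the photon noise.
#' @return a [sted_image()].
#' @export
render_sted_image <- function(gt, spec, mask, seed = 1L) {
  stopifnot(inherits(gt, "ground_truth"), inherits(spec, "render_spec"),
            inherits(mask, "cell_mask"))
  px <- spec$pixel_size
  nr <- nrow(mask); nc <- ncol(mask)
  if (nrow(gt$points) &&
      (any(gt$points[, 1L] < 0 | gt$points[, 1L] > nc * px) ||
       any(gt$points[, 2L] < 0 | gt$points[, 2L] > nr * px)))
    stop("ground-truth points fall outside the frame")
  img <- matrix(spec$outside_background, nr, nc)
  img[mask] <- spec$background_photons
  xc <- (seq_len(nc) - 0.5) * px
  yc <- (seq_len(nr) - 0.5) * px
  for (s in seq_len(nrow(gt$points))) {
    x0 <- gt$points[s, 1L]; y0 <- gt$points[s, 2L]; fw <- gt$fwhm[s]
    rc <- if (spec$psf_profile == "lorentzian") {
      (fw / 2) * sqrt(1 / 1e-3 - 1)
    } else {
      fw / (2 * sqrt(2 * log(2))) * sqrt(2 * log(1e6))
    }
    j0 <- max(1L, floor((x0 - rc) / px)); j1 <- min(nc, ceiling((x0 + rc) / px))
    i0 <- max(1L, floor((y0 - rc) / px)); i1 <- min(nr, ceiling((y0 + rc) / px))
    if (j0 > j1 || i0 > i1) next
    r2 <- outer((yc[i0:i1] - y0)^2, (xc[j0:j1] - x0)^2, `+`)
    img[i0:i1, j0:j1] <- img[i0:i1, j0:j1] +
      spec$peak_photons * spot_profile_r2(r2, fw, spec$psf_profile)
  }
  if (spec$noise == "poisson") {
    set.seed(seed)
    img[] <- stats::rpois(length(img), img)
  }
  sted_image(img, px)
}

#' Configuration for a synthetic multi-condition dataset
#'
#' @param conditions named list of [point_process()] objects, one per
#'   condition (>= 2 conditions).
#' @param n_cells cells per condition (>= 2).
#' @param shape_px frame size in pixels.
#' @param render a [render_spec()].
#' @param seed master seed; per-cell seeds are derived as
#'   `(seed * 10007 + index * 97) mod (2^31 - 19) + 1` with `index` the
#'   running cell number, and echoed in the dataset so any cell can be
#'   regenerated in isolation.
#' @return object of class `dataset_config`.
#' @export
dataset_config <- function(conditions, n_cells = 24L, shape_px = c(256L, 256L),
                           render = render_spec(), seed = 1L) {
  bad <- character(0)
  if (!is.list(conditions) || length(conditions) < 2L ||
      is.null(names(conditions)) || any(names(conditions) == "") ||
      anyDuplicated(names(conditions)) ||
      !all(vapply(conditions, inherits, logical(1), "point_process")))
    bad <- c(bad, "conditions: need a uniquely named list of >= 2 point_process objects")
  if (!is.numeric(n_cells) || n_cells < 2L)
    bad <- c(bad, "n_cells: must be >= 2")
  if (length(shape_px) != 2L || any(shape_px < 64))
    bad <- c(bad, "shape_px: must be two integers >= 64")
  if (!inherits(render, "render_spec"))
    bad <- c(bad, "render: must be a render_spec object")
  if (length(bad)) stop("invalid dataset config:\n  ", paste(bad, collapse = "\n  "))
  structure(list(conditions = conditions, n_cells = as.integer(n_cells),
                 shape_px = as.integer(shape_px), render = render,
                 seed = as.integer(seed)),
            class = "dataset_config")
}

#' Default three-condition study configuration
#'
#' Emulates a ligand-geometry experiment with three conditions: a control
#' with completely random cluster positions, and two conditions whose
#' clusters come in isolated pairs at the short (13.6 nm, below STED
#' resolution) and long (202.3 nm, well resolved) designed spacings.
#'
#' @param n_cells cells per condition.
#' @param shape_px frame size in pixels.
#' @param seed master seed.
#' @param intensity clusters per um^2 for every condition.
#' @return a [dataset_config()].
#' @export
default_study_config <- function(n_cells = 24L, shape_px = c(256L, 256L),
                                 seed = 1L, intensity = 1.2) {
  dataset_config(
    conditions = list(
      control  = point_process("csr", intensity = intensity),
      pairs13  = point_process("fixed_pairs", intensity = intensity,
                               pair_spacing = 13.6),
      pairs200 = point_process("fixed_pairs", intensity = intensity,
                               pair_spacing = 202.3)),
    n_cells = n_cells, shape_px = shape_px,
    render = render_spec(), seed = seed)
}

#' Generate a full synthetic dataset
#'
#' Produces `n_cells` image/mask/ground-truth records per condition, each
#' from a derived per-cell seed, so the whole dataset is a pure function of
#' its configuration.
#'
#' @param config a [dataset_config()].
#' @return object of class `sted_dataset`: a list with `cells` (each a list
#'   with `cell_id`, `condition`, `seed`, `image`, `mask`, `truth`) and the
#'   echoed `config`.
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "dataset_config"))
  cells <- list()
  idx <- 0L
  for (cond in names(config$conditions)) {
    for (cell in seq_len(config$n_cells)) {
      idx <- idx + 1L
      s <- derive_seed(config$seed, idx)
      mask <- make_cell_mask(config$shape_px, config$render$pixel_size, seed = s)
      gt <- sample_cluster_points(config$conditions[[cond]], mask, seed = s + 1L,
                                  fwhm_mean = config$render$fwhm_mean,
                                  fwhm_sd = config$render$fwhm_sd,
                                  fwhm_min = config$render$fwhm_min)
      img <- render_sted_image(gt, config$render, mask, seed = s + 2L)
      cells[[idx]] <- list(cell_id = sprintf("%s_%02d", cond, cell),
                           condition = cond, seed = s,
                           image = img, mask = mask, truth = gt)
    }
  }
  structure(list(cells = cells, config = config), class = "sted_dataset")
}

#' @export
print.sted_dataset <- function(x, ...) {
  conds <- table(vapply(x$cells, `[[`, character(1), "condition"))
  cat(sprintf("<sted_dataset> %d cells (%s); %d x %d px @ %g nm\n",
              length(x$cells),
              paste(sprintf("%s: %d", names(conds), conds), collapse = ", "),
              x$config$shape_px[1L], x$config$shape_px[2L],
              x$config$render$pixel_size))
  invisible(x)
}

#' Write a synthetic dataset to disk
#'
#' Writes one 16-bit TIFF image and one mask TIFF per cell, a pooled
#' ground-truth CSV (`cell_id, condition, x_nm, y_nm, fwhm_nm`), a manifest
#' CSV consumable by [read_manifest()], and a JSON echo of the configuration
#' (including the seed-derivation rule).
#'
#' @param dataset a `sted_dataset`.
#' @param dir output directory (created if missing).
#' @return the manifest path, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "sted_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  px <- dataset$config$render$pixel_size
  rows <- list(); truths <- list()
  for (cell in dataset$cells) {
    ipath <- file.path(dir, paste0(cell$cell_id, ".tif"))
    mpath <- file.path(dir, paste0(cell$cell_id, "_mask.tif"))
    write_sted_tiff(cell$image, ipath)
    write_mask_tiff(cell$mask, mpath)
    rows[[cell$cell_id]] <- data.frame(cell_id = cell$cell_id,
                                       condition = cell$condition,
                                       image = ipath, mask = mpath,
                                       pixel_size_nm = px)
    n <- nrow(cell$truth$points)
    if (n) truths[[cell$cell_id]] <- data.frame(
      cell_id = cell$cell_id, condition = cell$condition,
      x_nm = cell$truth$points[, 1L], y_nm = cell$truth$points[, 2L],
      fwhm_nm = cell$truth$fwhm)
  }
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  utils::write.csv(do.call(rbind, truths), file.path(dir, "ground_truth.csv"),
                   row.names = FALSE)
  cfg <- dataset$config
  echo <- list(conditions = lapply(cfg$conditions, function(p)
                 Filter(Negate(is.null), unclass(p))),
               n_cells = cfg$n_cells, shape_px = cfg$shape_px,
               render = unclass(cfg$render), seed = cfg$seed,
               seed_rule = "per-cell seed = (seed*10007 + index*97) %% (2^31-19) + 1")
  jsonlite::write_json(echo, file.path(dir, "config.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(file.path(dir, "manifest.csv"))
}
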