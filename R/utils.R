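# Internal numerics shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @noRd
trapz <- function(x, y) {
  sum(diff(x) * (utils::head(y, -1L) + utils::tail(y, -1L)) / 2)
}

#' @noRd
cumtrapz <- function(x, y) {
  c(0, cumsum(diff(x) * (utils::head(y, -1L) + utils::tail(y, -1L)) / 2))
}

#' Gaussian blur with reflective boundary handling
#'
#' Pads the matrix by mirror reflection before convolving with a normalized
#' sampled-Gaussian kernel (via EBImage), then crops back. Reflection keeps
#' the total intensity of the interior exactly conserved, which the
#' preprocessing chain relies on. `sigma_px = 0` is the identity.
#'
#' @param m numeric matrix.
#' @param sigma_px kernel standard deviation in pixels.
#' @return blurred matrix of the same dimension.
#' @noRd
blur_gaussian <- function(m, sigma_px) {
  if (sigma_px <= 0) return(m)
  hw <- as.integer(ceiling(3 * sigma_px)) + 1L
  hw <- min(hw, nrow(m) - 1L, ncol(m) - 1L)
  ri <- c(seq(hw, 1L), seq_len(nrow(m)), seq(nrow(m), nrow(m) - hw + 1L))
  ci <- c(seq(hw, 1L), seq_len(ncol(m)), seq(ncol(m), ncol(m) - hw + 1L))
  padded <- m[ri, ci]
  sm <- EBImage::imageData(EBImage::gblur(padded, sigma = sigma_px,
                                          radius = 2L * hw + 1L))
  sm[(hw + 1L):(hw + nrow(m)), (hw + 1L):(hw + ncol(m))]
}

#' Local maxima of a matrix with plateau merging
#'
#' A pixel is a candidate when its value is >= each of its 8 neighbours and
#' above `threshold`. Touching candidates (8-connectivity) necessarily share
#' one value and are merged into a single peak at their intensity-weighted
#' centroid. A candidate region only counts as a peak when at least one pixel
#' just outside it is strictly smaller, so a constant image has no peaks.
#'
#' @param m numeric matrix.
#' @param threshold minimum peak value.
#' @param mask optional logical matrix restricting candidates.
#' @return data.frame with fractional matrix indices `i`, `j` (centroids) and
#'   the peak `value`.
#' @noRd
find_peaks <- function(m, threshold = -Inf, mask = NULL) {
  nr <- nrow(m); nc <- ncol(m)
  pad <- matrix(-Inf, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- m
  cand <- matrix(TRUE, nr, nc)
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0L && dj == 0L) next
    cand <- cand & (m >= pad[(2:(nr + 1L)) + di, (2:(nc + 1L)) + dj])
  }
  cand <- cand & (m > threshold)
  if (!is.null(mask)) cand <- cand & mask
  if (!any(cand)) {
    return(data.frame(i = numeric(0), j = numeric(0), value = numeric(0)))
  }
  lab <- EBImage::imageData(EBImage::bwlabel(cand))
  nlab <- max(lab)
  out <- vector("list", nlab)
  for (l in seq_len(nlab)) {
    idx <- which(lab == l, arr.ind = TRUE)
    v <- m[idx]
    # exterior strictness: some neighbour outside the plateau must be smaller
    ext_smaller <- FALSE
    for (p in seq_len(nrow(idx))) {
      ii <- idx[p, 1L]; jj <- idx[p, 2L]
      nb <- pad[(ii + 1L) + (-1:1), (jj + 1L) + (-1:1)]
      if (any(nb[is.finite(nb)] < v[1L])) { ext_smaller <- TRUE; break }
    }
    if (!ext_smaller) next
    w <- v / sum(v)
    out[[l]] <- c(sum(w * idx[, 1L]), sum(w * idx[, 2L]), max(v))
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out)) {
    return(data.frame(i = numeric(0), j = numeric(0), value = numeric(0)))
  }
  res <- do.call(rbind, out)
  data.frame(i = res[, 1L], j = res[, 2L], value = res[, 3L])
}

# Deterministic per-cell seed derived from a master seed; kept below 2^31.
#' @noRd
derive_seed <- function(master, index) {
  as.integer((as.double(master) * 10007 + as.double(index) * 97) %% 2147483629) + 1L
}
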