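#' STED image container
#'
#' A `sted_image` couples a 2D non-negative intensity matrix (photon counts)
#' with its physical pixel size in nanometers. Rows index y, columns index x;
#' the center of pixel `[i, j]` sits at `((j - 0.5), (i - 0.5)) * pixel_size`
#' nm, so all downstream coordinates live in a continuous nm plane with the
#' origin at the image corner.
#'
#' @param pixels numeric matrix of intensities (counts); must be finite and
#'   non-negative.
#' @param pixel_size physical pixel size in nm (typical STED: 20-25 nm).
#' @return an object of class `sted_image` with fields `pixels` and
#'   `pixel_size`.
#' @examples
#' img <- sted_image(matrix(rpois(64 * 64, 5), 64), pixel_size = 20)
#' img
#' @export
sted_image <- function(pixels, pixel_size) {
  if (!is.matrix(pixels) || !is.numeric(pixels))
    stop("'pixels' must be a numeric matrix")
  if (any(!is.finite(pixels))) stop("'pixels' must be finite")
  if (!is.numeric(pixel_size) || length(pixel_size) != 1L || pixel_size <= 0)
    stop("'pixel_size' must be a single positive number (nm)")
  structure(list(pixels = pixels, pixel_size = as.numeric(pixel_size)),
            class = "sted_image")
}

#' @export
print.sted_image <- function(x, ...) {
  cat(sprintf("<sted_image> %d x %d px @ %.3g nm/px (%.2f x %.2f um), range [%.3g, %.3g]\n",
              nrow(x$pixels), ncol(x$pixels), x$pixel_size,
              ncol(x$pixels) * x$pixel_size / 1e3,
              nrow(x$pixels) * x$pixel_size / 1e3,
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' @export
dim.sted_image <- function(x) dim(x$pixels)

#' Binary cell mask
#'
#' Logical matrix marking in-cell pixels, carrying the pixel size so areas
#' and coordinates can be expressed in physical units.
#'
#' @param mask logical matrix (TRUE = inside the cell).
#' @param pixel_size pixel size in nm.
#' @return object of class `cell_mask` (a logical matrix with a `pixel_size`
#'   attribute).
#' @export
cell_mask <- function(mask, pixel_size) {
  if (!is.matrix(mask) || !is.logical(mask)) stop("'mask' must be a logical matrix")
  if (pixel_size <= 0) stop("'pixel_size' must be positive")
  structure(mask, pixel_size = as.numeric(pixel_size),
            class = c("cell_mask", "matrix"))
}

#' @export
print.cell_mask <- function(x, ...) {
  cat(sprintf("<cell_mask> %d x %d px @ %.3g nm/px, area %.2f um^2 (%.1f%% of frame)\n",
              nrow(x), ncol(x), attr(x, "pixel_size"),
              sum(x) * attr(x, "pixel_size")^2 / 1e6, 100 * mean(x)))
  invisible(x)
}

#' Area of a cell mask in square micrometers
#' @param mask a [cell_mask()].
#' @return area in um^2.
#' @export
mask_area_um2 <- function(mask) {
  px <- attr(mask, "pixel_size")
  sum(mask) * px^2 / 1e6
}

#' Read and write STED images as TIFF
#'
#' Images are stored as single-channel 16-bit TIFF; intensities are photon
#' counts in `[0, 65535]`. Masks use the same container with values 0/1.
#'
#' @param path file path.
#' @param pixel_size pixel size in nm (TIFF files do not carry it reliably,
#'   so it is supplied by the manifest or caller).
#' @return `read_sted_tiff` returns a [sted_image()]; `read_mask_tiff` a
#'   [cell_mask()].
#' @export
read_sted_tiff <- function(path, pixel_size) {
  a <- tiff::readTIFF(path, as.is = TRUE)
  if (length(dim(a)) == 3L) a <- a[, , 1L]
  sted_image(a * 1.0, pixel_size)
}

#' @param img a [sted_image()] to write.
#' @rdname read_sted_tiff
#' @export
write_sted_tiff <- function(img, path) {
  v <- pmax(pmin(img$pixels, 65535), 0)
  tiff::writeTIFF(v / 65535, path, bits.per.sample = 16L)
  invisible(path)
}

#' @rdname read_sted_tiff
#' @export
read_mask_tiff <- function(path, pixel_size) {
  a <- tiff::readTIFF(path, as.is = TRUE)
  if (length(dim(a)) == 3L) a <- a[, , 1L]
  cell_mask(a > 0, pixel_size)
}

#' @param mask a [cell_mask()] to write.
#' @rdname read_sted_tiff
#' @export
write_mask_tiff <- function(mask, path) {
  tiff::writeTIFF(matrix(as.numeric(mask), nrow(mask)), path,
                  bits.per.sample = 8L)
  invisible(path)
}
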