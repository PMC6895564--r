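#' Construct a grayscale image
#'
#' A `gray_image` is an integer matrix of intensities in `[0, 255]` with an
#' optional physical scale (microns per pixel) attached as an attribute.
#' Fluorescence values are never rescaled anywhere in the pipeline; images are
#' carried exactly as acquired.
#'
#' @param pixels numeric or integer matrix, values in `[0, 255]`, integral.
#' @param scale optional microns-per-pixel factor, `> 0`.
#' @return an integer matrix of class `gray_image` with attribute
#'   `microns_per_pixel` (may be `NULL`).
#' @export
gray_image <- function(pixels, scale = NULL) {
  if (!is.matrix(pixels)) stop("pixels must be a matrix")
  if (nrow(pixels) < 1L || ncol(pixels) < 1L) stop("image must be at least 1x1")
  if (anyNA(pixels)) stop("pixels must not contain NA")
  if (any(pixels < 0 | pixels > 255)) stop("intensities must lie in [0, 255]")
  if (any(pixels != round(pixels))) stop("intensities must be integer-valued")
  px <- matrix(as.integer(pixels), nrow(pixels), ncol(pixels))
  if (!is.null(scale)) {
    if (!is.numeric(scale) || length(scale) != 1L || scale <= 0)
      stop("scale (microns per pixel) must be a single positive number")
    attr(px, "microns_per_pixel") <- as.numeric(scale)
  }
  class(px) <- c("gray_image", class(px))
  px
}

#' @export
print.gray_image <- function(x, ...) {
  sc <- attr(x, "microns_per_pixel")
  cat(sprintf("<gray_image %d x %d px%s>\n", nrow(x), ncol(x),
              if (is.null(sc)) "" else sprintf(", %.4g um/px", sc)))
  invisible(x)
}

img_scale <- function(img) attr(img, "microns_per_pixel")

#' Read an 8-bit grayscale TIFF
#'
#' Intensities are read as stored, with no rescaling or normalisation: all
#' downstream fluorescence measurements are taken on unaltered images.
#' Multi-channel or deeper-than-8-bit files are rejected unless `coerce` is
#' set, in which case the first channel is taken and values are truncated to
#' 8 bits.
#'
#' @param path file path.
#' @param scale optional microns-per-pixel factor to attach.
#' @param coerce allow lossy coercion of multi-channel / >8-bit input.
#' @return a [gray_image()].
#' @export
read_gray_tiff <- function(path, scale = NULL, coerce = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- tiff::readTIFF(path, as.is = TRUE)
  if (length(dim(raw)) == 3L) {
    if (!coerce) stop("multi-channel TIFF; pass coerce = TRUE to take channel 1")
    raw <- raw[, , 1L]
    # multi-channel reads may come back rescaled to [0, 1]
    if (max(raw) <= 1 && any(raw != round(raw))) raw <- round(raw * 255)
  }
  if (max(raw) > 255L) {
    if (!coerce) stop(">8-bit TIFF; pass coerce = TRUE to truncate to 8 bits")
    raw <- pmin(raw, 255L)
  }
  gray_image(raw, scale = scale)
}

#' Write an 8-bit grayscale TIFF
#'
#' Uncompressed, single channel. Writing the result of [read_gray_tiff()] on a
#' file produced by this function reproduces that file byte for byte.
#'
#' @param img a [gray_image()] (or 0-255 integer matrix).
#' @param path output path.
#' @export
write_gray_tiff <- function(img, path) {
  m <- unclass(img)
  attr(m, "microns_per_pixel") <- NULL
  tiff::writeTIFF(m / 255, path, bits.per.sample = 8L, compression = "none")
  invisible(path)
}

#' Read / write label masks as 16-bit TIFF
#'
#' Region ids up to 65535 are stored losslessly.
#' @param labels integer matrix of non-negative region ids.
#' @param path file path.
#' @export
write_label_tiff <- function(labels, path) {
  if (any(labels < 0) || max(labels) > 65535L)
    stop("label ids must lie in [0, 65535]")
  tiff::writeTIFF(labels / 65535, path, bits.per.sample = 16L, compression = "none")
  invisible(path)
}

#' @rdname write_label_tiff
#' @export
read_label_tiff <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- tiff::readTIFF(path, as.is = TRUE)
  if (length(dim(raw)) == 3L) stop("label TIFF must be single channel")
  matrix(as.integer(raw), nrow(raw), ncol(raw))
}

#' Binarize an image at a threshold
#'
#' Foreground (value 1) is every pixel with intensity greater than or equal to
#' the threshold. Under this convention the stained boundary network is the
#' foreground, and lowering the threshold thickens the boundary.
#'
#' @param img a [gray_image()] or intensity matrix.
#' @param threshold intensity in `[0, 255]`.
#' @return integer matrix of 0/1.
#' @export
binarize <- function(img, threshold) {
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold < 0 || threshold > 255)
    stop("threshold must be a single value in [0, 255]")
  m <- unclass(img)
  out <- matrix(0L, nrow(m), ncol(m))
  out[m >= threshold] <- 1L
  out
}

#' Label connected regions of a binary mask
#'
#' Deterministic connected-component labeling: region ids are assigned in
#' row-major order of each region's first pixel, forming the contiguous set
#' `1..K` (0 = background). Interior regions are labeled with 4-connectivity so
#' that an 8-connected one-pixel boundary chain separates them; boundary
#' analyses use 8-connectivity.
#'
#' @param mask matrix; non-zero entries are foreground.
#' @param connectivity 4 or 8.
#' @return integer label matrix.
#' @export
label_regions <- function(mask, connectivity = 4L) {
  if (!connectivity %in% c(4L, 8L)) stop("connectivity must be 4 or 8")
  m <- matrix(as.integer(unclass(mask) != 0), nrow(mask), ncol(mask))
  label_cc_int(m, as.integer(connectivity))
}
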