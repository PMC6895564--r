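# rotating calipers on a convex hull: min over edges of the max perpendicular
# vertex distance from that edge
calipers_min_width <- function(hull) {
  n <- nrow(hull)
  if (n < 3L) return(0)
  best <- Inf
  for (i in seq_len(n)) {
    a <- hull[i, ]; b <- hull[if (i == n) 1L else i + 1L, ]
    e <- b - a
    len <- sqrt(sum(e^2))
    if (len == 0) next
    d <- abs((hull[, 1] - a[1]) * e[2] - (hull[, 2] - a[2]) * e[1]) / len
    best <- min(best, max(d))
  }
  best
}

# sub-pixel object outline: 0.5-level marching-squares contour of the
# 3x3-box-smoothed binary mask. For a straight edge of any orientation the
# half-coverage crossing of the box filter sits on the edge itself, so
# staircase quantization largely cancels; returns NULL for regions too small
# or thin to carry a half-coverage contour.
smoothed_outline <- function(coords) {
  r0 <- min(coords[, 1]); c0 <- min(coords[, 2])
  k <- 1L
  nr <- max(coords[, 1]) - r0 + 1L + 2L * (k + 1L)
  nc <- max(coords[, 2]) - c0 + 1L + 2L * (k + 1L)
  m <- matrix(0, nr, nc)
  m[cbind(coords[, 1] - r0 + k + 2L, coords[, 2] - c0 + k + 2L)] <- 1
  cum <- matrix(0, nr + 1L, nc + 1L)
  cum[-1, -1] <- t(apply(apply(m, 2, cumsum), 1, cumsum))
  w <- 2L * k + 1L
  S <- (cum[(w + 1):(nr + 1), (w + 1):(nc + 1)] -
        cum[1:(nr - w + 1), (w + 1):(nc + 1)] -
        cum[(w + 1):(nr + 1), 1:(nc - w + 1)] +
        cum[1:(nr - w + 1), 1:(nc - w + 1)]) / w^2
  Sf <- matrix(0, nr, nc)
  Sf[(k + 1):(nr - k), (k + 1):(nc - k)] <- S
  cl <- grDevices::contourLines(seq_len(nr), seq_len(nc), Sf, levels = 0.5)
  if (length(cl) == 0L) return(NULL)
  cbind(unlist(lapply(cl, `[[`, "x")), unlist(lapply(cl, `[[`, "y")))
}

#' Minimum Feret diameter of an ROI
#'
#' Smallest caliper width of the region over all orientations (rotating
#' calipers on a convex hull). The hull is taken over the sub-pixel object
#' outline (half-coverage contour of the box-smoothed mask), which removes the
#' orientation-dependent staircase bias of raw rasterization: an axis-aligned
#' w-pixel-wide rectangle measures exactly w and the same rectangle rotated
#' 45 degrees measures within raster quantization (about 0.6 px) of w.
#' Regions too small or thin to carry a half-coverage outline (single pixels,
#' one-pixel-wide lines) fall back to the hull of their pixel corners, so a
#' one-pixel region measures 1 (pixel-width convention).
#'
#' @param roi an `roi` from [extract_rois()].
#' @return minimum Feret diameter in pixels.
#' @export
min_feret <- function(roi) {
  out <- smoothed_outline(roi$coords)
  if (!is.null(out)) {
    h <- grDevices::chull(out[, 1], out[, 2])
    return(calipers_min_width(out[h, , drop = FALSE]))
  }
  calipers_min_width(roi_corner_hull(roi$coords))
}

#' Convert per-fiber pixel measurements to physical units
#'
#' Populates `area_um2 = area_px * scale^2` and
#' `min_feret_um = min_feret_px * scale`, where `scale` is microns per pixel
#' (named explicitly to avoid the px-per-um / um-per-px ambiguity).
#'
#' @param records data.frame with `area_px` and `min_feret_px` columns.
#' @param microns_per_pixel physical scale, `> 0`.
#' @return the records with `area_um2` and `min_feret_um` filled in.
#' @export
to_physical <- function(records, microns_per_pixel) {
  if (is.null(microns_per_pixel) || !is.numeric(microns_per_pixel) ||
      length(microns_per_pixel) != 1L || is.na(microns_per_pixel) ||
      microns_per_pixel <= 0)
    stop("microns_per_pixel must be a single positive number")
  records$area_um2 <- records$area_px * microns_per_pixel^2
  records$min_feret_um <- records$min_feret_px * microns_per_pixel
  records
}

record_columns <- function(channels = character(0)) {
  c("roi_id", "area_px", "area_um2", "min_feret_px", "min_feret_um", "cnf",
    if (length(channels)) paste0("mfi_", channels),
    if (length(channels)) paste0("pos_", channels),
    "fiber_type")
}

#' Export per-fiber records to CSV
#'
#' Fixed column order
#' `roi_id, area_px, area_um2, min_feret_px, min_feret_um, cnf, mfi_<ch>...,
#' pos_<ch>..., fiber_type`. Numeric fields are written with 17 significant
#' digits so that re-importing with [read_records()] reproduces the records
#' exactly, including double-precision MFIs.
#'
#' @param records data.frame of per-fiber records.
#' @param path output path.
#' @export
export_records <- function(records, path) {
  channels <- sub("^mfi_", "", grep("^mfi_", names(records), value = TRUE))
  cols <- record_columns(channels)
  missing <- setdiff(cols, names(records))
  for (m in missing) records[[m]] <- NA
  records <- records[, cols, drop = FALSE]
  fmt <- records
  for (cl in names(fmt)) {
    v <- fmt[[cl]]
    if (is.double(v)) {
      s <- sprintf("%.17g", v)
      s[is.na(v)] <- NA
      fmt[[cl]] <- s
    }
  }
  write.csv(fmt, path, row.names = FALSE, quote = FALSE, na = "NA")
  invisible(path)
}

#' @rdname export_records
#' @export
read_records <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  rec <- read.csv(path)
  for (cl in grep("^(cnf|pos_)", names(rec), value = TRUE))
    rec[[cl]] <- as.logical(rec[[cl]])
  rec
}

#' Assemble per-fiber records
#'
#' Joins the outputs of the segmentation, classification, CNF, and
#' fluorescence stages into one exportable table (myofiber-class ROIs only).
#'
#' @param rois list of `roi` objects.
#' @param labels named classification vector from [classify_rois()].
#' @param cnf optional data.frame from [detect_cnf()].
#' @param fluor optional named list per channel, each element a list with
#'   `mfi` (named vector) and `positive` (named logical).
#' @param fiber_type optional character vector named by ROI id.
#' @param microns_per_pixel optional physical scale; when `NULL` the unit
#'   fields are `NA`.
#' @return data.frame of per-fiber records.
#' @export
fiber_records <- function(rois, labels, cnf = NULL, fluor = NULL,
                          fiber_type = NULL, microns_per_pixel = NULL) {
  ids <- vapply(rois, function(r) r$id, 0L)
  keep <- labels[as.character(ids)] == "myofiber"
  rois <- rois[keep]
  ids <- ids[keep]
  rec <- data.frame(
    roi_id = ids,
    area_px = vapply(rois, function(r) nrow(r$coords), 0L),
    min_feret_px = vapply(rois, min_feret, 0)
  )
  rec$cnf <- if (is.null(cnf)) NA else cnf$cnf[match(ids, cnf$roi_id)]
  if (!is.null(fluor)) {
    for (ch in names(fluor)) {
      rec[[paste0("mfi_", ch)]] <- unname(fluor[[ch]]$mfi[as.character(ids)])
      p <- fluor[[ch]]$positive
      rec[[paste0("pos_", ch)]] <- if (is.null(p)) NA else
        unname(p[as.character(ids)])
    }
  }
  rec$fiber_type <- if (is.null(fiber_type)) NA_character_ else
    unname(fiber_type[as.character(ids)])
  if (!is.null(microns_per_pixel)) {
    rec <- to_physical(rec, microns_per_pixel)
  } else {
    rec$area_um2 <- NA_real_
    rec$min_feret_um <- NA_real_
  }
  rec[, record_columns(names(fluor))]
}

#' Measurement accuracy against a manual reference
#'
#' `(1 - |test - manual| / manual) * 100`, in percent. Symmetric in the
#' direction of the error and never above 100.
#'
#' @param test_value value produced by the automated method.
#' @param manual_value manually measured reference, `> 0`.
#' @return accuracy in percent.
#' @export
accuracy <- function(test_value, manual_value) {
  if (any(manual_value <= 0)) stop("manual_value must be > 0")
  (1 - abs(test_value - manual_value) / manual_value) * 100
}

#' Coefficient of variation
#'
#' Sample standard deviation (n - 1 denominator) over the mean, in percent.
#'
#' @param values numeric vector, at least 2 values, non-zero mean.
#' @return CV in percent.
#' @export
cv <- function(values) {
  if (length(values) < 2L) stop("cv needs at least 2 values")
  m <- mean(values)
  if (m == 0) stop("cv undefined for zero mean")
  sd(values) / m * 100
}
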