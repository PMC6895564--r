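#' Erode an ROI to a target fraction of its area
#'
#' Repeated one-pixel morphological erosion (4-connected, 3x3 diamond
#' structuring element) until the remaining area is at most
#' `(1 - erosion_percent/100)` of the original. The first iterate at or below
#' the target is returned, even when it undershoots; `erosion_percent = 0`
#' returns the ROI unchanged. Because the amount removed is a percentage of
#' area, the erosion depth scales with fiber cross-sectional size, which is
#' what lets small regenerating fibers be evaluated with the same setting as
#' large ones. Very small fibers can erode to nothing; the result then carries
#' `attr(, "core_empty") = TRUE` and the fiber is never called centrally
#' nucleated.
#'
#' @param roi an `roi` from [extract_rois()].
#' @param erosion_percent integer in `[0, 99]`; default 80.
#' @return (row, col) coordinate matrix of the eroded core, with attribute
#'   `core_empty`.
#' @export
erode_to_fraction <- function(roi, erosion_percent = 80L) {
  if (erosion_percent < 0 || erosion_percent > 99)
    stop("erosion_percent must lie in [0, 99]")
  co <- roi$coords
  if (nrow(co) == 0L) stop("roi must be non-empty")
  if (erosion_percent == 0L) {
    attr(co, "core_empty") <- FALSE
    return(co)
  }
  target <- (1 - erosion_percent / 100) * nrow(co)
  r0 <- min(co[, 1]); c0 <- min(co[, 2])
  m <- matrix(0L, max(co[, 1]) - r0 + 3L, max(co[, 2]) - c0 + 3L)
  m[cbind(co[, 1] - r0 + 2L, co[, 2] - c0 + 2L)] <- 1L
  kern <- EBImage::makeBrush(3L, shape = "diamond")
  repeat {
    m <- round(EBImage::erode(m, kern))
    a <- sum(m)
    if (a <= target) break
  }
  idx <- which(m == 1L, arr.ind = TRUE)
  out <- cbind(row = idx[, 1] + r0 - 2L, col = idx[, 2] + c0 - 2L)
  attr(out, "core_empty") <- nrow(out) == 0L
  out
}

#' Detect centrally nucleated fibers
#'
#' A myofiber is centrally nucleated when, after eroding its area by
#' `erosion_percent`, at least one nuclear-channel-positive pixel remains
#' inside the eroded core. Erosion excludes peripheral nuclei from the test;
#' only ROIs classified as myofibers are evaluated.
#'
#' @param rois list of `roi` objects.
#' @param labels named character vector from [classify_rois()] (names = ROI
#'   ids).
#' @param dapi binarized nuclear channel (0/1 matrix of the section's shape),
#'   or a [gray_image()] together with `dapi_threshold`.
#' @param erosion_percent integer in `[0, 99]`; default 80.
#' @param dapi_threshold optional intensity threshold applied to `dapi` when
#'   it is not already binary.
#' @return data.frame with columns `roi_id`, `is_myofiber`, `cnf` (logical,
#'   `NA` for non-myofibers), `core_empty`.
#' @export
detect_cnf <- function(rois, labels, dapi, erosion_percent = 80L,
                       dapi_threshold = NULL) {
  if (!is.null(dapi_threshold)) dapi <- binarize(dapi, dapi_threshold)
  dapi <- unclass(dapi)
  if (length(rois) > 0L && !all(dim(dapi) == rois[[1]]$dim))
    stop("nuclear channel shape does not match the section")
  ids <- vapply(rois, function(r) r$id, 0L)
  myo <- unname(labels[as.character(ids)] == "myofiber")
  cnf <- rep(NA, length(rois))
  core_empty <- rep(NA, length(rois))
  for (i in seq_along(rois)) {
    if (!isTRUE(myo[i])) next
    core <- erode_to_fraction(rois[[i]], erosion_percent)
    if (isTRUE(attr(core, "core_empty"))) {
      core_empty[i] <- TRUE
      cnf[i] <- FALSE
    } else {
      core_empty[i] <- FALSE
      cnf[i] <- any(dapi[core] != 0)
    }
  }
  data.frame(roi_id = ids, is_myofiber = myo, cnf = cnf,
             core_empty = core_empty)
}
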