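#' Per-fiber mean fluorescence intensity
#'
#' The MFI of a fiber is the arithmetic mean of the marker-channel intensity
#' over all of its member pixels, taken on the unaltered 8-bit image.
#'
#' @param rois list of `roi` objects.
#' @param channel a [gray_image()] marker channel of the section's shape.
#' @return numeric vector of MFIs, named by ROI id.
#' @export
measure_mfi <- function(rois, channel) {
  ch <- unclass(channel)
  if (length(rois) > 0L && !all(dim(ch) == rois[[1]]$dim))
    stop("marker channel shape does not match the section")
  out <- vapply(rois, function(r) mean(ch[r$coords]), 0)
  names(out) <- vapply(rois, function(r) r$id, 0L)
  out
}

#' Call marker-positive fibers from seed fibers
#'
#' The user designates the dimmest fibers that are still unambiguously
#' positive; the minimum of their MFIs becomes the channel threshold, and
#' every fiber with MFI greater than or equal to it is called positive. Every
#' seed is therefore positive, and recomputing with the current positive set
#' as seeds leaves the call unchanged.
#'
#' @param mfis named numeric vector from [measure_mfi()].
#' @param seed_ids ids of the designated dimmest-positive fibers (non-empty).
#' @return list with `threshold` (intensity used) and `positive` (named
#'   logical vector over all fibers).
#' @export
call_positive <- function(mfis, seed_ids) {
  if (length(seed_ids) == 0L) stop("seed fiber set must be non-empty")
  key <- as.character(seed_ids)
  if (!all(key %in% names(mfis))) stop("unknown seed fiber id")
  thr <- min(mfis[key])
  list(threshold = thr, positive = mfis >= thr)
}

#' Assign fiber types from per-channel positivity
#'
#' Single-positive fibers take the type of their channel; fibers positive on
#' two or more channels are hybrids (co-expression of multiple myosin
#' heavy-chain isoforms); fibers negative on every channel are type IIx under
#' the mouse convention (IIx has no stained isoform in the standard three-
#' antibody panel) or `unassigned` in generic mode.
#'
#' @param positive logical matrix or data.frame, one row per fiber, one column
#'   per typed channel (e.g. `I`, `IIa`, `IIb`); row order defines the fiber
#'   order of the result.
#' @param mode `"mouse"` (all-negative = IIx) or `"generic"` (all-negative =
#'   unassigned).
#' @return character vector of assignments, one per fiber.
#' @export
type_fibers <- function(positive, mode = c("mouse", "generic")) {
  mode <- match.arg(mode)
  pm <- as.matrix(positive)
  if (anyNA(pm)) stop("positivity calls must be complete over the fiber set")
  n_pos <- rowSums(pm)
  out <- character(nrow(pm))
  out[n_pos >= 2L] <- "hybrid"
  single <- which(n_pos == 1L)
  out[single] <- colnames(pm)[apply(pm[single, , drop = FALSE], 1, which.max)]
  out[n_pos == 0L] <- if (mode == "mouse") "IIx" else "unassigned"
  out
}
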