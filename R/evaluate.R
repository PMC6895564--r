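#' Match segmented regions to ground-truth fibers
#'
#' For every ground-truth fiber of a phantom, finds the segmented region with
#' the largest pixel overlap and reports the intersection-over-union. A fiber
#' is recovered one-to-one when its best region's best fiber is itself and the
#' IoU exceeds the cutoff; fibers whose best region is shared with another
#' fiber are merged.
#'
#' @param seg integer label matrix (e.g. `fill_gaps(...)$segmented` or
#'   [naive_segment()]).
#' @param phantom a [make_phantom()] result.
#' @param iou IoU cutoff for one-to-one recovery (default 0.7).
#' @return list with `per_fiber` (data.frame: `fiber_id`, `region`, `iou`,
#'   `recovered`), `recovered_fraction`, and `n_merged` (ground-truth fibers
#'   whose best region also best-matches another fiber).
#' @export
fiber_recovery <- function(seg, phantom, iou = 0.7) {
  stopifnot(inherits(phantom, "phantom"))
  gt <- phantom$truth$labels
  nf <- phantom$truth$n_fibers
  k <- max(seg)
  both <- gt > 0L & gt <= nf & seg > 0L
  gtv <- gt[both]; sgv <- seg[both]
  key <- (as.numeric(gtv) - 1) * k + sgv
  cnt <- table(key)
  kk <- as.numeric(names(cnt))
  fid <- floor((kk - 1) / k) + 1
  rid <- kk - (fid - 1) * k
  ov <- as.numeric(cnt)
  a_gt <- tabulate(gt[gt > 0L & gt <= nf], nbins = nf)
  a_seg <- tabulate(seg[seg > 0L], nbins = k)
  # best region per fiber
  best <- rep(NA_integer_, nf)
  best_ov <- rep(0, nf)
  o <- order(fid, -ov)
  first <- !duplicated(fid[o])
  best[fid[o][first]] <- rid[o][first]
  best_ov[fid[o][first]] <- ov[o][first]
  iou_v <- best_ov / (a_gt + a_seg[pmax(best, 1L)] - best_ov)
  iou_v[is.na(best)] <- 0
  claimed <- table(best[!is.na(best)])
  shared <- as.integer(names(claimed)[claimed > 1L])
  recovered <- !is.na(best) & iou_v > iou & !(best %in% shared)
  list(per_fiber = data.frame(fiber_id = seq_len(nf), region = best,
                              iou = iou_v, recovered = recovered),
       recovered_fraction = mean(recovered),
       n_merged = sum(best %in% shared, na.rm = TRUE))
}

#' Ground-truth class labels for segmented ROIs
#'
#' Assigns each segmented ROI the phantom's ground-truth class by majority
#' pixel vote: `myofiber` when most of its pixels lie on a ground-truth fiber,
#' `non_myofiber` otherwise. Used to build training/evaluation labels without
#' interactive annotation.
#'
#' @param rois list of `roi` objects from [extract_rois()].
#' @param phantom a [make_phantom()] result.
#' @return data.frame with `roi_id` and `label`.
#' @export
truth_roi_classes <- function(rois, phantom) {
  stopifnot(inherits(phantom, "phantom"))
  gt <- phantom$truth$labels
  nf <- phantom$truth$n_fibers
  lab <- vapply(rois, function(r) {
    v <- gt[r$coords]
    mean(v > 0L & v <= nf) > 0.5
  }, TRUE)
  data.frame(roi_id = vapply(rois, function(r) r$id, 0L),
             label = ifelse(lab, "myofiber", "non_myofiber"))
}
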