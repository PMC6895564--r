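#' Gap-filling configuration
#'
#' Parameters of the boundary gap-filling segmentation. The two thresholds
#' bracket the stain-intensity range over which the boundary network thins:
#' the thick end produces the thickest plausible boundary (smallest candidate
#' fiber interiors, used as tracking seeds) and the thin end the thinnest.
#' Under the >=-foreground convention the thick end is the numerically lower
#' threshold; [fill_gaps()] derives the ordering from boundary pixel counts
#' rather than trusting the argument order.
#'
#' @param thick_threshold intensity endpoint giving the thickest boundary.
#' @param thin_threshold intensity endpoint giving the thinnest boundary.
#' @param n_steps number of evenly spaced thresholds in the series (>= 2).
#' @param expansion_ratio fractional area increase above which a tracked
#'   region is considered to have escaped through a stain gap (default 0.20).
#' @param min_track_area regions smaller than this (in pixels) are allowed to
#'   grow freely; small seeds legitimately grow fast and the guard avoids
#'   freezing noise specks (default 50).
#' @return a list of class `gapfill_config`.
#' @export
gap_fill_config <- function(thick_threshold, thin_threshold, n_steps = 10L,
                            expansion_ratio = 0.20, min_track_area = 50L) {
  stopifnot(is.numeric(thick_threshold), is.numeric(thin_threshold),
            thick_threshold >= 0, thick_threshold <= 255,
            thin_threshold >= 0, thin_threshold <= 255)
  if (n_steps < 2L) stop("n_steps must be >= 2")
  if (thick_threshold == thin_threshold)
    stop("thresholds must differ when n_steps > 1")
  if (expansion_ratio <= 0) stop("expansion_ratio must be > 0")
  structure(list(thick_threshold = thick_threshold,
                 thin_threshold = thin_threshold,
                 n_steps = as.integer(n_steps),
                 expansion_ratio = expansion_ratio,
                 min_track_area = as.integer(min_track_area)),
            class = "gapfill_config")
}

#' Evenly spaced threshold series
#'
#' @param from,to intensity endpoints (both included).
#' @param n_steps number of values; `n_steps = 1` requires equal endpoints.
#' @return numeric vector of `n_steps` evenly spaced intensities.
#' @export
threshold_series <- function(from, to, n_steps) {
  if (n_steps < 1L) stop("n_steps must be >= 1")
  if (n_steps == 1L) {
    if (from != to) stop("a single-step series requires equal endpoints")
    return(from)
  }
  if (from == to) stop("equal endpoints with n_steps > 1")
  seq(from, to, length.out = n_steps)
}

#' Boundary pixel counts over candidate thresholds
#'
#' Dry-run helper for choosing the two endpoints of a [gap_fill_config()]:
#' reports how many pixels would be boundary at each candidate threshold.
#'
#' @param img a [gray_image()].
#' @param thresholds candidate intensities.
#' @return data.frame with columns `threshold`, `boundary_px`.
#' @export
threshold_preview <- function(img, thresholds) {
  m <- unclass(img)
  data.frame(threshold = thresholds,
             boundary_px = vapply(thresholds, function(t) sum(m >= t), 0))
}

# 8-neighborhood of pixel indices (column-major, 1-based), bounds-clipped
nbr8 <- function(idx, nr, nc) {
  r <- ((idx - 1L) %% nr) + 1L
  cc <- ((idx - 1L) %/% nr) + 1L
  out <- vector("list", 8L)
  k <- 0L
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0L && dc == 0L) next
    rr <- r + dr; c2 <- cc + dc
    ok <- rr >= 1L & rr <= nr & c2 >= 1L & c2 <= nc
    k <- k + 1L
    out[[k]] <- (c2[ok] - 1L) * nr + rr[ok]
  }
  unique(unlist(out))
}

# relabel an id raster to contiguous 1..K by row-major first-pixel order
relabel_rowmajor <- function(ids, nr, nc) {
  pos <- which(ids > 0L)
  if (length(pos) == 0L) return(matrix(0L, nr, nc))
  r <- ((pos - 1L) %% nr)
  cc <- ((pos - 1L) %/% nr)
  rowmaj <- r * nc + cc
  firsts <- tapply(rowmaj, ids[pos], min)
  old <- as.integer(names(firsts))
  newid <- integer(max(old))
  newid[old[order(firsts)]] <- seq_along(old)
  out <- matrix(0L, nr, nc)
  out[pos] <- newid[ids[pos]]
  out
}

#' Segment candidate fibers with boundary gap filling
#'
#' Implements the threshold-series region-tracking algorithm. An evenly spaced
#' series of binarization thresholds runs from the thickest-boundary setting
#' to the thinnest. Candidate-fiber interiors at the thickest setting seed the
#' tracking; at each subsequent (thinner-boundary) step every tracked region
#' is located inside the interior region that now contains it and either
#' grows to it, or — if the containing region's area exceeds the tracked area
#' by more than `expansion_ratio` (and the tracked region is at least
#' `min_track_area` pixels) — is frozen at its prior extent while a "white
#' filler" is written into the leak: the pixels of the expansion that touch
#' the prior region's border (8-connectivity). Filler is permanent boundary
#' for all later steps. If two tracked regions come to share one interior
#' region (a gap between two fibers has opened), both are frozen and filler
#' seals each of them. Expansion pixels beyond the filler are released and
#' re-tracked as separate regions, as are interior regions that appear at
#' later steps without containing any seed.
#'
#' @param img a [gray_image()] of the boundary (laminin) channel.
#' @param cfg a [gap_fill_config()].
#' @return a list of class `gapfill_result` with elements `segmented` (label
#'   matrix of final candidate regions), `filler_mask` (0/1 matrix of inserted
#'   filler), `boundary_mask` (0/1: thin-threshold boundary plus filler), and
#'   `thresholds` (the series actually used, thick to thin).
#' @export
fill_gaps <- function(img, cfg) {
  stopifnot(inherits(cfg, "gapfill_config"))
  px <- unclass(img)
  nr <- nrow(px); nc <- ncol(px)
  # thick end = endpoint yielding more boundary pixels under the >= rule
  e <- c(cfg$thick_threshold, cfg$thin_threshold)
  b <- c(sum(px >= e[1]), sum(px >= e[2]))
  thick <- if (b[1] >= b[2]) e[1] else e[2]
  thin <- if (b[1] >= b[2]) e[2] else e[1]
  th <- threshold_series(thick, thin, cfg$n_steps)

  filler <- matrix(FALSE, nr, nc)
  Tr <- matrix(0L, nr, nc)
  lab <- label_regions(px < th[1], 4L)
  pos <- which(lab > 0L)
  track_px <- unname(split(pos, lab[pos]))
  frozen <- rep(FALSE, length(track_px))
  for (i in seq_along(track_px)) Tr[track_px[[i]]] <- i

  for (t in th[-1]) {
    interior <- (px < t) & !filler
    lab <- label_cc_int(matrix(as.integer(interior), nr, nc), 4L)
    pos <- which(lab > 0L)
    pixl <- unname(split(pos, lab[pos]))
    pending <- vector("list", 0L)
    for (pl in pixl) {
      mem <- unique(Tr[pl])
      mem <- mem[mem != 0L]
      if (length(mem) == 0L) {
        id <- length(track_px) + 1L
        track_px[[id]] <- pl
        frozen[id] <- FALSE
        Tr[pl] <- id
      } else if (length(mem) == 1L) {
        id <- mem
        newpx <- pl[Tr[pl] == 0L]
        if (length(newpx) == 0L) next
        R <- track_px[[id]]
        if (frozen[id] ||
            (length(pl) > (1 + cfg$expansion_ratio) * length(R) &&
             length(R) >= cfg$min_track_area)) {
          frozen[id] <- TRUE
          shell <- intersect(newpx, nbr8(R, nr, nc))
          filler[shell] <- TRUE
          pending[[length(pending) + 1L]] <- setdiff(newpx, shell)
        } else {
          track_px[[id]] <- pl
          Tr[newpx] <- id
        }
      } else {
        # merge: several tracked regions now share one interior region
        newpx <- pl[Tr[pl] == 0L]
        shell <- integer(0)
        for (id in mem) {
          frozen[id] <- TRUE
          shell <- c(shell, intersect(newpx, nbr8(track_px[[id]], nr, nc)))
        }
        shell <- unique(shell)
        filler[shell] <- TRUE
        pending[[length(pending) + 1L]] <- setdiff(newpx, shell)
      }
    }
    rel <- unlist(pending)
    if (length(rel)) {
      pm <- matrix(0L, nr, nc)
      pm[rel] <- 1L
      plab <- label_cc_int(pm, 4L)
      ppos <- which(plab > 0L)
      for (pl in unname(split(ppos, plab[ppos]))) {
        id <- length(track_px) + 1L
        track_px[[id]] <- pl
        frozen[id] <- FALSE
        Tr[pl] <- id
      }
    }
  }

  seg <- relabel_rowmajor(Tr, nr, nc)
  fil <- matrix(0L, nr, nc); fil[filler] <- 1L
  bnd <- matrix(0L, nr, nc); bnd[px >= th[length(th)] | filler] <- 1L
  structure(list(segmented = seg, filler_mask = fil, boundary_mask = bnd,
                 thresholds = th),
            class = "gapfill_result")
}

#' Naive single-threshold segmentation (comparison baseline)
#'
#' Labels the candidate-fiber interiors of a single binarization: the regions
#' that a plain threshold would produce, with no gap handling. Adjacent fibers
#' whose shared boundary has a stain gap merge into one region here.
#'
#' @param img a [gray_image()].
#' @param threshold binarization threshold.
#' @return integer label matrix of interior regions (4-connected).
#' @export
naive_segment <- function(img, threshold) {
  label_regions(unclass(img) < threshold, 4L)
}
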