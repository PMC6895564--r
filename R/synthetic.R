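#' Phantom configuration
#'
#' Parameters of the synthetic muscle-section generator. A phantom is a mosaic
#' of convex-ish fiber cross-sections (Voronoi cells of Poisson-disk seeds)
#' separated by a bright boundary network of finite thickness, with a
#' configurable fraction of interstitial/artifact cells, boundary gaps of
#' intermediate stain intensity, nuclei placed centrally or peripherally, and
#' per-fiber marker intensities drawn from stated normal distributions. All
#' randomness derives from `seed`; the same seed yields a bit-identical
#' phantom.
#'
#' @param width,height image size in pixels.
#' @param n_fibers number of fiber cells.
#' @param n_interstitial number of interstitial/artifact cells (thin jagged
#'   channels embedded in bright connective-tissue matrix).
#' @param min_seed_distance Poisson-disk minimum seed spacing; default
#'   `0.6 * sqrt(width * height / n_cells)`.
#' @param boundary_thickness boundary band thickness in px.
#' @param boundary_mean,boundary_sd boundary stain intensity (mean/SD).
#' @param interior_mean,interior_sd fiber interior intensity on the boundary
#'   channel.
#' @param gap_fraction fraction of fibers given one boundary gap.
#' @param gap_length gap extent in px along the boundary.
#' @param gap_intensity,gap_intensity_sd stain intensity inside the gap
#'   (between the two gap-fill thresholds: closed at the thick end, open at
#'   the thin end — a weakly stained boundary stretch).
#' @param cnf_fraction fraction of fibers with a central nucleus.
#' @param peripheral_fraction fraction of the remaining fibers with a
#'   peripheral nucleus (within 2 px of the boundary).
#' @param nucleus_radius nucleus disc radius in px.
#' @param dapi_background_mean,dapi_background_sd,nucleus_mean,nucleus_sd
#'   nuclear-channel intensities.
#' @param marker_positive_mean,marker_negative_mean,marker_sd,marker_background_mean
#'   marker-channel intensities.
#' @param type_proportions named proportions over `I`, `IIa`, `IIb`, `IIx`
#'   (must sum to 1); IIx fibers are negative on all three channels.
#' @param hybrid_fraction fraction of fibers co-expressing two isoforms.
#' @param small_cluster_count,small_cluster_size clusters of small-caliber
#'   fibers (regenerating foci), used by the dystrophic preset.
#' @param snake_halfwidth half-width in px of interstitial channels.
#' @param seed RNG seed.
#' @return list of class `phantom_config`.
#' @export
phantom_config <- function(width = 512L, height = 512L, n_fibers = 120L,
                           n_interstitial = 25L, min_seed_distance = NULL,
                           boundary_thickness = 3, boundary_mean = 220,
                           boundary_sd = 8, interior_mean = 40,
                           interior_sd = 8, gap_fraction = 0, gap_length = 5,
                           gap_intensity = 150, gap_intensity_sd = 4,
                           cnf_fraction = 0.3, peripheral_fraction = 0.5,
                           nucleus_radius = 2, dapi_background_mean = 20,
                           dapi_background_sd = 5, nucleus_mean = 220,
                           nucleus_sd = 10, marker_positive_mean = 180,
                           marker_negative_mean = 40, marker_sd = 10,
                           marker_background_mean = 25,
                           type_proportions = c(I = 0.35, IIa = 0.30,
                                                IIb = 0.25, IIx = 0.10),
                           hybrid_fraction = 0, small_cluster_count = 0L,
                           small_cluster_size = 0L, snake_halfwidth = 1.2,
                           seed = 1L) {
  cfg <- as.list(environment())
  if (abs(sum(type_proportions) - 1) > 1e-8)
    stop("type_proportions must sum to 1")
  ints <- c(boundary_mean, interior_mean, gap_intensity, nucleus_mean,
            dapi_background_mean, marker_positive_mean, marker_negative_mean,
            marker_background_mean)
  if (any(ints < 0 | ints > 255)) stop("intensities must lie in [0, 255]")
  if (cfg$gap_fraction < 0 || cfg$gap_fraction > 1)
    stop("gap_fraction must lie in [0, 1]")
  structure(cfg, class = "phantom_config")
}

#' Dystrophic-morphology preset
#'
#' Returns a modified copy of a [phantom_config()] emulating dystrophic
#' muscle: higher fiber-size variance (clusters of small regenerating fibers),
#' more boundary gaps, more centrally nucleated fibers, and more interstitial
#' tissue. The base configuration is not modified.
#'
#' @param cfg a [phantom_config()].
#' @return a new `phantom_config`.
#' @export
dystrophic_preset <- function(cfg) {
  stopifnot(inherits(cfg, "phantom_config"))
  cfg$gap_fraction <- 0.3
  cfg$cnf_fraction <- 0.6
  cfg$peripheral_fraction <- 0.3
  cfg$small_cluster_count <- max(2L, round(cfg$n_fibers / 500))
  cfg$small_cluster_size <- 12L
  cfg$n_interstitial <- max(cfg$n_interstitial, round(0.15 * cfg$n_fibers))
  cfg
}

# shift-based one-step 4-connected erosion of a logical matrix
erode4_mask <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  up <- rbind(m[-1, , drop = FALSE], rep(FALSE, nc))
  dn <- rbind(rep(FALSE, nc), m[-nr, , drop = FALSE])
  lf <- cbind(m[, -1, drop = FALSE], rep(FALSE, nr))
  rt <- cbind(rep(FALSE, nr), m[, -nc, drop = FALSE])
  m & up & dn & lf & rt
}

# dart-throwing with per-seed radii; returns accepted points
dart_throw <- function(n, rlim, clim, radius, existing = NULL,
                       existing_radius = numeric(0), max_tries = 400L * n) {
  pts <- matrix(numeric(0), 0L, 2L)
  rads <- numeric(0)
  tries <- 0L
  while (nrow(pts) < n && tries < max_tries) {
    tries <- tries + 1L
    cand <- c(runif(1, rlim[1], rlim[2]), runif(1, clim[1], clim[2]))
    all_p <- rbind(existing, pts)
    all_r <- c(existing_radius, rads)
    ok <- TRUE
    if (!is.null(all_p) && nrow(all_p) > 0L) {
      d2 <- (all_p[, 1] - cand[1])^2 + (all_p[, 2] - cand[2])^2
      ok <- all(d2 >= ((all_r + radius) / 2)^2)
    }
    if (ok) {
      pts <- rbind(pts, cand)
      rads <- c(rads, radius)
    }
  }
  if (nrow(pts) < n)
    stop("infeasible packing: could not place ", n, " seeds at spacing ",
         signif(radius, 3))
  pts
}

# windowed nearest- and second-nearest-seed assignment
voronoi_fields <- function(seeds, h, w, win) {
  best1 <- matrix(Inf, h, w); best2 <- matrix(Inf, h, w)
  lab1 <- matrix(0L, h, w); lab2 <- matrix(0L, h, w)
  for (s in seq_len(nrow(seeds))) {
    r0 <- max(1L, floor(seeds[s, 1] - win)); r1 <- min(h, ceiling(seeds[s, 1] + win))
    c0 <- max(1L, floor(seeds[s, 2] - win)); c1 <- min(w, ceiling(seeds[s, 2] + win))
    d2 <- outer((r0:r1 - seeds[s, 1])^2, (c0:c1 - seeds[s, 2])^2, "+")
    b1 <- best1[r0:r1, c0:c1]; b2 <- best2[r0:r1, c0:c1]
    l1 <- lab1[r0:r1, c0:c1]; l2 <- lab2[r0:r1, c0:c1]
    nb <- d2 < b1
    b2[nb] <- b1[nb]; l2[nb] <- l1[nb]
    b1[nb] <- d2[nb]; l1[nb] <- s
    sec <- !nb & (d2 < b2)
    b2[sec] <- d2[sec]; l2[sec] <- s
    best1[r0:r1, c0:c1] <- b1; best2[r0:r1, c0:c1] <- b2
    lab1[r0:r1, c0:c1] <- l1; lab2[r0:r1, c0:c1] <- l2
  }
  miss <- which(!is.finite(best1))
  for (idx in miss) {
    r <- ((idx - 1L) %% h) + 1L; cc <- ((idx - 1L) %/% h) + 1L
    d2 <- (seeds[, 1] - r)^2 + (seeds[, 2] - cc)^2
    o <- order(d2)
    lab1[idx] <- o[1]; best1[idx] <- d2[o[1]]
    if (length(o) > 1L) { lab2[idx] <- o[2]; best2[idx] <- d2[o[2]] }
  }
  list(d1 = sqrt(best1), d2 = sqrt(best2), lab1 = lab1, lab2 = lab2)
}

# distance from points (n x 2) to segment a-b
pdist_segment <- function(p, a, b) {
  ab <- b - a
  len2 <- sum(ab^2)
  if (len2 == 0) return(sqrt((p[, 1] - a[1])^2 + (p[, 2] - a[2])^2))
  t <- ((p[, 1] - a[1]) * ab[1] + (p[, 2] - a[2]) * ab[2]) / len2
  t <- pmin(1, pmax(0, t))
  sqrt((p[, 1] - (a[1] + t * ab[1]))^2 + (p[, 2] - (a[2] + t * ab[2]))^2)
}

clip8 <- function(m) {
  m[m < 0] <- 0; m[m > 255] <- 255
  round(m)
}

disc_indices <- function(center, radius, h, w) {
  r0 <- max(1L, floor(center[1] - radius)); r1 <- min(h, ceiling(center[1] + radius))
  c0 <- max(1L, floor(center[2] - radius)); c1 <- min(w, ceiling(center[2] + radius))
  if (r0 > r1 || c0 > c1) return(integer(0))
  rr <- rep(r0:r1, times = c1 - c0 + 1L)
  cc <- rep(c0:c1, each = r1 - r0 + 1L)
  keep <- (rr - center[1])^2 + (cc - center[2])^2 <= radius^2
  (cc[keep] - 1L) * h + rr[keep]
}

#' Generate a synthetic muscle-section phantom
#'
#' Renders all channels (laminin boundary, DAPI, three myosin heavy-chain
#' marker channels) together with exhaustive ground truth: the fiber label
#' raster, per-fiber true areas, centroids, nucleus placement and CNF status,
#' fiber types and per-channel positivity, gap locations, and interstitial
#' region ids. Deterministic for a fixed `cfg$seed`.
#'
#' @param cfg a [phantom_config()].
#' @return list of class `phantom` with elements `channels` (named
#'   [gray_image()]s: `laminin`, `dapi`, and `markers$I/IIa/IIb`), `truth`,
#'   and `cfg`.
#' @export
make_phantom <- function(cfg) {
  stopifnot(inherits(cfg, "phantom_config"))
  set.seed(cfg$seed)
  h <- as.integer(cfg$height); w <- as.integer(cfg$width)
  n_cells <- cfg$n_fibers + cfg$n_interstitial
  md <- if (is.null(cfg$min_seed_distance))
    0.6 * sqrt(h * w / n_cells) else cfg$min_seed_distance
  margin <- max(4, md / 2)

  # seeds: small-fiber clusters first (dystrophic), then regular darts
  n_cluster <- cfg$small_cluster_count * cfg$small_cluster_size
  seeds <- matrix(numeric(0), 0L, 2L)
  radii <- numeric(0)
  if (n_cluster > 0L) {
    for (k in seq_len(cfg$small_cluster_count)) {
      cen <- c(runif(1, margin + 2 * md, h - margin - 2 * md),
               runif(1, margin + 2 * md, w - margin - 2 * md))
      spread <- 2.2 * md
      pts <- dart_throw(cfg$small_cluster_size,
                        c(max(margin, cen[1] - spread),
                          min(h - margin, cen[1] + spread)),
                        c(max(margin, cen[2] - spread),
                          min(w - margin, cen[2] + spread)),
                        radius = 0.45 * md, existing = seeds,
                        existing_radius = radii)
      seeds <- rbind(seeds, pts)
      radii <- c(radii, rep(0.45 * md, nrow(pts)))
    }
  }
  n_regular <- n_cells - nrow(seeds)
  pts <- dart_throw(n_regular, c(margin, h - margin), c(margin, w - margin),
                    radius = md, existing = seeds, existing_radius = radii)
  seeds <- rbind(seeds, pts)
  n_cluster_seeds <- n_cluster

  vf <- voronoi_fields(seeds, h, w, win = 5 * md)
  band <- (vf$d2 - vf$d1) <= cfg$boundary_thickness
  frame <- matrix(FALSE, h, w)
  frame[c(1:2, (h - 1):h), ] <- TRUE
  frame[, c(1:2, (w - 1):w)] <- TRUE
  boundary <- band | frame

  # cell roles: interstitial cells drawn from the regular (non-cluster) seeds
  regular_ids <- setdiff(seq_len(n_cells), seq_len(n_cluster_seeds))
  interstitial_cells <- if (cfg$n_interstitial > 0L)
    sort(sample(regular_ids, cfg$n_interstitial)) else integer(0)
  fiber_cells <- setdiff(seq_len(n_cells), interstitial_cells)

  interior <- !boundary
  cell_px <- split(which(interior), vf$lab1[interior])

  gt <- matrix(0L, h, w)
  inter_fill <- matrix(FALSE, h, w)  # interstitial matrix, rendered as stain
  fiber_id_of_cell <- integer(n_cells)
  fiber_id_of_cell[fiber_cells] <- seq_along(fiber_cells)
  next_id <- length(fiber_cells)
  interstitial_ids <- integer(0)
  for (cell in seq_len(n_cells)) {
    px <- cell_px[[as.character(cell)]]
    if (is.null(px) || length(px) == 0L) next
    if (cell %in% fiber_cells) {
      gt[px] <- fiber_id_of_cell[cell]
    } else {
      # interstitial: keep a thin bent channel, fill the rest with matrix
      r <- ((px - 1L) %% h) + 1L; cc <- ((px - 1L) %/% h) + 1L
      p <- cbind(r, cc)
      cen <- colMeans(p)
      d <- (p[, 1] - cen[1])^2 + (p[, 2] - cen[2])^2
      a <- p[which.max(d), ]
      d2 <- (p[, 1] - a[1])^2 + (p[, 2] - a[2])^2
      b <- p[which.max(d2), ]
      mid <- cen + runif(2, -0.2, 0.2) * sqrt(max(d))
      keep <- pmin(pdist_segment(p, a, mid), pdist_segment(p, mid, b)) <=
        cfg$snake_halfwidth
      if (!any(keep)) keep <- seq_len(nrow(p)) == which.min(d)
      next_id <- next_id + 1L
      gt[px[keep]] <- next_id
      interstitial_ids <- c(interstitial_ids, next_id)
      inter_fill[px[!keep]] <- TRUE
    }
  }
  n_fibers_actual <- length(fiber_cells)
  boundary_all <- boundary | inter_fill

  # per-fiber bookkeeping
  fib_idx <- which(gt > 0L & gt <= n_fibers_actual)
  fib_px <- split(fib_idx, factor(gt[fib_idx],
                                  levels = seq_len(n_fibers_actual)))
  fib_area <- lengths(fib_px)
  if (any(fib_area == 0L))
    stop("degenerate phantom: a fiber cell has no interior pixels; ",
         "reduce boundary_thickness or the seed count")
  fib_centroid <- t(vapply(fib_px, function(px) {
    c(mean(((px - 1L) %% h) + 1L), mean(((px - 1L) %/% h) + 1L))
  }, numeric(2)))

  # boundary gaps between adjacent fiber cells
  gap_mask <- matrix(FALSE, h, w)
  n_gaps <- round(cfg$gap_fraction * n_fibers_actual)
  gap_df <- data.frame(fiber_id = integer(0), partner_id = integer(0),
                       center_row = numeric(0), center_col = numeric(0))
  if (n_gaps > 0L) {
    cell_of_fiber <- fiber_cells
    band_idx <- which(band & !frame)
    pair1 <- vf$lab1[band_idx]; pair2 <- vf$lab2[band_idx]
    lo <- pmin(pair1, pair2); hi <- pmax(pair1, pair2)
    fiber_flag <- logical(n_cells); fiber_flag[fiber_cells] <- TRUE
    usable <- fiber_flag[lo] & fiber_flag[hi] & lo != hi
    cand_fibers <- sample(seq_len(n_fibers_actual))
    placed <- 0L
    rg <- max(cfg$gap_length / 2, cfg$boundary_thickness / 2 + 1)
    for (f in cand_fibers) {
      if (placed >= n_gaps) break
      cell <- cell_of_fiber[f]
      sel <- usable & (lo == cell | hi == cell)
      if (!any(sel)) next
      partner_cells <- ifelse(lo[sel] == cell, hi[sel], lo[sel])
      pc <- as.integer(names(which.max(table(partner_cells))))
      sel2 <- sel & (lo == pmin(cell, pc)) & (hi == pmax(cell, pc))
      idx <- band_idx[sel2]
      r <- ((idx - 1L) %% h) + 1L; cc <- ((idx - 1L) %/% h) + 1L
      midp <- (seeds[cell, ] + seeds[pc, ]) / 2
      ctr <- which.min((r - midp[1])^2 + (cc - midp[2])^2)
      center <- c(r[ctr], cc[ctr])
      corridor <- idx[(r - center[1])^2 + (cc - center[2])^2 <= rg^2]
      gap_mask[corridor] <- TRUE
      placed <- placed + 1L
      gap_df <- rbind(gap_df, data.frame(
        fiber_id = f, partner_id = fiber_id_of_cell[pc],
        center_row = center[1], center_col = center[2]))
    }
  }

  # nuclei: central (CNF) vs peripheral placement
  n_cnf <- round(cfg$cnf_fraction * n_fibers_actual)
  cnf_fibers <- if (n_cnf > 0L)
    sort(sample(seq_len(n_fibers_actual), n_cnf)) else integer(0)
  rest <- setdiff(seq_len(n_fibers_actual), cnf_fibers)
  n_per <- round(cfg$peripheral_fraction * length(rest))
  per_fibers <- if (n_per > 0L) sort(sample(rest, n_per)) else integer(0)
  nucleus <- rep("none", n_fibers_actual)
  nucleus[cnf_fibers] <- "central"
  nucleus[per_fibers] <- "peripheral"
  nuc_centers <- matrix(NA_real_, n_fibers_actual, 2L)
  for (f in cnf_fibers) {
    px <- fib_px[[as.character(f)]]
    r <- ((px - 1L) %% h) + 1L; cc <- ((px - 1L) %/% h) + 1L
    j <- which.min((r - fib_centroid[f, 1])^2 + (cc - fib_centroid[f, 2])^2)
    nuc_centers[f, ] <- c(r[j], cc[j])
  }
  for (f in per_fibers) {
    px <- fib_px[[as.character(f)]]
    r <- ((px - 1L) %% h) + 1L; cc <- ((px - 1L) %/% h) + 1L
    r0 <- min(r); c0 <- min(cc)
    m <- matrix(FALSE, max(r) - r0 + 1L, max(cc) - c0 + 1L)
    m[cbind(r - r0 + 1L, cc - c0 + 1L)] <- TRUE
    deep <- erode4_mask(erode4_mask(m))
    shallow <- which(!deep[cbind(r - r0 + 1L, cc - c0 + 1L)])
    j <- if (length(shallow)) shallow[sample(length(shallow), 1L)] else 1L
    nuc_centers[f, ] <- c(r[j], cc[j])
  }

  # fiber types and per-channel positivity
  tp <- cfg$type_proportions
  counts <- floor(tp * n_fibers_actual)
  rem <- n_fibers_actual - sum(counts)
  if (rem > 0L) {
    frac <- tp * n_fibers_actual - counts
    add <- order(frac, decreasing = TRUE)[seq_len(rem)]
    counts[add] <- counts[add] + 1L
  }
  type <- sample(rep(names(tp), counts))
  channels3 <- c("I", "IIa", "IIb")
  pos <- matrix(FALSE, n_fibers_actual, 3L,
                dimnames = list(NULL, channels3))
  for (ch in channels3) pos[type == ch, ch] <- TRUE
  n_hyb <- round(cfg$hybrid_fraction * n_fibers_actual)
  if (n_hyb > 0L) {
    hyb <- sample(seq_len(n_fibers_actual), n_hyb)
    for (f in hyb) {
      chs <- sample(channels3, 2L)
      pos[f, ] <- FALSE
      pos[f, chs] <- TRUE
      type[f] <- "hybrid"
    }
  }

  # render laminin channel
  lam <- matrix(rnorm(h * w, cfg$interior_mean, cfg$interior_sd), h, w)
  nb <- sum(boundary_all)
  lam[boundary_all] <- rnorm(nb, cfg$boundary_mean, cfg$boundary_sd)
  ng <- sum(gap_mask)
  if (ng > 0L) lam[gap_mask] <- rnorm(ng, cfg$gap_intensity,
                                      cfg$gap_intensity_sd)
  lam <- clip8(lam)

  # render DAPI channel
  dapi <- matrix(rnorm(h * w, cfg$dapi_background_mean,
                       cfg$dapi_background_sd), h, w)
  for (f in which(nucleus != "none")) {
    idx <- disc_indices(nuc_centers[f, ], cfg$nucleus_radius, h, w)
    dapi[idx] <- rnorm(length(idx), cfg$nucleus_mean, cfg$nucleus_sd)
  }
  dapi <- clip8(dapi)

  # render marker channels
  markers <- list()
  for (ch in channels3) {
    m <- matrix(rnorm(h * w, cfg$marker_background_mean, cfg$marker_sd), h, w)
    for (f in seq_len(n_fibers_actual)) {
      px <- fib_px[[as.character(f)]]
      mu <- if (pos[f, ch]) cfg$marker_positive_mean else
        cfg$marker_negative_mean
      m[px] <- rnorm(length(px), mu, cfg$marker_sd)
    }
    markers[[ch]] <- gray_image(clip8(m))
  }

  fibers <- data.frame(
    id = seq_len(n_fibers_actual),
    cell = fiber_cells,
    area_px = as.integer(fib_area),
    centroid_row = fib_centroid[, 1],
    centroid_col = fib_centroid[, 2],
    nucleus = nucleus,
    cnf = nucleus == "central",
    type = type,
    pos_I = pos[, "I"], pos_IIa = pos[, "IIa"], pos_IIb = pos[, "IIb"],
    has_gap = seq_len(n_fibers_actual) %in% gap_df$fiber_id
  )

  structure(list(
    channels = list(laminin = gray_image(lam), dapi = gray_image(dapi),
                    markers = markers),
    truth = list(labels = gt, fibers = fibers, n_fibers = n_fibers_actual,
                 interstitial_ids = interstitial_ids, gap_mask = gap_mask,
                 gaps = gap_df, seeds = seeds),
    cfg = cfg), class = "phantom")
}

#' Recommended gap-fill configuration for a phantom
#'
#' Thresholds bracketing the gap intensity: closed at the thick end, open at
#' the thin end, with ordinary boundary and interior intensities far outside
#' the series.
#'
#' @param phantom a [make_phantom()] result (or a `phantom_config`).
#' @param n_steps,expansion_ratio,min_track_area passed to
#'   [gap_fill_config()].
#' @return a [gap_fill_config()].
#' @export
phantom_gapfill_config <- function(phantom, n_steps = 10L,
                                   expansion_ratio = 0.20,
                                   min_track_area = 50L) {
  cfg <- if (inherits(phantom, "phantom")) phantom$cfg else phantom
  # thick endpoint: halfway between interior and gap intensity (every gap is
  # still closed); thin endpoint: 5 SD below the boundary mean (no ordinary
  # boundary pixel thins away, but every gap has opened)
  lo <- (cfg$interior_mean + cfg$gap_intensity) / 2
  hi <- cfg$boundary_mean - 5 * cfg$boundary_sd
  if (hi <= cfg$gap_intensity + 5 * cfg$gap_intensity_sd)
    warning("thin threshold does not clear the gap intensity band; ",
            "gaps may stay closed")
  gap_fill_config(thick_threshold = lo, thin_threshold = hi,
                  n_steps = n_steps, expansion_ratio = expansion_ratio,
                  min_track_area = min_track_area)
}
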