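# Independent oracles and raster shape builders used across test files.
# These deliberately avoid the code paths they check.

# breadth-first flood-fill labeling, pure R
oracle_label <- function(mask, connectivity = 4L) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  offs <- if (connectivity == 8L)
    cbind(c(-1, 1, 0, 0, -1, -1, 1, 1), c(0, 0, -1, 1, -1, 1, -1, 1))
  else cbind(c(-1, 1, 0, 0), c(0, 0, -1, 1))
  nxt <- 0L
  for (r in seq_len(nr)) for (cc in seq_len(nc)) {
    if (mask[r, cc] != 0 && lab[r, cc] == 0L) {
      nxt <- nxt + 1L
      queue <- list(c(r, cc))
      lab[r, cc] <- nxt
      while (length(queue)) {
        p <- queue[[1]]; queue <- queue[-1]
        for (k in seq_len(nrow(offs))) {
          rr <- p[1] + offs[k, 1]; c2 <- p[2] + offs[k, 2]
          if (rr >= 1 && rr <= nr && c2 >= 1 && c2 <= nc &&
              mask[rr, c2] != 0 && lab[rr, c2] == 0L) {
            lab[rr, c2] <- nxt
            queue[[length(queue) + 1]] <- c(rr, c2)
          }
        }
      }
    }
  }
  lab
}

# one-step 4-connected erosion by matrix shifts
oracle_erode4 <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  up <- rbind(m[-1, , drop = FALSE], rep(FALSE, nc))
  dn <- rbind(rep(FALSE, nc), m[-nr, , drop = FALSE])
  lf <- cbind(m[, -1, drop = FALSE], rep(FALSE, nr))
  rt <- cbind(rep(FALSE, nr), m[, -nc, drop = FALSE])
  m & up & dn & lf & rt
}

# iterate-and-measure erosion oracle: first iterate with area <= target
oracle_erode_fraction <- function(mask, percent) {
  if (percent == 0) return(mask)
  target <- (1 - percent / 100) * sum(mask)
  repeat {
    mask <- oracle_erode4(mask)
    if (sum(mask) <= target) return(mask)
  }
}

# convex-area oracle: rasterize the pixel-center hull with pracma::inpolygon
oracle_convex_area <- function(coords) {
  h <- grDevices::chull(coords[, 1], coords[, 2])
  poly <- coords[h, , drop = FALSE]
  rr <- seq(floor(min(poly[, 1])), ceiling(max(poly[, 1])))
  cc <- seq(floor(min(poly[, 2])), ceiling(max(poly[, 2])))
  g <- expand.grid(r = rr, c = cc)
  sum(pracma::inpolygon(g$r, g$c, poly[, 1], poly[, 2], boundary = TRUE))
}

# minimum caliper width by exhaustive 0.5-degree projection sweep over the
# pixel corner cloud
oracle_min_feret <- function(coords, step_deg = 0.5) {
  pts <- rbind(cbind(coords[, 1] - 0.5, coords[, 2] - 0.5),
               cbind(coords[, 1] - 0.5, coords[, 2] + 0.5),
               cbind(coords[, 1] + 0.5, coords[, 2] - 0.5),
               cbind(coords[, 1] + 0.5, coords[, 2] + 0.5))
  h <- grDevices::chull(pts[, 1], pts[, 2])
  pts <- pts[h, , drop = FALSE]
  th <- seq(0, 180 - step_deg, by = step_deg) * pi / 180
  widths <- vapply(th, function(a) {
    p <- pts[, 1] * cos(a) + pts[, 2] * sin(a)
    max(p) - min(p)
  }, 0)
  min(widths)
}

# --- raster shape builders ------------------------------------------------

mask_to_roi <- function(mask, id = 1L) {
  idx <- which(mask != 0, arr.ind = TRUE)
  structure(list(id = id, coords = cbind(row = idx[, 1], col = idx[, 2]),
                 dim = dim(mask),
                 centroid = c(row = mean(idx[, 1]), col = mean(idx[, 2]))),
            class = "roi")
}

disc_mask <- function(radius, pad = 2L) {
  n <- 2L * (radius + pad) + 1L
  ctr <- radius + pad + 1L
  g <- expand.grid(r = seq_len(n), c = seq_len(n))
  matrix((g$r - ctr)^2 + (g$c - ctr)^2 <= radius^2, n, n)
}

rect_mask <- function(h, w, pad = 2L) {
  m <- matrix(FALSE, h + 2L * pad, w + 2L * pad)
  m[pad + seq_len(h), pad + seq_len(w)] <- TRUE
  m
}

ellipse_mask <- function(a, b, pad = 2L) {
  n1 <- 2L * (ceiling(a) + pad) + 1L
  n2 <- 2L * (ceiling(b) + pad) + 1L
  g <- expand.grid(r = seq_len(n1), c = seq_len(n2))
  ctr <- c(ceiling(a) + pad + 1L, ceiling(b) + pad + 1L)
  matrix((g$r - ctr[1])^2 / a^2 + (g$c - ctr[2])^2 / b^2 <= 1, n1, n2)
}

plus_mask <- function(arm = 10L) {
  n <- 3L * arm
  m <- matrix(FALSE, n, n)
  m[arm + seq_len(arm), ] <- TRUE
  m[, arm + seq_len(arm)] <- TRUE
  m
}

# rectangle h x w rotated by angle (radians), rasterized analytically
rot_rect_mask <- function(h, w, angle, pad = 4L) {
  half <- ceiling(sqrt(h^2 + w^2) / 2) + pad
  n <- 2L * half + 1L
  g <- expand.grid(r = seq_len(n), c = seq_len(n))
  u <- (g$r - half - 1L) * cos(angle) + (g$c - half - 1L) * sin(angle)
  v <- -(g$r - half - 1L) * sin(angle) + (g$c - half - 1L) * cos(angle)
  matrix(abs(u) <= h / 2 & abs(v) <= w / 2, n, n)
}

# random star-convex polygon rasterized with pracma; returns the largest
# 4-connected component so the ROI contract (connectivity) holds
random_polygon_roi <- function(n_vertices = 8L, radius = 15) {
  ang <- sort(runif(n_vertices, 0, 2 * pi))
  rad <- runif(n_vertices, 0.35 * radius, radius)
  ctr <- radius + 4
  vr <- ctr + rad * cos(ang)
  vc <- ctr + rad * sin(ang)
  n <- 2L * ceiling(radius) + 8L
  g <- expand.grid(r = seq_len(n), c = seq_len(n))
  inside <- pracma::inpolygon(g$r, g$c, vr, vc, boundary = TRUE)
  m <- matrix(inside, n, n)
  lab <- oracle_label(m, 4L)
  if (max(lab) == 0L) return(NULL)
  biggest <- which.max(tabulate(lab[lab > 0]))
  mask_to_roi(lab == biggest)
}
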