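#' Extract regions of interest from a label image
#'
#' One ROI per positive label; the ROI id equals the label. Coordinates are
#' (row, col) pixel positions; the centroid is the mean pixel-center position.
#'
#' @param seg integer label matrix (0 = background/boundary).
#' @return list of `roi` objects (fields `id`, `coords`, `dim`, `centroid`).
#' @export
extract_rois <- function(seg) {
  pos <- which(seg > 0L)
  if (length(pos) == 0L) return(list())
  nr <- nrow(seg)
  ids <- sort(unique(seg[pos]))
  byid <- split(pos, seg[pos])
  lapply(ids, function(i) {
    idx <- byid[[as.character(i)]]
    r <- ((idx - 1L) %% nr) + 1L
    cc <- ((idx - 1L) %/% nr) + 1L
    structure(list(id = i, coords = cbind(row = r, col = cc),
                   dim = dim(seg),
                   centroid = c(row = mean(r), col = mean(cc))),
              class = "roi")
  })
}

# corner points of the convex hull of a pixel set: the hull of all 4 corners
# of every pixel equals the hull of the corners of the center-hull's vertices
# (Minkowski sum of the center hull with the unit square), so only those need
# enumerating
roi_corner_hull <- function(coords) {
  cen <- coords
  if (nrow(cen) > 3L) {
    h <- grDevices::chull(cen[, 1], cen[, 2])
    cen <- cen[h, , drop = FALSE]
  }
  pts <- rbind(cbind(cen[, 1] - 0.5, cen[, 2] - 0.5),
               cbind(cen[, 1] - 0.5, cen[, 2] + 0.5),
               cbind(cen[, 1] + 0.5, cen[, 2] - 0.5),
               cbind(cen[, 1] + 0.5, cen[, 2] + 0.5))
  h <- grDevices::chull(pts[, 1], pts[, 2])
  pts[h, , drop = FALSE]  # clockwise vertex order
}

polygon_perimeter <- function(v) {
  nxt <- rbind(v[-1, , drop = FALSE], v[1, , drop = FALSE])
  sum(sqrt(rowSums((v - nxt)^2)))
}

polygon_area <- function(v) {
  x <- v[, 1]; y <- v[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  abs(sum(x * yn - xn * y)) / 2
}

# convex hull of pixel centers (vertex matrix); degenerate sets allowed
roi_center_hull <- function(coords) {
  u <- unique(coords[, 1:2, drop = FALSE])
  if (nrow(u) <= 2L) return(u)
  h <- grDevices::chull(u[, 1], u[, 2])
  u[h, , drop = FALSE]
}

# count raster pixels whose centers fall inside a convex polygon (inclusive)
convex_raster_area <- function(hull, tol = 1e-9) {
  if (nrow(hull) == 1L) return(1L)
  rr <- seq(floor(min(hull[, 1])), ceiling(max(hull[, 1])))
  cc <- seq(floor(min(hull[, 2])), ceiling(max(hull[, 2])))
  pr <- rep(rr, times = length(cc))
  pc <- rep(cc, each = length(rr))
  inside <- rep(TRUE, length(pr))
  n <- nrow(hull)
  x <- hull[, 1]; y <- hull[, 2]
  signed2 <- sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)
  for (i in seq_len(n)) {
    a <- hull[i, ]; b <- hull[if (i == n) 1L else i + 1L, ]
    cr <- (b[1] - a[1]) * (pc - a[2]) - (b[2] - a[2]) * (pr - a[1])
    inside <- inside & if (signed2 >= 0) cr >= -tol else cr <= tol
    if (!any(inside)) break
  }
  sum(inside)
}

#' Shape descriptors of an ROI
#'
#' Computes the four features used to separate myofibers from interstitial
#' space and artifacts:
#' \describe{
#' \item{area}{pixel count.}
#' \item{eccentricity}{of the inertia-equivalent ellipse: focal distance over
#'   major axis length, i.e. `sqrt(1 - (b/a)^2)`. Second moments include each
#'   pixel's own 1/12 square-inertia term, so a one-pixel region has
#'   eccentricity 0 and even a single-pixel-wide line stays strictly below 1.}
#' \item{convexity}{area divided by convex area, where convex area is the
#'   number of pixels whose centers lie within the convex hull of the region's
#'   pixel centers; exactly 1 for convex rasterized shapes and always in
#'   (0, 1].}
#' \item{circularity}{`4 * pi * area / perimeter^2`. The perimeter estimator
#'   is the convex-contour length (perimeter of the convex hull of the pixel
#'   corners): exact for convex shapes, which myofiber profiles approximate,
#'   and a lower bound for concave regions.}
#' }
#'
#' @param roi an `roi` from [extract_rois()].
#' @return named numeric vector `area`, `eccentricity`, `convexity`,
#'   `circularity`.
#' @export
compute_features <- function(roi) {
  co <- roi$coords
  area <- nrow(co)
  # moment ellipse
  mr <- co[, 1] - mean(co[, 1]); mc <- co[, 2] - mean(co[, 2])
  mu20 <- mean(mr^2) + 1 / 12
  mu02 <- mean(mc^2) + 1 / 12
  mu11 <- mean(mr * mc)
  com <- sqrt((mu20 - mu02)^2 + 4 * mu11^2)
  l1 <- (mu20 + mu02 + com) / 2
  l2 <- (mu20 + mu02 - com) / 2
  ecc <- sqrt(max(0, 1 - l2 / l1))
  conv <- area / convex_raster_area(roi_center_hull(co))
  per <- polygon_perimeter(roi_corner_hull(co))
  circ <- 4 * pi * area / per^2
  c(area = area, eccentricity = ecc, convexity = min(conv, 1), circularity = circ)
}

#' Feature table for a list of ROIs
#'
#' @param rois list of `roi` objects.
#' @return data.frame with columns `roi_id`, `area`, `eccentricity`,
#'   `convexity`, `circularity`.
#' @export
compute_features_table <- function(rois) {
  if (length(rois) == 0L)
    return(data.frame(roi_id = integer(0), area = numeric(0),
                      eccentricity = numeric(0), convexity = numeric(0),
                      circularity = numeric(0)))
  f <- t(vapply(rois, compute_features, numeric(4)))
  data.frame(roi_id = vapply(rois, function(r) r$id, 0L),
             area = f[, "area"], eccentricity = f[, "eccentricity"],
             convexity = f[, "convexity"], circularity = f[, "circularity"])
}

feature_cols <- c("area", "eccentricity", "convexity", "circularity")

#' Train the myofiber/non-myofiber classifier
#'
#' Support vector machine with a radial basis function kernel on the four
#' shape descriptors. Features are standardized (z-score on training
#' statistics) before kernel evaluation; `gamma` defaults to 1 over the number
#' of features, which on standardized features matches the usual
#' variance-scaled heuristic. Training is deterministic for a fixed seed.
#'
#' @param training data.frame with the feature columns of
#'   [compute_features_table()] and a `label` column with values `"myofiber"`
#'   and `"non_myofiber"` (both classes must be present).
#' @param seed integer RNG seed.
#' @param cost,gamma RBF-SVM hyperparameters.
#' @return an object of class `fiber_classifier`.
#' @export
train_classifier <- function(training, seed = 1L, cost = 1,
                             gamma = 1 / length(feature_cols)) {
  stopifnot(is.data.frame(training), all(feature_cols %in% names(training)),
            "label" %in% names(training))
  lab <- factor(as.character(training$label),
                levels = c("myofiber", "non_myofiber"))
  if (anyNA(lab)) stop("labels must be 'myofiber' or 'non_myofiber'")
  if (length(unique(lab)) < 2L)
    stop("training set must contain both classes")
  x <- as.matrix(training[, feature_cols])
  # explicit z-score standardization on training statistics; constant
  # features pass through unscaled instead of disabling scaling entirely
  ctr <- colMeans(x)
  scl <- apply(x, 2, sd)
  scl[!is.finite(scl) | scl < 1e-12] <- 1
  xs <- scale(x, center = ctr, scale = scl)
  set.seed(seed)
  fit <- e1071::svm(x = xs, y = lab, type = "C-classification",
                    kernel = "radial", cost = cost, gamma = gamma,
                    scale = FALSE)
  structure(list(fit = fit, features = feature_cols, center = ctr,
                 scale = scl, seed = seed, cost = cost, gamma = gamma,
                 version = 1L),
            class = "fiber_classifier")
}

#' Classify ROIs as myofiber or non-myofiber
#'
#' @param model a [train_classifier()] model.
#' @param features data.frame from [compute_features_table()] (or with the
#'   same feature columns).
#' @return character vector of `"myofiber"`/`"non_myofiber"`, named by
#'   `roi_id` when present.
#' @export
classify_rois <- function(model, features) {
  stopifnot(inherits(model, "fiber_classifier"))
  if (nrow(features) == 0L) return(character(0))
  xs <- scale(as.matrix(features[, model$features]),
              center = model$center, scale = model$scale)
  p <- as.character(predict(model$fit, xs))
  if ("roi_id" %in% names(features)) names(p) <- features$roi_id
  p
}

#' Flip the class of selected ROIs
#'
#' Correction filter: each listed ROI id has its myofiber/non-myofiber call
#' inverted (so toggling twice is the identity); all other calls are
#' untouched.
#'
#' @param labels named character vector from [classify_rois()].
#' @param toggle_ids ROI ids to flip.
#' @return corrected labels.
#' @export
apply_corrections <- function(labels, toggle_ids) {
  if (length(toggle_ids) == 0L) return(labels)
  key <- as.character(toggle_ids)
  if (!all(key %in% names(labels))) stop("unknown roi id in corrections")
  flip <- c(myofiber = "non_myofiber", non_myofiber = "myofiber")
  labels[key] <- flip[labels[key]]
  labels
}

#' Save / load a training set as a plain-text table
#'
#' The persistence format is a version-stamped CSV of feature vectors and
#' labels, so saved training data stays retrainable across sessions and
#' package versions.
#'
#' @param training data.frame as accepted by [train_classifier()].
#' @param path file path.
#' @export
save_training_set <- function(training, path) {
  stopifnot(all(c(feature_cols, "label") %in% names(training)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# fiberquant training set v1", con)
  write.csv(training[, c(feature_cols, "label")], con, row.names = FALSE)
  invisible(path)
}

#' @rdname save_training_set
#' @export
load_training_set <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  first <- readLines(path, n = 1L)
  if (!startsWith(first, "# fiberquant training set"))
    stop("not a fiberquant training set file")
  read.csv(path, comment.char = "#")
}
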