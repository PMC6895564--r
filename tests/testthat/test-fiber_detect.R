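test_that("ROIs are extracted one per positive label", {
  expect_length(extract_rois(matrix(0L, 5, 5)), 0)
  lab <- matrix(0L, 6, 6)
  lab[2:4, 2:4] <- 1L
  rois <- extract_rois(lab)
  expect_length(rois, 1)
  expect_identical(rois[[1]]$id, 1L)
  expect_identical(nrow(rois[[1]]$coords), 9L)

  ph <- phantom_small()
  res <- fill_gaps(ph$channels$laminin, phantom_gapfill_config(ph))
  rois <- extract_rois(res$segmented)
  expect_identical(length(rois), max(res$segmented))
  expect_identical(vapply(rois, function(r) r$id, 0L),
                   sort(unique(res$segmented[res$segmented > 0L])))
})

test_that("shape descriptors hit their closed-form limits", {
  disc <- compute_features(mask_to_roi(disc_mask(30)))
  expect_lt(disc[["eccentricity"]], 0.05)
  expect_gt(disc[["convexity"]], 0.98)
  expect_lt(abs(disc[["circularity"]] - 1), 0.05)

  sq <- compute_features(mask_to_roi(rect_mask(40, 40)))
  expect_identical(unname(sq["area"]), 1600)
  expect_lt(abs(sq[["circularity"]] - pi / 4) / (pi / 4), 0.05)

  ell <- compute_features(mask_to_roi(ellipse_mask(40, 20)))
  expect_lt(abs(ell[["eccentricity"]] - sqrt(3) / 2), 0.03)

  # single pixel: degenerate contract
  one <- compute_features(mask_to_roi(matrix(c(FALSE, TRUE, FALSE, FALSE), 2, 2)))
  expect_identical(unname(one["area"]), 1)
  expect_identical(unname(one["eccentricity"]), 0)
  expect_identical(unname(one["convexity"]), 1)
  expect_gt(one[["circularity"]], 0)
})

test_that("convexity matches the independent hull-rasterization oracle", {
  skip_if_not_installed("pracma")
  plus <- mask_to_roi(plus_mask(10L))
  f <- compute_features(plus)
  expect_equal(unname(f["convexity"]),
               nrow(plus$coords) / oracle_convex_area(plus$coords),
               tolerance = 1e-6)

  set.seed(4)
  n_checked <- 0
  while (n_checked < 50) {
    roi <- random_polygon_roi()
    if (is.null(roi) || nrow(roi$coords) < 5) next
    n_checked <- n_checked + 1
    f <- compute_features(roi)
    expect_identical(unname(f["area"]), as.numeric(nrow(roi$coords)))
    expect_equal(unname(f["convexity"]),
                 nrow(roi$coords) / oracle_convex_area(roi$coords),
                 tolerance = 1e-6)
    expect_gte(f[["eccentricity"]], 0)
    expect_lt(f[["eccentricity"]], 1)
    expect_lte(f[["convexity"]], 1 + 1e-9)
    expect_gt(f[["circularity"]], 0)
  }
})

test_that("descriptors are invariant under translation and 90-degree rotation", {
  set.seed(5)
  roi <- random_polygon_roi()
  f0 <- compute_features(roi)
  shifted <- roi
  shifted$coords <- roi$coords + 100L
  expect_equal(compute_features(shifted), f0, tolerance = 1e-12)

  rot <- roi
  rot$coords <- cbind(row = roi$coords[, 2],
                      col = max(roi$coords[, 1]) + 1L - roi$coords[, 1])
  fr <- compute_features(rot)
  expect_equal(unname(fr["area"]), unname(f0["area"]))
  for (feat in c("eccentricity", "convexity", "circularity"))
    expect_equal(unname(fr[feat]), unname(f0[feat]), tolerance = 1e-6)
})

test_that("the SVM separates trivially separable ROIs and is deterministic", {
  rois <- list(mask_to_roi(disc_mask(10), id = 1L),
               mask_to_roi(rect_mask(2, 60), id = 2L),
               mask_to_roi(disc_mask(11), id = 3L),
               mask_to_roi(rect_mask(2, 50), id = 4L))
  feats <- compute_features_table(rois)
  train <- feats[1:2, ]
  train$label <- c("myofiber", "non_myofiber")
  model <- train_classifier(train, seed = 1L)
  pred <- classify_rois(model, feats)
  expect_identical(unname(pred), c("myofiber", "non_myofiber",
                                   "myofiber", "non_myofiber"))
  # memorized training points keep their labels
  expect_identical(unname(pred[1:2]), train$label)

  model2 <- train_classifier(train, seed = 1L)
  expect_identical(classify_rois(model2, feats), pred)

  single <- train
  single$label <- "myofiber"
  expect_error(train_classifier(single), "both classes")
  expect_identical(classify_rois(model, feats[0, ]), character(0))
})

test_that("held-out classification on a phantom exceeds 95 percent", {
  ph <- phantom_small()
  res <- fill_gaps(ph$channels$laminin, phantom_gapfill_config(ph))
  rois <- extract_rois(res$segmented)
  feats <- compute_features_table(rois)
  tc <- truth_roi_classes(rois, ph)
  training <- phantom_training(rois, ph, n_per_class = 10L, seed = 2L)
  model <- train_classifier(merge(feats, training, by = "roi_id"), seed = 1L)
  held <- !(tc$roi_id %in% training$roi_id)
  pred <- classify_rois(model, feats[held, ])
  expect_gte(mean(pred == tc$label[held]), 0.95)
})

test_that("correction toggles flip calls and are involutive", {
  labels <- c("1" = "myofiber", "2" = "non_myofiber", "3" = "myofiber")
  expect_identical(apply_corrections(labels, integer(0)), labels)
  once <- apply_corrections(labels, c(1, 2))
  expect_identical(unname(once), c("non_myofiber", "myofiber", "myofiber"))
  expect_identical(apply_corrections(once, c(1, 2)), labels)
  expect_error(apply_corrections(labels, 99), "unknown roi id")
})

test_that("training sets persist as retrainable plain text", {
  rois <- list(mask_to_roi(disc_mask(10), id = 1L),
               mask_to_roi(rect_mask(2, 60), id = 2L))
  train <- compute_features_table(rois)
  train$label <- c("myofiber", "non_myofiber")
  p <- withr::local_tempfile(fileext = ".csv")
  save_training_set(train, p)
  expect_match(readLines(p, n = 1L), "training set v1")
  back <- load_training_set(p)
  expect_equal(back[, c("area", "eccentricity", "convexity", "circularity")],
               train[, c("area", "eccentricity", "convexity", "circularity")],
               tolerance = 1e-12)
  m1 <- train_classifier(train, seed = 3L)
  m2 <- train_classifier(back, seed = 3L)
  grid <- compute_features_table(list(mask_to_roi(disc_mask(8), id = 9L),
                                      mask_to_roi(rect_mask(2, 40), id = 10L)))
  expect_identical(classify_rois(m1, grid), classify_rois(m2, grid))
})
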