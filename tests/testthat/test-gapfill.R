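# two 13x13 fiber interiors separated by a 3-px boundary stripe; the stripe
# carries a weakly stained 3-row gap that is closed at the thick threshold
# (95) but open at the thin one (180)
two_fiber_gap_fixture <- function() {
  img <- matrix(220L, 19, 33)
  img[4:16, 4:16] <- 40L
  img[4:16, 20:32] <- 40L   # 3-px stripe at cols 17:19
  img[9:11, 17:19] <- 150L  # the gap corridor
  list(img = gray_image(img),
       gap_rows = 9:11, gap_cols = 17:19,
       left = expand.grid(row = 4:16, col = 4:16),
       right = expand.grid(row = 4:16, col = 20:32))
}

test_that("threshold series is evenly spaced with endpoints included", {
  expect_equal(threshold_series(200, 100, 3), c(200, 150, 100))
  expect_equal(threshold_series(90, 30, 4), c(90, 70, 50, 30))
  expect_equal(threshold_series(42, 42, 1), 42)
  expect_error(threshold_series(10, 20, 1), "equal endpoints")
  expect_error(threshold_series(10, 10, 5), "equal endpoints")
  expect_error(gap_fill_config(100, 100), "differ")
  expect_error(gap_fill_config(100, 180, expansion_ratio = 0), "> 0")
})

test_that("naive segmentation merges gapped fibers; fill_gaps separates them", {
  fx <- two_fiber_gap_fixture()
  cfg <- gap_fill_config(95, 180, n_steps = 10L, min_track_area = 20L)

  merged <- naive_segment(fx$img, 180)
  li <- merged[cbind(fx$left$row, fx$left$col)]
  ri <- merged[cbind(fx$right$row, fx$right$col)]
  expect_identical(unique(c(li, ri)), 1L)  # one combined region

  res <- fill_gaps(fx$img, cfg)
  li <- unique(res$segmented[cbind(fx$left$row, fx$left$col)])
  ri <- unique(res$segmented[cbind(fx$right$row, fx$right$col)])
  expect_length(li, 1)
  expect_length(ri, 1)
  expect_true(li != ri)
  # filler exists and sits inside the annotated gap corridor
  fil <- which(res$filler_mask == 1L, arr.ind = TRUE)
  expect_gt(nrow(fil), 0)
  expect_true(all(fil[, 1] %in% fx$gap_rows & fil[, 2] %in% fx$gap_cols))
})

test_that("intact boundaries reduce fill_gaps to thin-threshold segmentation", {
  ph <- phantom_small()
  cfg <- phantom_gapfill_config(ph)
  res <- fill_gaps(ph$channels$laminin, cfg)
  expect_identical(sum(res$filler_mask), 0L)
  expect_identical(res$segmented,
                   naive_segment(ph$channels$laminin, cfg$thin_threshold))
})

test_that("segmentation invariants hold on a gapped phantom", {
  ph <- phantom_small_gaps()
  cfg <- phantom_gapfill_config(ph)
  res <- fill_gaps(ph$channels$laminin, cfg)
  naive <- naive_segment(ph$channels$laminin, cfg$thin_threshold)

  # conservativity: every segmented region lies within one naive region
  pos <- which(res$segmented > 0L)
  by_reg <- split(naive[pos], res$segmented[pos])
  expect_true(all(vapply(by_reg, function(v) length(unique(v)) == 1L, TRUE)))

  # filler within boundary mask; segmented disjoint from boundary mask
  expect_true(all(res$boundary_mask[res$filler_mask == 1L] == 1L))
  expect_true(all(res$segmented[res$boundary_mask == 1L] == 0L))

  # gaps were actually needed and recovered
  rec <- fiber_recovery(res$segmented, ph)
  nrec <- fiber_recovery(naive, ph)
  expect_gt(nrec$n_merged, 0)
  expect_gte(rec$recovered_fraction, 0.95)
  # filler confined to annotated gap corridors
  expect_identical(sum(res$filler_mask == 1L & !ph$truth$gap_mask), 0L)
})

test_that("segmentation baseline handles degenerate images", {
  allb <- gray_image(matrix(255L, 10, 10))
  expect_identical(max(naive_segment(allb, 100)), 0L)
  allbg <- gray_image(matrix(0L, 10, 10))
  expect_identical(max(naive_segment(allbg, 100)), 1L)
})

test_that("threshold_preview reports monotone boundary counts", {
  ph <- phantom_small()
  pv <- threshold_preview(ph$channels$laminin, c(50, 120, 200, 250))
  expect_true(all(diff(pv$boundary_px) <= 0))
})
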