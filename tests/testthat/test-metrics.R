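test_that("minimum Feret diameter matches projection-sweep oracle and closed forms", {
  rect <- mask_to_roi(rect_mask(10, 30))
  expect_lt(abs(min_feret(rect) - 10), 1)
  expect_lt(abs(min_feret(rect) - oracle_min_feret(rect$coords)), 1)

  disc <- mask_to_roi(disc_mask(30))
  expect_lt(abs(min_feret(disc) - 60) / 60, 0.02)

  # rotated rasterizations stay within a pixel of the corner-sweep oracle
  rot <- mask_to_roi(rot_rect_mask(10, 30, pi / 4))
  expect_lt(abs(min_feret(rot) - oracle_min_feret(rot$coords)), 1)
  expect_lt(abs(min_feret(rot) - 10), 1)

  # rotation invariance within 2 percent once quantization is amortized
  big <- mask_to_roi(rect_mask(40, 120))
  for (ang in c(pi / 6, pi / 4)) {
    bigrot <- mask_to_roi(rot_rect_mask(40, 120, ang))
    expect_lt(abs(min_feret(bigrot) - min_feret(big)) / min_feret(big), 0.02)
  }

  one <- mask_to_roi(matrix(c(TRUE, FALSE, FALSE, FALSE), 2, 2))
  expect_equal(min_feret(one), 1)
  line <- mask_to_roi(rbind(rep(FALSE, 12), c(FALSE, rep(TRUE, 10), FALSE),
                            rep(FALSE, 12)))
  expect_equal(min_feret(line), 1)  # one-pixel-wide line: pixel width
})

test_that("min Feret is bounded by the max hull distance and scale-equivariant", {
  skip_if_not_installed("pracma")
  set.seed(10)
  rasterize_poly <- function(vr, vc, scale) {
    n <- ceiling(max(vr, vc) * scale) + 4L
    g <- expand.grid(r = seq_len(n), c = seq_len(n))
    m <- matrix(pracma::inpolygon(g$r, g$c, vr * scale, vc * scale,
                                  boundary = TRUE), n, n)
    mask_to_roi(m)
  }
  for (i in 1:5) {
    ang <- sort(runif(8, 0, 2 * pi))
    rad <- runif(8, 12, 30)
    vr <- 34 + rad * cos(ang)
    vc <- 34 + rad * sin(ang)
    roi <- rasterize_poly(vr, vc, 1)
    mf <- min_feret(roi)
    d <- as.matrix(dist(roi$coords))
    expect_lte(mf, max(d) + 1)  # max pairwise distance (+corner allowance)
    # rasterizing the same shape at twice the resolution doubles the caliper
    mf2 <- min_feret(rasterize_poly(vr, vc, 2))
    expect_lt(abs(mf2 - 2 * mf) / (2 * mf), 0.02)
  }
})

test_that("physical-unit conversion applies the microns-per-pixel scale", {
  rec <- data.frame(roi_id = 1:3, area_px = c(100L, 100L, 400L),
                    min_feret_px = c(20, 10, 40))
  out <- to_physical(rec, 1)
  expect_equal(out$area_um2, c(100, 100, 400))
  out <- to_physical(rec, 0.5)
  expect_equal(out$area_um2, c(25, 25, 100))
  expect_equal(out$min_feret_um, c(10, 5, 20))
  expect_error(to_physical(rec, 0), "positive")
  expect_error(to_physical(rec, NULL), "positive")
})

test_that("record export round-trips losslessly", {
  rec <- data.frame(
    roi_id = 1:3, area_px = c(10L, 20L, 30L),
    area_um2 = c(10, 20, 30) * 0.755^2,
    min_feret_px = c(3.123456789012345, 4, 5),
    min_feret_um = c(3.123456789012345, 4, 5) * 0.755,
    cnf = c(TRUE, FALSE, NA),
    mfi_I = c(10 / 3, 2, 255), pos_I = c(TRUE, FALSE, TRUE),
    fiber_type = c("I", "IIx", "hybrid"))
  p <- withr::local_tempfile(fileext = ".csv")
  export_records(rec, p)
  back <- read_records(p)
  expect_identical(back$roi_id, rec$roi_id)
  expect_identical(back$cnf, rec$cnf)
  expect_identical(back$mfi_I, rec$mfi_I)      # exact double round trip
  expect_identical(back$min_feret_um, rec$min_feret_um)
  expect_identical(back$fiber_type, rec$fiber_type)

  export_records(rec[0, ], p)
  expect_identical(nrow(read_records(p)), 0L)
  expect_identical(readLines(p, n = 1L),
                   paste(c("roi_id,area_px,area_um2,min_feret_px",
                           "min_feret_um,cnf,mfi_I,pos_I,fiber_type"),
                         collapse = ","))
})

test_that("accuracy follows the absolute-error formula and is capped at 100", {
  expect_equal(accuracy(100, 100), 100)
  expect_equal(accuracy(110, 100), 90)
  expect_equal(accuracy(90, 100), 90)
  expect_error(accuracy(5, 0), "> 0")
  set.seed(11)
  x <- runif(50, 0, 200)
  expect_true(all(accuracy(x, 100) <= 100))
})

test_that("coefficient of variation matches a two-pass oracle", {
  expect_equal(cv(c(10, 10, 10)), 0)
  expect_equal(cv(c(90, 100, 110)), 10)  # mean 100, sample SD 10
  set.seed(12)
  v <- rnorm(200, 50, 7)
  m <- sum(v) / length(v)
  s <- sqrt(sum((v - m)^2) / (length(v) - 1))
  expect_lt(abs(cv(v) - s / m * 100), 1e-10)
  expect_error(cv(5), "at least 2")
  expect_error(cv(c(-1, 1)), "zero mean")
})
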