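test_that("intensity normalization rescales to [0, 1] and is idempotent", {
  f <- matrix(seq(0.2, 0.7, length.out = 100), 10, 10)
  n <- normalize_intensity(f)
  expect_equal(range(n), c(0, 1))
  expect_equal(n[5, 5], (f[5, 5] - 0.2) / 0.5, tolerance = 1e-12)
  expect_identical(normalize_intensity(n), n)
  expect_warning(normalize_intensity(matrix(0.3, 8, 8)), "constant")
})

test_that("binarize honors mode, boundary thresholds, and counts disc area exactly", {
  f <- matrix(0.9, 40, 60)
  d1 <- disc_mask(40, 60, 10, 15, 4)
  d2 <- disc_mask(40, 60, 25, 40, 5)
  d3 <- disc_mask(40, 60, 30, 12, 3)
  f[d1 | d2 | d3] <- 0.1
  m <- binarize(f, 0.5, "dark")
  expect_equal(sum(m), sum(d1) + sum(d2) + sum(d3))
  expect_true(all(binarize(matrix(0.3, 5, 5), 0.5, "dark")))
  bright <- binarize(matrix(c(0, 0.01, 0.5, 1), 2, 2), 0, "bright")
  expect_equal(sum(bright), 3)
})

test_that("contour tracing matches component labeling and preserves the mask", {
  m <- matrix(FALSE, 30, 40)
  m[3:8, 3:8] <- TRUE; m[15:22, 10:17] <- TRUE; m[5:10, 25:35] <- TRUE
  before <- sum(m)
  ct <- trace_contours(m)
  expect_equal(sum(m), before)  # tracing never modifies the mask
  outer <- ct[ct$type == "outer", ]
  expect_equal(nrow(outer), 3)
  # oracle: independent 8-connected component count (union-find)
  expect_equal(nrow(outer), count_components8(m))
  # polygon area within one-pixel rim of the filled square area
  sq <- outer[outer$x0 == 2 & outer$y0 == 2, ]
  expect_equal(sq$area, 25)       # (6-1)^2: border through pixel centers
  expect_equal(sq$n_pixels, 36)   # filled 6x6 square
  expect_true(all(outer$level == 0))
})

test_that("contour count equals component count on random speckle masks", {
  for (seed in 1:5) {
    set.seed(seed)
    m <- matrix(runif(40 * 40) < 0.12, 40, 40)
    ct <- trace_contours(m)
    expect_equal(nrow(ct[ct$type == "outer", ]), count_components8(m))
  }
})

test_that("a ring produces an outer contour at level 0 and a hole at level 1", {
  m <- matrix(FALSE, 20, 20)
  m[5:15, 5:15] <- TRUE
  m[8:12, 8:12] <- FALSE
  ct <- trace_contours(m)
  expect_equal(ct$level[ct$type == "outer"], 0L)
  expect_equal(ct$level[ct$type == "hole"], 1L)
  expect_equal(nrow(ct), 2)
})

test_that("tracing is deterministic and ordered by raster position", {
  set.seed(9)
  m <- matrix(runif(50 * 50) < 0.1, 50, 50)
  a <- trace_contours(m)
  b <- trace_contours(m)
  expect_identical(a, b)
  expect_true(all(diff(order(a$y0 * 1000 + a$x0)) > 0) || nrow(a) <= 1)
  expect_identical(trace_contours(matrix(FALSE, 10, 10))$contour, integer(0))
})

test_that("apply_roi follows the 0-based half-open convention", {
  f <- matrix(seq_len(100), 10, 10)
  roi <- roi_rect(2, 3, 4, 5)
  crop <- apply_roi(f, roi)
  expect_equal(dim(crop), c(5, 4))
  expect_equal(crop[1, 1], f[4, 3])
  full <- apply_roi(f, roi_rect(0, 0, 10, 10))
  expect_identical(full, f)
  expect_error(roi_rect(0, 0, 2, 2), "at least 4x4")
  expect_error(apply_roi(f, roi_rect(8, 8, 4, 4)), "bounds")
})

test_that("motion mask is empty on static clips and covers the vessel on moving ones", {
  static <- static_clip(textured_frame(64, seed = 41), n = 4)
  mm <- motion_mask(static)
  expect_false(any(mm))
  expect_error(auto_roi(static), "manual ROI")
  sim <- synthetic_vessel_clip(vessel_scene_params(n_frames = 8, seed = 51))
  mv <- motion_mask(sim$clip)
  band <- (sim$truth$vessel_rect$y0 + 1):(sim$truth$vessel_rect$y0 +
                                            sim$truth$vessel_rect$height)
  expect_gt(mean(mv[band, ]), 0.8)       # >= 80% of the true vessel band
  expect_lt(mean(mv[-band, ]), 0.1)      # <= 10% of the background
})

test_that("auto ROI picks the larger of two moving bands and is deterministic", {
  p <- vessel_scene_params(shape = c(96L, 192L), vessel_band = c(10L, 29L),
                           n_rows = 1L, n_frames = 8, seed = 61)
  simA <- synthetic_vessel_clip(p)
  p2 <- vessel_scene_params(shape = c(96L, 192L), vessel_band = c(50L, 89L),
                            n_rows = 3L, n_frames = 8, seed = 61)
  simB <- synthetic_vessel_clip(p2)
  merged <- simA$clip
  for (i in seq_along(merged$frames)) {
    lower <- simB$clip$frames[[i]][41:96, ]
    merged$frames[[i]][41:96, ] <- lower
  }
  roi <- auto_roi(merged)
  # the ROI must cover the larger (lower, 40 px) band, not the 20 px one
  expect_gt(roi$y0 + roi$height, 60)
  expect_gt(roi_iou(roi, simB$truth$vessel_rect), 0.5)
  expect_identical(unclass(auto_roi(merged)), unclass(roi))
})

test_that("roi_iou is exact on hand cases", {
  a <- roi_rect(0, 0, 10, 10)
  expect_equal(roi_iou(a, a), 1)
  b <- roi_rect(5, 0, 10, 10)
  expect_equal(roi_iou(a, b), 50 / 150)
  expect_equal(roi_iou(a, roi_rect(20, 20, 5, 5)), 0)
})
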