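mkflow <- function(u, v, valid = NULL) {
  if (is.null(valid)) valid <- matrix(TRUE, nrow(u), ncol(u))
  structure(list(u = u, v = v, valid = valid), class = "flow_field")
}

test_that("frame speed statistics: uniform fields, 3-4-5, thresholded exclusion", {
  u <- matrix(2, 20, 20); v <- matrix(0, 20, 20)
  expect_equal(frame_flow_speed(mkflow(u, v), motion_threshold = 0.2), 2)
  expect_equal(frame_flow_speed(mkflow(matrix(3, 10, 10), matrix(4, 10, 10)),
                                motion_threshold = 0.2), 5)
  # half moving at 2, half static, fixed threshold 0.5: static half excluded
  u2 <- matrix(0, 10, 10); u2[, 1:5] <- 2
  sp <- frame_flow_speed(mkflow(u2, matrix(0, 10, 10)), motion_threshold = 0.5,
                         statistic = "thresholded_mean")
  expect_equal(sp, 2)
  expect_equal(frame_flow_speed(mkflow(u2, matrix(0, 10, 10)),
                                motion_threshold = 0.5), 2)  # median agrees
  # all invalid: zero with QC attribute
  z <- frame_flow_speed(mkflow(u, v, valid = matrix(FALSE, 20, 20)))
  expect_equal(as.numeric(z), 0)
  expect_equal(attr(z, "qc"), "all_invalid")
  # frobenius variant is the RMS magnitude
  expect_equal(frame_flow_speed(mkflow(u2, matrix(0, 10, 10)),
                                statistic = "frobenius"), sqrt(mean(u2^2)))
})

test_that("physical velocity conversion and QC banding", {
  calib <- calibration(0.5, 200, "zebrafish")
  v <- to_physical_velocity(1.5, calib)
  expect_equal(as.numeric(v), 150)
  expect_true(attr(v, "qc_out_of_range"))  # 150 um/s < 300 um/s band floor
  expect_equal(as.numeric(to_physical_velocity(0, calib)), 0)
  inside <- to_physical_velocity(4, calib)   # 400 um/s
  expect_false(attr(inside, "qc_out_of_range"))
  # flagged values are never clamped
  high <- to_physical_velocity(20, calib)    # 2000 um/s, above the band
  expect_equal(as.numeric(high), 2000)
  expect_true(attr(high, "qc_out_of_range"))
  # medaka preset has no band: nothing flagged
  med <- to_physical_velocity(20, calibration(0.5, 200, "medaka"))
  expect_false(attr(med, "qc_out_of_range"))
  expect_error(calibration(-1, 200), "positive")
  expect_error(calibration(0.5, 200, "custom"), "range_mm_s")
})

test_that("Savitzky-Golay smoothing reproduces quadratics exactly", {
  x <- seq_len(31)
  quad <- 2 + 0.3 * x - 0.01 * x^2
  for (w in c(5, 11, 21)) {
    expect_equal(smooth_trace(quad, w), quad, tolerance = 1e-9)
  }
  expect_identical(smooth_trace(quad, 1), quad)
  expect_equal(smooth_trace(rep(3, 15), 7), rep(3, 15))
  expect_error(smooth_trace(quad, 4), "odd")
  expect_error(smooth_trace(quad, 33), "length")
})

test_that("hampel despiking removes isolated spikes but keeps smooth oscillation", {
  x <- rep(4, 21); x[11] <- 16
  expect_equal(hampel_despike(x)[11], 4)
  expect_equal(hampel_despike(x)[-11], x[-11])
  wave <- 400 + 150 * sin(seq(0, 4 * pi, length.out = 60))
  expect_equal(hampel_despike(wave), wave)  # physiological pulsatility untouched
})

test_that("cells_per_frame counts qualifying contours with the edge rule", {
  m <- matrix(FALSE, 40, 80)
  for (cx in c(10, 30, 50, 70)) m[disc_mask(40, 80, 20, cx, 3)] <- TRUE
  expect_equal(cells_per_frame(m, min_area = 10, max_area = 100), 4)
  expect_equal(cells_per_frame(matrix(FALSE, 10, 10)), 0)
  # a disc sliced by the right edge is excluded; by the left edge, counted
  m2 <- matrix(FALSE, 40, 80)
  m2[disc_mask(40, 80, 20, 79, 4)] <- TRUE
  m2[disc_mask(40, 80, 20, 2, 4)] <- TRUE
  expect_equal(cells_per_frame(m2, min_area = 5, max_area = 100), 1)
  expect_equal(cells_per_frame(m2, min_area = 5, max_area = 100,
                               edge_rule = "none"), 2)
  # area bounds reject specks and clumps
  m3 <- matrix(FALSE, 40, 80)
  m3[5, 5] <- TRUE                      # speck, area 1
  m3[disc_mask(40, 80, 20, 40, 10)] <- TRUE  # clump, area ~314
  expect_equal(cells_per_frame(m3, min_area = 8, max_area = 100), 0)
})

test_that("cell flux follows the line-crossing closed form and its properties", {
  expect_equal(cells_per_second(2, 5, 2.5, 30), 30)
  expect_equal(cells_per_second(2, 5, 0, 30), 0)
  base <- cells_per_second(3, 11, 4, 200)
  expect_equal(cells_per_second(3, 11, 8, 200), 2 * base)  # linear in speed
  expect_equal(cells_per_second(6, 11, 4, 200), 2 * base)  # linear in rows
  expect_error(cells_per_second(2, 0, 1, 30), "positive")
  # printed-form compatibility flag: rows * width / speed, accumulated per s
  expect_equal(cells_per_second(2, 5, 2.5, 30, formula = "printed"),
               30 * 2 * 5 / 2.5)
})

test_that("cell flux closed form matches a line-crossing simulation oracle", {
  # oracle: advect disc centers at constant speed and count crossings of a
  # fixed transverse line over one second
  rows <- 2; spacing <- 5; speed <- 2.5; fps <- 30
  starts <- unlist(lapply(1:rows, function(r) seq(0, 1000, by = spacing)))
  line_x <- 500
  crossings <- sum(starts < line_x & starts + speed * fps >= line_x)
  expect_equal(cells_per_second(rows, spacing, speed, fps), crossings)
})

test_that("cell geometry: single and stacked rows of discs", {
  h <- 30; w <- 120
  one <- matrix(FALSE, h, w)
  for (cx in seq(10, 110, by = 12)) one[disc_mask(h, w, 15, cx, 3)] <- TRUE
  g1 <- estimate_cell_geometry(list(one), roi = NULL, min_area = 8, max_area = 100)
  expect_equal(g1$rows, 1L)
  expect_equal(g1$cell_width, 6, tolerance = 0.2)
  expect_equal(g1$pitch, 12, tolerance = 0.2)
  two <- one
  # second row two diameters up so the stacked discs stay 8-disconnected
  for (cx in seq(10, 110, by = 12)) two[disc_mask(h, w, 7, cx, 3)] <- TRUE
  g2 <- estimate_cell_geometry(list(two), roi = NULL, min_area = 8, max_area = 100)
  expect_equal(g2$rows, 2L)
  expect_error(estimate_cell_geometry(list(matrix(FALSE, 10, 10)), NULL),
               "manually")
})

test_that("summaries carry exact means and round-trip through CSV", {
  calib <- calibration(0.5, 200)
  flows <- list(mkflow(matrix(4, 20, 20), matrix(0, 20, 20)),
                mkflow(matrix(4, 20, 20), matrix(0, 20, 20)))
  tr <- velocity_trace(flows, NULL, calib, smooth_window = 1)
  expect_equal(tr$mean_speed, 400)
  expect_equal(tr$per_frame_speed, tr$smoothed)
  expect_equal(glance(tr)$mean_um_s, 400)
  roi <- roi_rect(0, 0, 20, 20)
  rec <- summarize_video("v1", tr, NULL, roi, "abc")
  expect_equal(rec$mean_velocity_um_s, 400)
  expect_equal(rec$sd_velocity_um_s, 0)
  csv <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(rec, csv, row.names = FALSE)
  back <- utils::read.csv(csv)
  expect_equal(back$mean_velocity_um_s, rec$mean_velocity_um_s)
  expect_equal(back$video, "v1")
  # two-sample trace mean
  fl2 <- list(mkflow(matrix(1, 8, 8), matrix(0, 8, 8)),
              mkflow(matrix(3, 8, 8), matrix(0, 8, 8)))
  tr2 <- velocity_trace(fl2, NULL, calib, smooth_window = 1)
  expect_equal(mean(tr2$per_frame_speed), 200)
})
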