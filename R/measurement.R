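# From flow fields to physiology: per-frame speeds inside the ROI, physical
# units via the calibration, Savitzky-Golay trace smoothing, per-frame cell
# counts from contours, and the per-second cell flux.

#' Flow speed inside an ROI
#'
#' Displacement magnitude `sqrt(u^2 + v^2)` summarized over the valid ROI
#' pixels whose magnitude reaches `motion_threshold`. The threshold excludes
#' static vessel-wall and plasma pixels, which would otherwise bias the
#' statistic toward zero; if no pixel qualifies (e.g. between heartbeats) all
#' valid ROI pixels are used instead, so the statistic is never computed on
#' an empty set. The default summary is the spatial *median*, which is
#' robust to the small outlier populations that dense periodic cell patterns
#' can produce in gradient-based flow; the spatial mean is available as
#' `"thresholded_mean"`. An all-invalid ROI yields 0 with attribute
#' `qc = "all_invalid"`.
#'
#' @param flow A `flow_field` (see [farneback_flow()]).
#' @param roi An [roi_rect()] inside the flow field; `NULL` = whole field.
#' @param motion_threshold Minimum magnitude (px/frame) for a pixel to count
#'   as moving: a fixed number, or `"adaptive"` for
#'   `max(0.2, 0.25 * q90)` where `q90` is the 90th percentile of the valid
#'   ROI magnitudes -- a cut that scales with the flow itself, so slow and
#'   fast vessels are treated alike.
#' @param statistic `"thresholded_median"` (default), `"thresholded_mean"`,
#'   or `"frobenius"`: the Frobenius norm of the ROI displacement matrix
#'   divided by sqrt(n pixels), a root-mean-square variant retained for
#'   comparability with normalization-based implementations.
#' @return Scalar speed in px/frame.
#' @export
frame_flow_speed <- function(flow, roi = NULL, motion_threshold = "adaptive",
                             statistic = c("thresholded_median",
                                           "thresholded_mean", "frobenius")) {
  statistic <- match.arg(statistic)
  u <- flow$u; v <- flow$v; valid <- flow$valid
  if (!is.null(roi)) {
    u <- apply_roi(u, roi); v <- apply_roi(v, roi); valid <- apply_roi(valid, roi)
  }
  mag <- sqrt(u^2 + v^2)
  if (!any(valid)) {
    return(structure(0, qc = "all_invalid"))
  }
  if (statistic == "frobenius") {
    return(sqrt(sum(mag[valid]^2) / sum(valid)))
  }
  if (identical(motion_threshold, "adaptive")) {
    motion_threshold <- max(0.2, 0.25 * stats::quantile(mag[valid], 0.9,
                                                        names = FALSE))
  }
  moving <- valid & (mag >= motion_threshold)
  vals <- if (any(moving)) mag[moving] else mag[valid]
  if (statistic == "thresholded_median") stats::median(vals) else mean(vals)
}

#' Convert a pixel-per-frame speed to physical units
#'
#' `speed_px_per_frame * um_per_px * acquisition_fps`, in micrometers per
#' second. The conversion always uses the acquisition frame rate -- the
#' physical time base -- never the playback rate, so slow-motion relabelling
#' cannot bias the velocity.
#'
#' @param speed_px_per_frame Speed in pixels per acquisition-frame interval.
#' @param calib A [calibration()].
#' @return Speed in um/s, with attribute `qc_out_of_range` flagging values
#'   outside the calibration's species band (values are flagged, never
#'   clamped).
#' @export
to_physical_velocity <- function(speed_px_per_frame, calib) {
  stopifnot(inherits(calib, "calibration"))
  v <- speed_px_per_frame * calib$um_per_px * calib$acquisition_fps
  rng <- calib$range_mm_s * 1000  # mm/s -> um/s
  flag <- if (all(is.finite(rng))) v < rng[1] | v > rng[2] else rep(FALSE, length(v))
  structure(as.numeric(v), qc_out_of_range = flag)
}

#' Hampel despiking of a trace
#'
#' Replaces samples that deviate from their local rolling median by more than
#' `t0` scaled median absolute deviations (with a 5% relative floor on the
#' scale, so near-constant traces are not over-triggered) with that median.
#' Removes the rare single-pair tracking failures that dense, quasi-periodic
#' cell patterns can induce in gradient-based flow, while leaving smooth
#' physiological oscillation (cardiac-cycle scale at a 200 fps acquisition)
#' untouched.
#'
#' @param x Numeric series.
#' @param half_window Samples on each side of the rolling window.
#' @param t0 Outlier threshold in robust standard deviations.
#' @return The despiked series.
#' @export
hampel_despike <- function(x, half_window = 3L, t0 = 5) {
  n <- length(x)
  if (n < 3) return(x)
  out <- x
  for (i in seq_len(n)) {
    win <- x[max(1, i - half_window):min(n, i + half_window)]
    med <- stats::median(win)
    scale <- max(1.4826 * stats::median(abs(win - med)), 0.05 * abs(med), 1e-12)
    if (abs(x[i] - med) > t0 * scale) out[i] <- med
  }
  out
}

#' Savitzky-Golay smoothing of a velocity (or count) trace
#'
#' Order-2 Savitzky-Golay filter; the first and last half-windows are fitted
#' with the filter's asymmetric edge polynomials rather than padded, so a
#' quadratic series is reproduced exactly at every point. `window = 1` is the
#' identity.
#'
#' @param raw Numeric series.
#' @param window Odd window length, `<= length(raw)`.
#' @return The smoothed series, same length.
#' @export
smooth_trace <- function(raw, window = 11L) {
  if (window %% 2 == 0) stop("smoothing window must be odd", call. = FALSE)
  if (window > length(raw)) stop("window exceeds series length", call. = FALSE)
  if (window <= 3) return(as.numeric(raw))  # order-2 fit through <=3 points is exact
  as.numeric(signal::sgolayfilt(as.numeric(raw), p = 2, n = window))
}

#' Build a velocity trace from a clip's flow fields
#'
#' Computes one [frame_flow_speed()] per consecutive frame pair, converts to
#' um/s with the calibration, despikes ([hampel_despike()]) and smooths
#' ([smooth_trace()]) into the `smoothed` series, and attaches QC flags for
#' raw samples outside the species velocity band. The raw series is kept
#' untouched (`per_frame_speed`); all summary statistics are computed over
#' the smoothed series.
#'
#' @param flows List of `flow_field`s (length `n_frames - 1`).
#' @param roi [roi_rect()] or `NULL`.
#' @param calib A [calibration()].
#' @param motion_threshold Passed to [frame_flow_speed()].
#' @param smooth_window Passed to [smooth_trace()].
#' @return An object of class `velocity_trace`; tidy with [tidy()], summarize
#'   with [glance()].
#' @export
velocity_trace <- function(flows, roi, calib, motion_threshold = "adaptive",
                           smooth_window = 11L) {
  px <- vapply(flows, frame_flow_speed, numeric(1), roi = roi,
               motion_threshold = motion_threshold)
  um <- to_physical_velocity(px, calib)
  qc <- attr(um, "qc_out_of_range")
  smooth_window <- min(smooth_window, if (length(um) %% 2 == 1) length(um) else length(um) - 1L)
  sm <- smooth_trace(hampel_despike(as.numeric(um)), smooth_window)
  structure(list(per_frame_speed = as.numeric(um), smoothed = sm,
                 mean_speed = mean(um), qc_flags = qc,
                 acquisition_fps = calib$acquisition_fps),
            class = "velocity_trace")
}

#' @export
print.velocity_trace <- function(x, ...) {
  cat(sprintf("<velocity_trace> %d samples | mean %.4g um/s | sd %.4g | %d QC-flagged\n",
              length(x$per_frame_speed), x$mean_speed,
              stats::sd(x$per_frame_speed), sum(x$qc_flags)))
  invisible(x)
}

#' @rdname velocity_trace
#' @param x A `velocity_trace`.
#' @param ... Unused.
#' @method tidy velocity_trace
#' @export
tidy.velocity_trace <- function(x, ...) {
  n <- length(x$per_frame_speed)
  tibble::tibble(frame = seq_len(n),
                 t_seconds = (seq_len(n) - 1) / x$acquisition_fps,
                 raw_um_s = x$per_frame_speed,
                 smoothed_um_s = x$smoothed,
                 qc_flag = x$qc_flags)
}

#' @rdname velocity_trace
#' @method glance velocity_trace
#' @export
glance.velocity_trace <- function(x, ...) {
  tibble::tibble(mean_um_s = mean(x$smoothed), sd_um_s = stats::sd(x$smoothed),
                 mean_raw_um_s = x$mean_speed,
                 n_samples = length(x$per_frame_speed),
                 n_qc_flagged = sum(x$qc_flags))
}

#' Count cells in one frame's mask within an ROI
#'
#' Crops the mask to the ROI, traces contours ([trace_contours()]) and counts
#' the outer contours whose filled pixel area lies within `[min_area,
#' max_area]`. The area bounds reject noise specks and merged clumps; they are
#' magnification-dependent and must be set for the recording scale.
#'
#' @param mask Logical matrix (cells = `TRUE`; see [binarize()] dark mode).
#' @param roi [roi_rect()] or `NULL` for the whole mask.
#' @param min_area,max_area Filled-area bounds in px^2, `0 < min < max`.
#' @param edge_rule `"exclude_right"` (default) drops contours touching the
#'   ROI's right (downstream) edge -- the unbiased counting-frame rule: a cell
#'   sliced by the ROI boundary appears as two partial contours (entering at
#'   the left edge, exiting at the right), and counting only the entering
#'   piece counts each cell exactly once in expectation. `"none"` counts
#'   every qualifying contour.
#' @return Integer cell count.
#' @export
cells_per_frame <- function(mask, roi = NULL, min_area = 8, max_area = 400,
                            edge_rule = c("exclude_right", "none")) {
  stopifnot(min_area > 0, min_area < max_area)
  edge_rule <- match.arg(edge_rule)
  if (!is.null(roi)) mask <- apply_roi(mask, roi)
  ct <- trace_contours(mask)
  ct <- ct[ct$type == "outer", , drop = FALSE]
  if (edge_rule == "exclude_right" && nrow(ct) > 0) {
    ct <- ct[ct$x0 + ct$width < ncol(mask), , drop = FALSE]
  }
  sum(ct$n_pixels >= min_area & ct$n_pixels <= max_area)
}

#' Cell flux through the vessel, in cells per second
#'
#' The number of cells crossing a fixed transverse line per second. With
#' `rows` parallel single-file cell rows moving at `speed_px_per_frame` and a
#' mean along-flow cell extent of `cell_width` pixels, each row delivers
#' `speed / cell_width` cells per frame, so the flux is
#' `rows * speed / cell_width * acquisition_fps`. Accumulating the printed
#' per-frame form over one second of frames is available as
#' `formula = "printed"` for compatibility; note its operand order
#' (`rows * cell_width / speed`) is not dimensionally a flux and is retained
#' only for comparison against legacy outputs.
#'
#' @param rows Number of parallel cell rows across the vessel (>= 1).
#' @param cell_width Mean cell extent along the flow direction, px (> 0).
#' @param speed_px_per_frame Cell speed in px/frame (>= 0).
#' @param acquisition_fps Acquisition frame rate (1/s).
#' @param formula `"flux"` (default) or `"printed"` (legacy accumulation).
#' @return Cells per second.
#' @export
cells_per_second <- function(rows, cell_width, speed_px_per_frame,
                             acquisition_fps, formula = c("flux", "printed")) {
  formula <- match.arg(formula)
  stopifnot(rows >= 1, acquisition_fps > 0, speed_px_per_frame >= 0)
  if (cell_width <= 0) stop("cell_width must be positive", call. = FALSE)
  if (formula == "flux") {
    rows * speed_px_per_frame / cell_width * acquisition_fps
  } else {
    if (speed_px_per_frame == 0) return(0)
    acquisition_fps * rows * cell_width / speed_px_per_frame
  }
}

#' Estimate cell geometry (rows and width) from segmented masks
#'
#' `cell_width` is the median equivalent diameter `2 sqrt(area / pi)` of the
#' qualifying contours pooled across frames. The row count scales the mean
#' transverse fill by the circular cell shape: for each mask column that
#' intersects at least one cell, the cell-pixel count is the locally stacked
#' cell height; since the mean chord of a disc is `(pi/4)` of its diameter,
#' the mean fill divided by `(pi/4) * cell_width`, rounded and floored at 1,
#' is the number of parallel cell rows (exact for stacked discs).
#'
#' @param masks List of logical masks (full frame).
#' @param roi [roi_rect()] within which to measure.
#' @param min_area,max_area Contour area bounds, as in [cells_per_frame()].
#' @return A list with `rows` (integer >= 1), `cell_width` (px, median
#'   equivalent diameter) and `pitch` (px, median center-to-center advance
#'   between along-flow neighbors; equals `cell_width` when too few neighbor
#'   pairs are observed).
#' @export
estimate_cell_geometry <- function(masks, roi, min_area = 8, max_area = 400) {
  areas <- numeric(0)
  fills <- numeric(0)
  gaps <- numeric(0)
  for (m in masks) {
    mm <- if (is.null(roi)) m else apply_roi(m, roi)
    ct <- trace_contours(mm)
    ct <- ct[ct$type == "outer" & ct$n_pixels >= min_area & ct$n_pixels <= max_area, ,
             drop = FALSE]
    if (nrow(ct) == 0L) next
    # contours cut by the ROI's left/right edge are partial cells: keep them
    # out of the size statistics
    whole <- ct$x0 > 0L & ct$x0 + ct$width < ncol(mm)
    areas <- c(areas, ct$n_pixels[whole])
    # transverse fill: cell pixels per column, over columns touching a cell
    keep <- matrix(FALSE, nrow(mm), ncol(mm))
    cen <- matrix(NA_real_, nrow(ct), 2)
    for (i in seq_len(nrow(ct))) {
      pts <- ct$points[[i]]
      y0 <- min(pts[, 1]); y1 <- max(pts[, 1]); x0 <- min(pts[, 2]); x1 <- max(pts[, 2])
      keep[y0:y1, x0:x1] <- TRUE
      cen[i, ] <- c(mean(pts[, 1]), mean(pts[, 2]))
    }
    colfill <- colSums(mm & keep)
    fills <- c(fills, colfill[colfill > 0])
    # along-flow pitch: nearest same-row neighbor distance between whole-cell
    # centroids
    cw <- cen[whole, , drop = FALSE]
    if (nrow(cw) >= 2) {
      for (i in seq_len(nrow(cw))) {
        same <- abs(cw[, 1] - cw[i, 1]) < 3 & seq_len(nrow(cw)) != i
        if (any(same)) {
          gaps <- c(gaps, min(abs(cw[same, 2] - cw[i, 2])))
        }
      }
    }
  }
  if (length(areas) == 0L) {
    stop("no qualifying cell contours; supply rows and cell_width manually",
         call. = FALSE)
  }
  cell_width <- stats::median(2 * sqrt(areas / pi))
  # circular cells: the mean chord of a disc is (pi/4) * diameter, so the
  # stacked height of k rows averages k * (pi/4) * cell_width per column
  rows <- max(1L, as.integer(round(mean(fills) / (cell_width * pi / 4))))
  # center-to-center advance per cell along the flow; this is the length a
  # row moves to deliver one cell, so it (not the thresholded core diameter)
  # converts speed into flux. Falls back to cell_width for sparse scenes.
  pitch <- if (length(gaps) >= 5) {
    max(stats::median(gaps), cell_width)
  } else {
    cell_width
  }
  list(rows = rows, cell_width = cell_width, pitch = pitch)
}

#' Per-frame and per-second cell counts for a clip
#'
#' @param masks List of per-frame cell masks (dark-mode [binarize()] output).
#' @param roi [roi_rect()] or `NULL`.
#' @param speed_px_per_frame Measured cell speed, px/frame (for the flux).
#' @param acquisition_fps Acquisition frame rate.
#' @param min_area,max_area Contour area bounds.
#' @param geometry Optional list `(rows, cell_width, pitch)`; estimated from
#'   the masks with [estimate_cell_geometry()] when `NULL`. The flux uses
#'   `pitch` (center-to-center cell advance) when present, else `cell_width`.
#' @return An object of class `cell_count_result`: `per_frame_count`,
#'   `per_second_count`, `avg_per_frame`, `geometry`.
#' @export
count_cells <- function(masks, roi, speed_px_per_frame, acquisition_fps,
                        min_area = 8, max_area = 400, geometry = NULL) {
  per_frame <- vapply(masks, cells_per_frame, numeric(1), roi = roi,
                      min_area = min_area, max_area = max_area)
  if (is.null(geometry)) {
    geometry <- estimate_cell_geometry(masks, roi, min_area, max_area)
  }
  pitch <- if (!is.null(geometry$pitch)) geometry$pitch else geometry$cell_width
  per_sec <- cells_per_second(geometry$rows, pitch,
                              speed_px_per_frame, acquisition_fps)
  structure(list(per_frame_count = per_frame,
                 per_second_count = per_sec,
                 avg_per_frame = mean(per_frame),
                 geometry = geometry),
            class = "cell_count_result")
}

#' @export
print.cell_count_result <- function(x, ...) {
  cat(sprintf("<cell_count_result> avg %.3g cells/frame | %.3g cells/s | %d rows, cell width %.3g px\n",
              x$avg_per_frame, x$per_second_count, x$geometry$rows,
              x$geometry$cell_width))
  invisible(x)
}

#' @rdname count_cells
#' @param x A `cell_count_result`.
#' @param ... Unused.
#' @method tidy cell_count_result
#' @export
tidy.cell_count_result <- function(x, ...) {
  tibble::tibble(frame = seq_along(x$per_frame_count),
                 cells_in_frame = x$per_frame_count)
}

#' @rdname count_cells
#' @method glance cell_count_result
#' @export
glance.cell_count_result <- function(x, ...) {
  tibble::tibble(avg_cells_per_frame = x$avg_per_frame,
                 cells_per_second = x$per_second_count,
                 rows = x$geometry$rows, cell_width_px = x$geometry$cell_width)
}

#' One-row summary record for a processed video
#'
#' @param id Video identifier.
#' @param trace A `velocity_trace`.
#' @param counts A `cell_count_result` (or `NULL` if counting failed).
#' @param roi The [roi_rect()] used.
#' @param params_hash Short hash of the resolved run parameters.
#' @return A one-row tibble with a fixed column order.
#' @export
summarize_video <- function(id, trace, counts, roi, params_hash = "") {
  tibble::tibble(
    video = id,
    mean_velocity_um_s = mean(trace$smoothed),
    sd_velocity_um_s = stats::sd(trace$smoothed),
    avg_cells_per_frame = if (is.null(counts)) NA_real_ else counts$avg_per_frame,
    cells_per_second = if (is.null(counts)) NA_real_ else counts$per_second_count,
    n_qc_flagged = sum(trace$qc_flags),
    roi_x0 = roi$x0, roi_y0 = roi$y0,
    roi_width = roi$width, roi_height = roi$height,
    params_hash = params_hash)
}
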