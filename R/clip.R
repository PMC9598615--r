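# Video clip carrier: an ordered list of grayscale frames plus the two time
# bases (acquisition vs playback) and the spatial calibration.

#' Construct a video clip
#'
#' A `video_clip` is the pipeline's carrier: an ordered list of grayscale
#' frames (numeric matrices in `[0, 1]`, identical dimensions, origin top-left)
#' together with the physical acquisition frame rate, the presentation playback
#' frame rate and an optional spatial calibration. All velocity computation
#' uses `acquisition_fps`; `playback_fps` only affects how long the clip takes
#' to watch (see [relabel_playback()]).
#'
#' @param frames List of numeric matrices, all the same dimensions, values in
#'   `[0, 1]`, at least 8x8 pixels.
#' @param acquisition_fps Physical recording rate, frames per second.
#' @param playback_fps Presentation rate, frames per second. Defaults to the
#'   acquisition rate.
#' @param um_per_px Micrometers per pixel, or `NA` when uncalibrated. Required
#'   by [to_physical_velocity()].
#' @return An object of class `video_clip`.
#' @export
#' @examples
#' frames <- replicate(4, matrix(runif(64), 8, 8), simplify = FALSE)
#' clip <- video_clip(frames, acquisition_fps = 200, um_per_px = 0.5)
#' clip
video_clip <- function(frames, acquisition_fps, playback_fps = acquisition_fps,
                       um_per_px = NA_real_) {
  if (!is.list(frames) || length(frames) < 2L) {
    stop("a video clip needs at least 2 frames", call. = FALSE)
  }
  frames <- lapply(frames, validate_frame)
  dims <- vapply(frames, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    stop("all frames must share the same dimensions", call. = FALSE)
  }
  if (!is.numeric(acquisition_fps) || acquisition_fps <= 0) {
    stop("acquisition_fps must be positive", call. = FALSE)
  }
  if (!is.numeric(playback_fps) || playback_fps <= 0) {
    stop("playback_fps must be positive", call. = FALSE)
  }
  structure(
    list(frames = frames, acquisition_fps = as.numeric(acquisition_fps),
         playback_fps = as.numeric(playback_fps),
         um_per_px = as.numeric(um_per_px)),
    class = "video_clip"
  )
}

#' @keywords internal
validate_frame <- function(f) {
  if (!is.matrix(f) || !is.numeric(f)) stop("frame must be a numeric matrix", call. = FALSE)
  if (nrow(f) < 8L || ncol(f) < 8L) stop("frames must be at least 8x8 pixels", call. = FALSE)
  if (any(!is.finite(f))) stop("frame contains non-finite values", call. = FALSE)
  if (min(f) < 0 || max(f) > 1) stop("frame intensities must lie in [0, 1]", call. = FALSE)
  f
}

#' @export
print.video_clip <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat(sprintf(
    "<video_clip> %d frames of %dx%d px | acquisition %.6g fps | playback %.6g fps | %s\n",
    n_frames(x), d[1], d[2], x$acquisition_fps, x$playback_fps,
    if (is.na(x$um_per_px)) "uncalibrated" else sprintf("%.4g um/px", x$um_per_px)))
  cat(sprintf("  acquisition duration %.4g s | playback duration %.4g s | slowdown %.4g-fold\n",
              n_frames(x) / x$acquisition_fps, n_frames(x) / x$playback_fps,
              slowdown_factor(x)))
  invisible(x)
}

#' Number of frames in a clip
#' @param clip A [video_clip()].
#' @return Integer frame count.
#' @export
n_frames <- function(clip) length(clip$frames)

#' Slow-motion factor of the current playback labelling
#'
#' Ratio of acquisition to playback frame rate: how many seconds of playback
#' one second of physical time occupies. A 200 fps recording relabelled for
#' 30 fps playback has a slowdown of 200/30 = 6.67.
#'
#' @param clip A [video_clip()].
#' @return Numeric slowdown factor.
#' @export
slowdown_factor <- function(clip) clip$acquisition_fps / clip$playback_fps

#' Relabel a clip's playback rate (slow motion)
#'
#' High-frame-rate recordings of embryonic blood flow are typically re-exported
#' at a low presentation rate so the motion can be inspected by eye. This is a
#' pure metadata operation: no frame is dropped, duplicated or resampled, and
#' the acquisition time base used for velocimetry is untouched.
#'
#' @param clip A [video_clip()].
#' @param target_playback_fps New presentation rate in frames per second.
#' @return The clip with `playback_fps` replaced.
#' @export
#' @examples
#' clip <- synthetic_vessel_clip(vessel_scene_params(n_frames = 10))$clip
#' slow <- relabel_playback(clip, 30)
#' slowdown_factor(slow)
relabel_playback <- function(clip, target_playback_fps) {
  stopifnot(inherits(clip, "video_clip"))
  if (!is.numeric(target_playback_fps) || target_playback_fps <= 0) {
    stop("target_playback_fps must be positive", call. = FALSE)
  }
  clip$playback_fps <- as.numeric(target_playback_fps)
  clip
}

#' Spatial and temporal calibration with a QC velocity band
#'
#' Bundles the micrometers-per-pixel scale, the acquisition frame rate and an
#' expected physiological velocity range. The range is used only to flag
#' implausible per-frame velocities for quality control; values are never
#' clamped. The built-in `"zebrafish"` preset uses the 0.3-1.5 mm/s band
#' typical of the embryonic dorsal aorta at 2-5 dpf; `"medaka"` has no
#' published band here and disables range QC unless a custom range is given.
#'
#' @param um_per_px Micrometers per pixel (> 0).
#' @param acquisition_fps Acquisition frame rate (1/s).
#' @param species One of `"zebrafish"`, `"medaka"`, `"custom"`.
#' @param range_mm_s Length-2 numeric `(low, high)` expected-velocity band in
#'   mm/s; required for `species = "custom"`, overrides the preset otherwise.
#' @return An object of class `calibration`.
#' @export
calibration <- function(um_per_px, acquisition_fps, species = "zebrafish",
                        range_mm_s = NULL) {
  species <- match.arg(species, c("zebrafish", "medaka", "custom"))
  if (!is.numeric(um_per_px) || is.na(um_per_px) || um_per_px <= 0) {
    stop("um_per_px must be a positive number", call. = FALSE)
  }
  if (!is.numeric(acquisition_fps) || acquisition_fps <= 0) {
    stop("acquisition_fps must be positive", call. = FALSE)
  }
  if (is.null(range_mm_s)) {
    range_mm_s <- switch(species,
      zebrafish = c(0.3, 1.5),
      medaka = c(NA_real_, NA_real_),
      custom = stop("species = 'custom' requires range_mm_s", call. = FALSE))
  }
  if (all(is.finite(range_mm_s)) && range_mm_s[1] >= range_mm_s[2]) {
    stop("range_mm_s must satisfy low < high", call. = FALSE)
  }
  structure(list(um_per_px = as.numeric(um_per_px),
                 acquisition_fps = as.numeric(acquisition_fps),
                 species = species,
                 range_mm_s = as.numeric(range_mm_s)),
            class = "calibration")
}

#' @export
print.calibration <- function(x, ...) {
  rng <- if (all(is.finite(x$range_mm_s))) {
    sprintf("QC band %.3g-%.3g mm/s", x$range_mm_s[1], x$range_mm_s[2])
  } else "no QC band"
  cat(sprintf("<calibration> %.4g um/px @ %.6g fps (%s, %s)\n",
              x$um_per_px, x$acquisition_fps, x$species, rng))
  invisible(x)
}

# Rec. 601 luma weights used for all RGB->gray conversion; declared in the
# frame-directory sidecar so ingested sources are reproducible.
LUMA_WEIGHTS <- c(r = 0.299, g = 0.587, b = 0.114)

#' Convert an RGB array to a grayscale frame
#'
#' Uses fixed Rec. 601 luma weights (0.299, 0.587, 0.114). Already-gray input
#' (a matrix, or an array with one channel) passes through unchanged, so the
#' conversion is idempotent.
#'
#' @param x A numeric matrix (returned as-is) or an H x W x 3 array in `[0, 1]`.
#' @return A numeric matrix in `[0, 1]`.
#' @export
rgb_to_gray <- function(x) {
  if (is.matrix(x)) return(x)
  if (length(dim(x)) == 3L && dim(x)[3] == 1L) return(x[, , 1])
  if (length(dim(x)) == 3L && dim(x)[3] >= 3L) {
    return(LUMA_WEIGHTS[["r"]] * x[, , 1] + LUMA_WEIGHTS[["g"]] * x[, , 2] +
             LUMA_WEIGHTS[["b"]] * x[, , 3])
  }
  stop("expected a matrix or an HxWx3 array", call. = FALSE)
}
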