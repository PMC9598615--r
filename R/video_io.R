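# Clip I/O. The canonical on-disk form is a "frame directory": numbered 16-bit
# grayscale TIFFs plus a JSON sidecar carrying the frame rates and calibration.
# This dialect is lossless at 16-bit quantization, so written clips round-trip
# exactly -- unlike codec containers, whose decoders are nondeterministic
# across builds and which this package therefore does not write.

FRAME_EXTS <- c("tif", "tiff", "png")
SIDECAR_NAME <- "clip.json"

#' Read a clip from a frame directory
#'
#' Reads a directory of numbered single-channel or RGB image frames (TIFF or
#' PNG; zero-padded numeric names so lexicographic order equals temporal
#' order). RGB frames are converted to grayscale with fixed Rec. 601 luma
#' weights ([rgb_to_gray()]). Frame-rate and calibration metadata come from
#' the arguments, falling back to the directory's JSON sidecar when present.
#' Codec containers (AVI/MP4) are not decodable here; convert them to a frame
#' directory first (any ffmpeg build can: `ffmpeg -i in.mp4 f_%06d.tif`).
#'
#' @param path Directory containing the frames.
#' @param acquisition_fps Physical recording rate; falls back to the sidecar.
#' @param um_per_px Micrometers per pixel; falls back to the sidecar, else `NA`.
#' @param playback_fps Presentation rate; falls back to the sidecar, else the
#'   acquisition rate.
#' @return A [video_clip()].
#' @export
read_clip <- function(path, acquisition_fps = NULL, um_per_px = NULL,
                      playback_fps = NULL) {
  if (!dir.exists(path)) {
    if (file.exists(path)) {
      stop("'", path, "' is a file; codec containers are not decodable in this ",
           "build -- convert to a frame directory (numbered TIFF/PNG) first",
           call. = FALSE)
    }
    stop("path not found: ", path, call. = FALSE)
  }
  files <- list.files(path, pattern = paste0("\\.(", paste(FRAME_EXTS, collapse = "|"), ")$"),
                      full.names = TRUE, ignore.case = TRUE)
  files <- sort(files)
  if (length(files) < 2L) {
    stop("fewer than 2 decodable frames in ", path, call. = FALSE)
  }
  side <- read_sidecar(file.path(path, SIDECAR_NAME))
  acquisition_fps <- acquisition_fps %||% side$acquisition_fps %||%
    stop("acquisition_fps not given and no sidecar present", call. = FALSE)
  playback_fps <- playback_fps %||% side$playback_fps %||% acquisition_fps
  um_per_px <- um_per_px %||% side$um_per_px %||% NA_real_
  frames <- lapply(files, read_frame_file)
  video_clip(frames, acquisition_fps = acquisition_fps,
             playback_fps = playback_fps, um_per_px = um_per_px)
}

#' @keywords internal
read_sidecar <- function(path) {
  if (!file.exists(path)) return(list())
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' @keywords internal
read_frame_file <- function(file) {
  ext <- tolower(tools::file_ext(file))
  img <- if (ext %in% c("tif", "tiff")) tiff::readTIFF(file) else png::readPNG(file)
  f <- rgb_to_gray(img)
  clamp01(f)
}

#' Write a clip as a lossless frame directory
#'
#' Writes numbered 16-bit grayscale TIFFs (`frame_000001.tif`, ...) plus a
#' JSON sidecar with the acquisition/playback frame rates, the calibration and
#' the luma weights used for any RGB ingest. Reading the directory back yields
#' pixel-identical frames at 16-bit quantization and identical metadata.
#'
#' @param clip A [video_clip()].
#' @param path Output directory (created if needed).
#' @return Invisibly, the output path.
#' @export
write_clip <- function(clip, path) {
  stopifnot(inherits(clip, "video_clip"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(path)) stop("cannot create output directory ", path, call. = FALSE)
  for (i in seq_along(clip$frames)) {
    f <- round(clip$frames[[i]] * 65535) / 65535
    tiff::writeTIFF(f, file.path(path, sprintf("frame_%06d.tif", i)),
                    bits.per.sample = 16L, compression = "none")
  }
  jsonlite::write_json(
    list(acquisition_fps = clip$acquisition_fps,
         playback_fps = clip$playback_fps,
         um_per_px = clip$um_per_px,
         n_frames = n_frames(clip),
         luma_weights = as.list(LUMA_WEIGHTS)),
    file.path(path, SIDECAR_NAME), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a) || (length(a) == 1L && is.na(a))) b else a
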