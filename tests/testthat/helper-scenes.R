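# Shared fixtures, all generated in code.

# smooth random texture in [0,1]; sigma controls feature size
textured_frame <- function(n = 128, sigma = 2, seed = 1) {
  set.seed(seed)
  f <- hemoflow:::gaussian_blur(matrix(stats::rnorm(n * n), n, n), sigma)
  (f - min(f)) / (max(f) - min(f))
}

# integer circular shift: content moves by +dx columns (right), +dy rows (down)
circshift <- function(m, dx, dy) {
  h <- nrow(m); w <- ncol(m)
  m[((seq_len(h) - 1 - dy) %% h) + 1, ((seq_len(w) - 1 - dx) %% w) + 1]
}

# sub-pixel translation by Fourier shift (periodic)
fourier_shift <- function(m, dx, dy) {
  h <- nrow(m); w <- ncol(m)
  ky <- c(0:floor(h / 2), -(ceiling(h / 2) - 1):-1)
  kx <- c(0:floor(w / 2), -(ceiling(w / 2) - 1):-1)
  ph <- outer(ky * dy / h, kx * dx / w, `+`)
  Re(stats::fft(stats::fft(m) * exp(-2i * pi * ph), inverse = TRUE)) / (h * w)
}

# filled disc mask
disc_mask <- function(h, w, cy, cx, r) {
  g <- hemoflow:::coord_grids(h, w)
  sqrt((g$x - cx)^2 + (g$y - cy)^2) <= r
}

# brute-force rigid oracle: exhaustive integer shift + parabolic refinement
# (independent of the package's FFT path); returns best (dx, dy)
brute_shift <- function(a, b, max_shift = 6) {
  hemoflow::block_match_shift(a, b, max_shift)
}

# independent 8-connected component counter (union-find over pixel pairs),
# used as the labeling oracle for contour tracing
count_components8 <- function(mask) {
  idx <- which(mask)
  if (length(idx) == 0) return(0L)
  h <- nrow(mask); w <- ncol(mask)
  id <- seq_len(h * w)
  find <- function(i) { while (id[i] != i) { id[i] <<- id[id[i]]; i <- id[i] }; i }
  union <- function(i, j) { ri <- find(i); rj <- find(j); if (ri != rj) id[ri] <<- rj }
  ys <- (idx - 1L) %% h + 1L; xs <- (idx - 1L) %/% h + 1L
  for (k in seq_along(idx)) {
    y <- ys[k]; x <- xs[k]
    for (d in list(c(-1L, 0L), c(0L, -1L), c(-1L, -1L), c(-1L, 1L))) {
      yy <- y + d[1]; xx <- x + d[2]
      if (yy >= 1L && yy <= h && xx >= 1L && xx <= w && mask[yy, xx]) {
        union(idx[k], (xx - 1L) * h + yy)
      }
    }
  }
  length(unique(vapply(idx, find, integer(1))))
}

# static clip from one frame
static_clip <- function(frame, n = 5, fps = 200, um_per_px = 0.5) {
  video_clip(replicate(n, frame, simplify = FALSE), acquisition_fps = fps,
             um_per_px = um_per_px)
}

# cache for expensive end-to-end runs shared between test files
.e2e_cache <- new.env(parent = emptyenv())

e2e_result <- function(speed, n_frames = 30, seed = NULL) {
  if (is.null(seed)) seed <- 100 + speed
  key <- sprintf("s%s_n%d_seed%d", speed, n_frames, seed)
  if (!is.null(.e2e_cache[[key]])) return(.e2e_cache[[key]])
  sim <- synthetic_vessel_clip(vessel_scene_params(n_frames = n_frames,
                                                   speed = speed, seed = seed))
  res <- analyze_clip(sim$clip, options = pipeline_options(stabilize = FALSE))
  out <- list(sim = sim, res = res, summary = as.data.frame(glance(res)))
  .e2e_cache[[key]] <- out
  out
}
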