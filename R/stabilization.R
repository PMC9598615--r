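# Jitter removal: estimate an interframe rigid Euclidean transform
# (translation + rotation, no scale -- scale or affine terms would absorb the
# biological motion we are trying to measure), accumulate the per-frame
# trajectory, low-pass it with a centered sliding window, and warp each frame
# by the smoothed-minus-raw residual.
#
# A transform T = (dx, dy, dtheta) maps a point p of frame A to its position
# in frame B as p' = R(dtheta) (p - c) + c + (dx, dy), with c the frame
# center. Composition and inversion are exact (rotation matrices), not
# small-angle approximations.

#' Construct a rigid (Euclidean) transform
#'
#' @param dx,dy Translation in pixels (x = columns rightward, y = rows
#'   downward).
#' @param dtheta Rotation in radians about the frame center.
#' @param low_confidence Flag set by [estimate_rigid_transform()] when the
#'   input was featureless.
#' @return An object of class `rigid_transform`.
#' @export
rigid_transform <- function(dx = 0, dy = 0, dtheta = 0, low_confidence = FALSE) {
  stopifnot(is.finite(dx), is.finite(dy), is.finite(dtheta))
  structure(list(dx = as.numeric(dx), dy = as.numeric(dy),
                 dtheta = as.numeric(dtheta),
                 low_confidence = isTRUE(low_confidence)),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat(sprintf("<rigid_transform> dx=%.4g dy=%.4g dtheta=%.4g rad%s\n",
              x$dx, x$dy, x$dtheta,
              if (x$low_confidence) " (low confidence)" else ""))
  invisible(x)
}

#' Compose two rigid transforms
#'
#' `compose_rigid(t2, t1)` applies `t1` first, then `t2`.
#' @param t2,t1 [rigid_transform()] objects.
#' @return The composed [rigid_transform()].
#' @export
compose_rigid <- function(t2, t1) {
  th <- t1$dtheta + t2$dtheta
  c2 <- cos(t2$dtheta); s2 <- sin(t2$dtheta)
  rigid_transform(
    dx = c2 * t1$dx - s2 * t1$dy + t2$dx,
    dy = s2 * t1$dx + c2 * t1$dy + t2$dy,
    dtheta = th)
}

#' Invert a rigid transform
#' @param t A [rigid_transform()].
#' @return The inverse [rigid_transform()].
#' @export
invert_rigid <- function(t) {
  ci <- cos(-t$dtheta); si <- sin(-t$dtheta)
  rigid_transform(
    dx = -(ci * t$dx - si * t$dy),
    dy = -(si * t$dx + ci * t$dy),
    dtheta = -t$dtheta)
}

# Warp a frame so its content is moved by `t`: out(p) = f(T^{-1}(p)).
# Out-of-frame samples replicate the border (cropping would shift ROI
# coordinates mid-pipeline).
#' @keywords internal
warp_rigid <- function(f, t) {
  g <- coord_grids(nrow(f), ncol(f))
  ctr <- frame_center(f)
  ti <- invert_rigid(t)
  ci <- cos(ti$dtheta); si <- sin(ti$dtheta)
  px <- g$x - ctr[1]; py <- g$y - ctr[2]
  xq <- ci * px - si * py + ctr[1] + ti$dx
  yq <- si * px + ci * py + ctr[2] + ti$dy
  sample_field(f, xq, yq)
}

# Sub-pixel translation by FFT phase correlation on Hann-windowed frames.
#' @keywords internal
phase_correlate <- function(a, b) {
  w <- hann_window(nrow(a), ncol(a))
  fa <- stats::fft(a * w); fb <- stats::fft(b * w)
  cp <- fb * Conj(fa)
  mag <- Mod(cp)
  cp <- cp / pmax(mag, 1e-12)
  r <- Re(stats::fft(cp, inverse = TRUE)) / length(cp)
  peak <- which.max(r)
  h <- nrow(r); wd <- ncol(r)
  py <- (peak - 1L) %% h + 1L
  px <- (peak - 1L) %/% h + 1L
  # 3-point parabolic sub-pixel refinement per axis (circular neighbors)
  sub <- function(vm, v0, vp) {
    den <- vm - 2 * v0 + vp
    if (abs(den) < 1e-12) 0 else 0.5 * (vm - vp) / den
  }
  ym <- r[(py - 2L) %% h + 1L, px]; yp <- r[py %% h + 1L, px]
  xm <- r[py, (px - 2L) %% wd + 1L]; xp <- r[py, px %% wd + 1L]
  dy <- py - 1L + sub(ym, r[py, px], yp)
  dx <- px - 1L + sub(xm, r[py, px], xp)
  if (dy > h / 2) dy <- dy - h
  if (dx > wd / 2) dx <- dx - wd
  list(dx = dx, dy = dy, peak = max(r))
}

# One Gauss-Newton pass per iteration on the global brightness-constancy
# equations: warp b back by the current estimate and solve the 2x2 normal
# equations for the residual shift. Removes the sub-pixel bias of the
# parabolic peak fit. Only photometric inliers (residual within 3 robust SDs)
# enter the solve, so independently moving content -- the blood column itself
# on a vessel scene -- cannot drag the camera-motion estimate.
#' @keywords internal
refine_translation <- function(a, b, dx, dy, iters = 2L) {
  h <- nrow(a); w <- ncol(a)
  m <- max(4L, ceiling(max(abs(dx), abs(dy))) + 2L)
  if (2L * m + 8L >= min(h, w)) return(c(dx, dy))
  rows <- (m + 1L):(h - m); cols <- (m + 1L):(w - m)
  k <- c(-0.5, 0, 0.5)
  for (it in seq_len(iters)) {
    bw <- warp_rigid(b, rigid_transform(-dx, -dy, 0))
    gx <- filter_axis(bw, k, "x", pad = "replicate")[rows, cols]
    gy <- filter_axis(bw, k, "y", pad = "replicate")[rows, cols]
    err <- (a - bw)[rows, cols]
    keep <- abs(err) <= 3 * max(stats::mad(err), 1e-6)
    gx <- gx[keep]; gy <- gy[keep]; errk <- err[keep]
    gxx <- sum(gx^2); gyy <- sum(gy^2); gxy <- sum(gx * gy)
    det <- gxx * gyy - gxy^2
    if (det < 1e-12) break
    bx <- sum(gx * errk); by <- sum(gy * errk)
    dx <- dx + (gyy * bx - gxy * by) / det
    dy <- dy + (gxx * by - gxy * bx) / det
  }
  c(dx, dy)
}

#' Estimate the rigid transform between two frames
#'
#' Translation is recovered to sub-pixel precision by FFT phase correlation on
#' Hann-windowed frames followed by a Gauss-Newton photometric refinement;
#' rotation (when `rotation = TRUE`) by a golden-section
#' search over the angle that maximizes the phase-correlation peak after
#' de-rotating `b`. Featureless (constant) frames return the identity with
#' `low_confidence = TRUE`.
#'
#' @param a,b Frames (numeric matrices) of identical dimensions.
#' @param rotation Search for a rotation component? Skipping it roughly halves
#'   the cost when the rig can only translate.
#' @param max_rotation Half-width of the rotation search interval, radians.
#' @return A [rigid_transform()] mapping `a` onto `b`.
#' @export
estimate_rigid_transform <- function(a, b, rotation = TRUE, max_rotation = 0.1) {
  stopifnot(is.matrix(a), is.matrix(b), all(dim(a) == dim(b)))
  if (stats::sd(a) < 1e-10 || stats::sd(b) < 1e-10) {
    return(rigid_transform(low_confidence = TRUE))
  }
  base <- phase_correlate(a, b)
  if (!rotation) {
    d <- refine_translation(a, b, base$dx, base$dy)
    return(rigid_transform(d[1], d[2], 0))
  }
  score <- function(th) phase_correlate(a, warp_rigid(b, rigid_transform(0, 0, -th)))$peak
  opt <- stats::optimize(score, c(-max_rotation, max_rotation),
                         maximum = TRUE, tol = 5e-4)
  th <- opt$maximum
  if (opt$objective <= base$peak + 1e-9) th <- 0  # rotation did not help
  b2 <- if (th == 0) b else warp_rigid(b, rigid_transform(0, 0, -th))
  pc <- if (th == 0) base else phase_correlate(a, b2)
  d <- refine_translation(a, b2, pc$dx, pc$dy)
  # the de-rotated correlation recovers the pre-rotation shift; compose it
  # back under rotate-after-shift to get this parametrization's translation
  compose_rigid(rigid_transform(0, 0, th), rigid_transform(d[1], d[2], 0))
}

#' Smooth a cumulative trajectory with a centered sliding window
#'
#' Each parameter (dx, dy, dtheta) is replaced by its centered moving average;
#' at the series ends the window is truncated to the available frames.
#' `window = 1` is the identity.
#'
#' @param traj A `trajectory` as returned by [stabilize()], or a list of
#'   [rigid_transform()]s.
#' @param window Odd window length in frames.
#' @return A trajectory of the same length.
#' @export
smooth_trajectory <- function(traj, window) {
  ts <- trajectory_transforms(traj)
  if (window %% 2 == 0) stop("smoothing window must be odd", call. = FALSE)
  if (window < 1 || window > length(ts)) {
    stop("window must be in [1, n_frames]", call. = FALSE)
  }
  mavg <- function(x) {
    h <- (window - 1) / 2
    vapply(seq_along(x), function(i) {
      mean(x[max(1, i - h):min(length(x), i + h)])
    }, numeric(1))
  }
  dx <- mavg(vapply(ts, `[[`, numeric(1), "dx"))
  dy <- mavg(vapply(ts, `[[`, numeric(1), "dy"))
  th <- mavg(vapply(ts, `[[`, numeric(1), "dtheta"))
  out <- lapply(seq_along(ts), function(i) rigid_transform(dx[i], dy[i], th[i]))
  structure(list(cumulative = out), class = "trajectory")
}

#' @keywords internal
trajectory_transforms <- function(traj) {
  if (inherits(traj, "trajectory")) traj$cumulative else traj
}

#' Tidy a trajectory into a tibble
#'
#' @param x A `trajectory` (see [stabilize()]).
#' @param ... Unused.
#' @return A tibble with `frame`, `dx`, `dy`, `dtheta`.
#' @method tidy trajectory
#' @export
tidy.trajectory <- function(x, ...) {
  ts <- x$cumulative
  tibble::tibble(
    frame = seq_along(ts),
    dx = vapply(ts, `[[`, numeric(1), "dx"),
    dy = vapply(ts, `[[`, numeric(1), "dy"),
    dtheta = vapply(ts, `[[`, numeric(1), "dtheta"))
}

#' Stabilize a clip by rigid trajectory smoothing
#'
#' Estimates the interframe rigid transform for every consecutive pair,
#' accumulates the cumulative camera trajectory (first frame = identity),
#' smooths it with a centered sliding window, and warps each frame by the
#' smoothed-minus-raw residual so only the low-frequency component of the
#' apparent camera motion survives. Frame count and shape never change;
#' out-of-frame pixels are filled by edge replication.
#'
#' @param clip A [video_clip()] with at least 2 frames.
#' @param window Odd smoothing window in frames. The default 15 spans about
#'   75 ms at a 200 fps acquisition rate: longer than single-frame jitter,
#'   shorter than cardiac-cycle-scale signal.
#' @param rotation Passed to [estimate_rigid_transform()].
#' @param exclude_rows Optional integer vector of frame rows (1-based) left
#'   out of transform *estimation* (the warp still covers the full frame).
#'   Camera motion must be estimated from the static anatomy; on scenes whose
#'   center is dominated by the flowing blood column, excluding the vessel
#'   rows stops the estimator from tracking the blood itself. Translations
#'   survive row deletion exactly, so estimation runs on the remaining rows
#'   concatenated; rotation search is disabled in this mode.
#' @return A list with `clip` (the stabilized [video_clip()]), `trajectory`
#'   (raw cumulative trajectory, for QC; tidy with [tidy()]) and
#'   `trajectory_smooth`.
#' @export
stabilize <- function(clip, window = 15, rotation = TRUE, exclude_rows = NULL) {
  stopifnot(inherits(clip, "video_clip"))
  n <- n_frames(clip)
  h <- nrow(clip$frames[[1]])
  keep <- seq_len(h)
  if (!is.null(exclude_rows)) {
    keep <- setdiff(keep, exclude_rows)
    if (length(keep) < 16L) {
      warning("fewer than 16 rows left after exclusion; estimating on full frames")
      keep <- seq_len(h)
    } else {
      rotation <- FALSE
    }
  }
  window <- min(window, if (n %% 2 == 1) n else n - 1)
  cum <- vector("list", n)
  cum[[1]] <- rigid_transform()
  for (i in 2:n) {
    t_i <- estimate_rigid_transform(clip$frames[[i - 1]][keep, , drop = FALSE],
                                    clip$frames[[i]][keep, , drop = FALSE],
                                    rotation = rotation)
    if (t_i$low_confidence) {
      warning("featureless frame pair at index ", i, "; using identity transform")
    }
    cum[[i]] <- compose_rigid(t_i, cum[[i - 1]])
  }
  raw <- structure(list(cumulative = cum), class = "trajectory")
  smo <- smooth_trajectory(raw, window)
  frames <- clip$frames
  for (i in seq_len(n)) {
    corr <- compose_rigid(smo$cumulative[[i]], invert_rigid(raw$cumulative[[i]]))
    if (abs(corr$dx) + abs(corr$dy) + abs(corr$dtheta) > 1e-9) {
      frames[[i]] <- clamp01(warp_rigid(clip$frames[[i]], corr))
    }
  }
  out <- clip
  out$frames <- frames
  list(clip = out, trajectory = raw, trajectory_smooth = smo)
}
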