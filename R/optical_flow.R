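# Dense optical flow by polynomial expansion (Farneback). Each frame is
# modelled per pixel as a local quadratic I(x) ~ x'Ax + b'x + c over a
# Gaussian-weighted neighborhood; for a pure translation d of an in-model
# signal the linear coefficients obey b2 = b1 - 2 A d, so d can be read off
# from the two expansions. The per-pixel solve is regularised by averaging
# the normal equations over a Gaussian window, and large displacements are
# handled coarse-to-fine over an image pyramid with iterative refinement.

#' Flow-engine parameters
#'
#' @param pyramid_levels Number of pyramid levels (>= 1). Level 1 is full
#'   resolution; the coarsest level must keep both dimensions >= 12 px, else
#'   the count is reduced with a warning. The default 4 keeps displacements
#'   up to the top of the physiological range (~15 px/frame at 0.5 um/px,
#'   200 fps) within about 2 px at the coarsest level, inside the
#'   displacement solver's convergence basin.
#' @param pyramid_scale Downscale factor per level, in (0, 1).
#' @param window Side length (px) of the Gaussian averaging window applied to
#'   the normal equations of the displacement solve.
#' @param iterations Refinement iterations per level.
#' @param poly_n Odd side length of the polynomial-expansion neighborhood.
#' @param poly_sigma Gaussian applicability width (px) of the expansion.
#' @return A list of class `farneback_params`.
#' @export
farneback_params <- function(pyramid_levels = 4L, pyramid_scale = 0.5,
                             window = 15L, iterations = 3L,
                             poly_n = 5L, poly_sigma = 1.1) {
  stopifnot(pyramid_levels >= 1, pyramid_scale > 0, pyramid_scale < 1,
            window >= 1, iterations >= 1, poly_n >= 3, poly_n %% 2 == 1,
            poly_sigma > 0)
  structure(list(pyramid_levels = as.integer(pyramid_levels),
                 pyramid_scale = pyramid_scale, window = as.integer(window),
                 iterations = as.integer(iterations), poly_n = as.integer(poly_n),
                 poly_sigma = poly_sigma),
            class = "farneback_params")
}

#' Spatio-temporal gradients of a frame pair
#'
#' Central-difference spatial gradients of the mean frame, and the temporal
#' difference `b - a`. These are the terms of the brightness-constancy
#' constraint `fx u + fy v + ft = 0`.
#'
#' @param a,b Frames of identical dimensions.
#' @return A list with matrices `fx`, `fy`, `ft`.
#' @export
gradients <- function(a, b) {
  stopifnot(all(dim(a) == dim(b)))
  m <- (a + b) / 2
  k <- c(-0.5, 0, 0.5)
  list(fx = filter_axis(m, k, "x", pad = "replicate"),
       fy = filter_axis(m, k, "y", pad = "replicate"),
       ft = b - a)
}

#' Per-pixel quadratic (polynomial) expansion of a frame
#'
#' Fits `I(x + e) ~ e' A e + b' e + c` by weighted least squares over the
#' `poly_n` x `poly_n` neighborhood of every pixel, with separable Gaussian
#' applicability weights of width `poly_sigma` and local coordinates
#' `e = (x, y)` centered at the pixel (x = columns rightward, y = rows
#' downward). Because the weights are fixed, the normal-equation matrix is
#' the same at every pixel and the fit reduces to six separable correlations
#' plus a constant linear solve. Borders use reflected padding.
#'
#' @param f A frame (numeric matrix).
#' @param poly_n Odd neighborhood side length (>= 3).
#' @param poly_sigma Gaussian applicability width in pixels.
#' @return An object of class `poly_expansion`: matrices `A11`, `A12`, `A22`
#'   (the symmetric quadratic term), `B1`, `B2` (linear term) and `C`.
#' @export
polynomial_expansion <- function(f, poly_n = 5L, poly_sigma = 1.1) {
  stopifnot(is.matrix(f), poly_n >= 3, poly_n %% 2 == 1)
  r <- (poly_n - 1L) %/% 2L
  a <- (-r):r
  w <- exp(-a^2 / (2 * poly_sigma^2))
  k0 <- w; k1 <- w * a; k2 <- w * a^2
  s0 <- sum(w); s2 <- sum(w * a^2); s4 <- sum(w * a^4)
  m1 <- sep_filter(f, k0, k0)  # sum w I
  m2 <- sep_filter(f, k1, k0)  # sum w x I
  m3 <- sep_filter(f, k0, k1)  # sum w y I
  m4 <- sep_filter(f, k2, k0)  # sum w x^2 I
  m5 <- sep_filter(f, k0, k2)  # sum w y^2 I
  m6 <- sep_filter(f, k1, k1)  # sum w xy I
  # (c, axx, ayy) couple through the even moments; x, y, xy terms decouple.
  M <- matrix(c(s0 * s0, s2 * s0, s2 * s0,
                s2 * s0, s4 * s0, s2 * s2,
                s2 * s0, s2 * s2, s4 * s0), 3, 3, byrow = TRUE)
  Mi <- solve(M)
  cc <- Mi[1, 1] * m1 + Mi[1, 2] * m4 + Mi[1, 3] * m5
  axx <- Mi[2, 1] * m1 + Mi[2, 2] * m4 + Mi[2, 3] * m5
  ayy <- Mi[3, 1] * m1 + Mi[3, 2] * m4 + Mi[3, 3] * m5
  structure(list(A11 = axx, A12 = (m6 / (s2 * s2)) / 2, A22 = ayy,
                 B1 = m2 / (s2 * s0), B2 = m3 / (s2 * s0), C = cc,
                 poly_n = poly_n, poly_sigma = poly_sigma),
            class = "poly_expansion")
}

#' Displacement field from two polynomial expansions
#'
#' Solves the translation relation `b2 = b1 - 2 A d` per pixel, i.e.
#' `d = -1/2 A^{-1} (b2 - b1)`, with `A = (A1 + A2) / 2`. When a prior flow is
#' supplied, the second expansion is sampled at the displaced positions and
#' the solve refines the prior. The per-pixel normal equations (`G = A'A`,
#' `h = A' db`) are averaged over a Gaussian window of side `window` before
#' solving, which propagates flow into locally flat regions; pixels whose
#' averaged `G` is ill-conditioned (condition number > 1e6) are marked
#' invalid and keep the prior (or zero).
#'
#' @param e1,e2 [polynomial_expansion()] objects of identical dimensions.
#' @param prior Optional prior flow field (list with matrices `u`, `v`).
#' @param window Averaging window side length (px); 1 disables averaging.
#' @return A `flow_field`: matrices `u`, `v` (pixels per frame interval;
#'   +x right, +y down) and logical `valid`.
#' @export
displacement_from_expansions <- function(e1, e2, prior = NULL, window = 15L) {
  stopifnot(inherits(e1, "poly_expansion"), inherits(e2, "poly_expansion"),
            all(dim(e1$A11) == dim(e2$A11)))
  h <- nrow(e1$A11); w <- ncol(e1$A11)
  if (!is.null(prior)) {
    g <- coord_grids(h, w)
    xq <- g$x + prior$u; yq <- g$y + prior$v
    A11b <- sample_field(e2$A11, xq, yq); A12b <- sample_field(e2$A12, xq, yq)
    A22b <- sample_field(e2$A22, xq, yq)
    B1b <- sample_field(e2$B1, xq, yq); B2b <- sample_field(e2$B2, xq, yq)
    pu <- prior$u; pv <- prior$v
  } else {
    A11b <- e2$A11; A12b <- e2$A12; A22b <- e2$A22; B1b <- e2$B1; B2b <- e2$B2
    pu <- matrix(0, h, w); pv <- matrix(0, h, w)
  }
  A11 <- (e1$A11 + A11b) / 2
  A12 <- (e1$A12 + A12b) / 2
  A22 <- (e1$A22 + A22b) / 2
  db1 <- -0.5 * (B1b - e1$B1) + A11 * pu + A12 * pv
  db2 <- -0.5 * (B2b - e1$B2) + A12 * pu + A22 * pv
  G11 <- A11^2 + A12^2
  G12 <- A12 * (A11 + A22)
  G22 <- A12^2 + A22^2
  h1 <- A11 * db1 + A12 * db2
  h2 <- A12 * db1 + A22 * db2
  if (window > 1) {
    rad <- (window - 1L) %/% 2L
    kw <- gaussian_kernel((window - 1) / 4, radius = rad)
    blur <- function(m) sep_filter(m, kw, kw)
    G11 <- blur(G11); G12 <- blur(G12); G22 <- blur(G22)
    h1 <- blur(h1); h2 <- blur(h2)
  }
  det <- G11 * G22 - G12^2
  tr <- G11 + G22
  disc <- sqrt(pmax(tr^2 - 4 * det, 0))
  lmin <- (tr - disc) / 2
  lmax <- (tr + disc) / 2
  valid <- is.finite(det) & lmax > 0 & lmin > lmax / 1e6
  dets <- ifelse(valid, det, 1)
  u <- (G22 * h1 - G12 * h2) / dets
  v <- (G11 * h2 - G12 * h1) / dets
  u[!valid] <- pu[!valid]
  v[!valid] <- pv[!valid]
  structure(list(u = u, v = v, valid = valid), class = "flow_field")
}

#' @export
print.flow_field <- function(x, ...) {
  mag <- sqrt(x$u^2 + x$v^2)
  cat(sprintf("<flow_field> %dx%d px | mean |d| %.3g px | %.1f%% valid\n",
              nrow(x$u), ncol(x$u), mean(mag[x$valid]), 100 * mean(x$valid)))
  invisible(x)
}

#' @keywords internal
pyramid_of <- function(f, levels, scale) {
  pyr <- vector("list", levels)
  pyr[[1]] <- f
  if (levels > 1) {
    blur_sigma <- 0.5 * sqrt(1 / scale^2 - 1)  # anti-alias before resampling (~0.87 at scale 0.5)
    for (l in 2:levels) {
      prev <- pyr[[l - 1]]
      sm <- gaussian_blur(prev, blur_sigma)
      pyr[[l]] <- resize_bilinear(sm, max(2L, round(nrow(prev) * scale)),
                                  max(2L, round(ncol(prev) * scale)))
    }
  }
  pyr
}

#' Dense optical flow between two frames
#'
#' Coarse-to-fine pyramidal flow: at each pyramid level both frames are
#' expanded with [polynomial_expansion()] and the displacement solve of
#' [displacement_from_expansions()] is iterated with the upsampled previous
#' estimate as prior. The returned displacements are in pixels per frame
#' interval at full resolution, mapping frame `a` (time t) to frame `b`
#' (time t+1).
#'
#' @param a,b Frames of identical dimensions, intensities in `[0, 1]`.
#' @param params A [farneback_params()].
#' @return A `flow_field` (see [displacement_from_expansions()]).
#' @export
#' @examples
#' p <- vessel_scene_params(n_frames = 2)
#' clip <- synthetic_vessel_clip(p)$clip
#' flow <- farneback_flow(clip$frames[[1]], clip$frames[[2]])
#' flow
farneback_flow <- function(a, b, params = farneback_params()) {
  stopifnot(is.matrix(a), is.matrix(b), all(dim(a) == dim(b)))
  levels <- params$pyramid_levels
  min_dim <- min(dim(a))
  while (levels > 1 && min_dim * params$pyramid_scale^(levels - 1) < 12) {
    levels <- levels - 1L
  }
  if (levels < params$pyramid_levels) {
    warning("frames too small for ", params$pyramid_levels,
            " pyramid levels; using ", levels)
  }
  pa <- pyramid_of(a, levels, params$pyramid_scale)
  pb <- pyramid_of(b, levels, params$pyramid_scale)
  flow <- NULL
  for (l in levels:1) {
    e1 <- polynomial_expansion(pa[[l]], params$poly_n, params$poly_sigma)
    e2 <- polynomial_expansion(pb[[l]], params$poly_n, params$poly_sigma)
    if (!is.null(flow)) {
      ry <- nrow(pa[[l]]) / nrow(flow$u)
      rx <- ncol(pa[[l]]) / ncol(flow$u)
      flow <- list(u = resize_bilinear(flow$u, nrow(pa[[l]]), ncol(pa[[l]])) * rx,
                   v = resize_bilinear(flow$v, nrow(pa[[l]]), ncol(pa[[l]])) * ry)
    }
    for (it in seq_len(params$iterations)) {
      flow <- displacement_from_expansions(e1, e2, prior = flow,
                                           window = params$window)
    }
  }
  flow
}

#' Summed directional flow components
#'
#' Sums the horizontal and vertical displacement planes of one or more flow
#' fields pixelwise: `H = sum of u`, `V = sum of v`. With the axis convention
#' used throughout (+x rightward), positive `H` is left-to-right motion --
#' the counting direction for arterial flow in trunk recordings.
#'
#' @param flows A single `flow_field` or a list of them, all the same shape.
#' @return A list of class `directional_flow` with matrices `H` and `V`.
#' @export
directional_components <- function(flows) {
  if (inherits(flows, "flow_field")) flows <- list(flows)
  if (!is.list(flows) || length(flows) == 0L) {
    stop("need at least one flow field", call. = FALSE)
  }
  H <- Reduce(`+`, lapply(flows, `[[`, "u"))
  V <- Reduce(`+`, lapply(flows, `[[`, "v"))
  structure(list(H = H, V = V), class = "directional_flow")
}

#' Exhaustive block-matching reference flow estimator
#'
#' Independent cross-check for the gradient-based flow engine, in the spirit
#' of correlation-based particle image velocimetry: the global translation
#' between two frames is found by exhaustive search over integer shifts
#' (minimum mean squared error on the overlapping interior), then refined to
#' sub-pixel precision by fitting a parabola to the error surface around the
#' minimum. It is deliberately simple and slow, and only estimates a single
#' global translation.
#'
#' @param a,b Frames of identical dimensions.
#' @param max_shift Search radius in pixels.
#' @return A list with `dx`, `dy` (pixels; content motion of `a` toward `b`).
#' @export
block_match_shift <- function(a, b, max_shift = 6L) {
  stopifnot(all(dim(a) == dim(b)))
  h <- nrow(a); w <- ncol(a)
  s <- as.integer(max_shift)
  stopifnot(h > 2 * s + 2, w > 2 * s + 2)
  rows <- (s + 1L):(h - s); cols <- (s + 1L):(w - s)
  err <- matrix(NA_real_, 2L * s + 1L, 2L * s + 1L)
  for (iy in -s:s) {
    for (ix in -s:s) {
      d <- b[rows, cols] - a[rows - iy, cols - ix]
      err[iy + s + 1L, ix + s + 1L] <- mean(d^2)
    }
  }
  idx <- which(err == min(err), arr.ind = TRUE)[1, ]
  by_ <- idx[1]; bx_ <- idx[2]
  refine <- function(i, j, di, dj) {
    # parabolic 3-point refinement, clamped at the search border
    if (i + di < 1 || i + di > nrow(err) || i - di < 1 || i - di > nrow(err)) return(0)
    vm <- err[i - di, j - dj]; v0 <- err[i, j]; vp <- err[i + di, j + dj]
    den <- vm - 2 * v0 + vp
    if (!is.finite(den) || abs(den) < 1e-15) 0 else 0.5 * (vm - vp) / den
  }
  dy <- by_ - s - 1L + refine(by_, bx_, 1L, 0L)
  dx <- bx_ - s - 1L + (
    if (bx_ > 1 && bx_ < ncol(err)) {
      vm <- err[by_, bx_ - 1L]; v0 <- err[by_, bx_]; vp <- err[by_, bx_ + 1L]
      den <- vm - 2 * v0 + vp
      if (!is.finite(den) || abs(den) < 1e-15) 0 else 0.5 * (vm - vp) / den
    } else 0)
  list(dx = as.numeric(dx), dy = as.numeric(dy))
}
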