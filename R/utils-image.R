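# Low-level image helpers shared by the flow engine, the stabilizer and the
# synthetic generator. Frames are plain numeric matrices: rows = y (downward),
# columns = x (rightward), both 1-based internally; user-facing ROI coordinates
# are 0-based (see roi_rect()).

#' @keywords internal
pad_indices <- function(n, r, mode = c("reflect", "replicate")) {
  mode <- match.arg(mode)
  if (r == 0L) return(seq_len(n))
  if (mode == "reflect") {
    # symmetric reflection including the edge sample: c b a | a b c ...
    left <- pmin(r:1, n)
    right <- pmax(n - seq_len(r) + 1L, 1L)
    c(left, seq_len(n), right)
  } else {
    c(rep(1L, r), seq_len(n), rep(n, r))
  }
}

# Separable correlation along one axis with border padding. `k` has odd length
# 2r+1 and is indexed by offsets -r..r, so moment kernels (w * a, w * a^2) keep
# their sign convention.
#' @keywords internal
filter_axis <- function(m, k, axis = c("x", "y"), pad = "reflect") {
  axis <- match.arg(axis)
  r <- (length(k) - 1L) %/% 2L
  h <- nrow(m); w <- ncol(m)
  out <- matrix(0, h, w)
  if (axis == "x") {
    mp <- m[, pad_indices(w, r, pad), drop = FALSE]
    for (j in seq_along(k)) {
      if (k[j] != 0) out <- out + k[j] * mp[, j:(j + w - 1L), drop = FALSE]
    }
  } else {
    mp <- m[pad_indices(h, r, pad), , drop = FALSE]
    for (j in seq_along(k)) {
      if (k[j] != 0) out <- out + k[j] * mp[j:(j + h - 1L), , drop = FALSE]
    }
  }
  out
}

#' @keywords internal
sep_filter <- function(m, kx, ky, pad = "reflect") {
  filter_axis(filter_axis(m, kx, "x", pad), ky, "y", pad)
}

#' @keywords internal
gaussian_kernel <- function(sigma, radius = max(1L, ceiling(3 * sigma))) {
  a <- (-radius):radius
  k <- exp(-a^2 / (2 * sigma^2))
  k / sum(k)
}

#' @keywords internal
gaussian_blur <- function(m, sigma, pad = "reflect") {
  if (sigma <= 0) return(m)
  k <- gaussian_kernel(sigma)
  sep_filter(m, k, k, pad)
}

# Bilinear sampling at arbitrary (x, y) query coordinates (1-based, x = column,
# y = row). Queries outside the frame are clamped to the border, which realises
# the edge-replication boundary policy used throughout.
#' @keywords internal
bilinear_sample <- function(m, xq, yq) {
  h <- nrow(m); w <- ncol(m)
  xq <- pmin(pmax(as.numeric(xq), 1), w)
  yq <- pmin(pmax(as.numeric(yq), 1), h)
  x0 <- pmin(floor(xq), w - 1L); y0 <- pmin(floor(yq), h - 1L)
  if (w == 1L) x0 <- rep(1, length(xq))
  if (h == 1L) y0 <- rep(1, length(yq))
  fx <- xq - x0; fy <- yq - y0
  i00 <- (x0 - 1) * h + y0
  i01 <- i00 + h * (w > 1L)
  i10 <- i00 + (h > 1L)
  i11 <- i01 + (h > 1L)
  v <- (1 - fy) * (1 - fx) * m[i00] + (1 - fy) * fx * m[i01] +
    fy * (1 - fx) * m[i10] + fy * fx * m[i11]
  v
}

#' @keywords internal
sample_field <- function(m, xq, yq) {
  matrix(bilinear_sample(m, xq, yq), nrow(xq), ncol(xq))
}

#' @keywords internal
coord_grids <- function(h, w) {
  list(x = matrix(rep(seq_len(w), each = h), h, w),
       y = matrix(rep(seq_len(h), times = w), h, w))
}

#' @keywords internal
frame_center <- function(m) c((ncol(m) + 1) / 2, (nrow(m) + 1) / 2)

#' @keywords internal
resize_bilinear <- function(m, new_h, new_w) {
  sy <- nrow(m) / new_h; sx <- ncol(m) / new_w
  xq <- matrix(rep((seq_len(new_w) - 0.5) * sx + 0.5, each = new_h), new_h, new_w)
  yq <- matrix(rep((seq_len(new_h) - 0.5) * sy + 0.5, times = new_w), new_h, new_w)
  sample_field(m, xq, yq)
}

#' @keywords internal
clamp01 <- function(m) pmin(pmax(m, 0), 1)

#' @keywords internal
hann_window <- function(h, w) {
  wy <- 0.5 - 0.5 * cos(2 * pi * (seq_len(h) - 1) / (h - 1))
  wx <- 0.5 - 0.5 * cos(2 * pi * (seq_len(w) - 1) / (w - 1))
  outer(wy, wx)
}
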