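# Vessel/cell segmentation: intensity normalization, thresholding, border
# following (Suzuki-Abe-style contour tracing with a containment hierarchy),
# a motion-energy mask over the moving blood column, and rectangular ROI
# handling. ROI coordinates are 0-based with half-open extents; x = column,
# y = row.

#' Min-max intensity normalization
#'
#' Rescales a frame linearly so its minimum maps to 0 and its maximum to 1,
#' increasing overall contrast before thresholding. A constant frame cannot be
#' rescaled and is returned unchanged with a warning. Idempotent.
#'
#' @param f A frame (numeric matrix).
#' @return The rescaled frame.
#' @export
normalize_intensity <- function(f) {
  rng <- range(f)
  if (diff(rng) < .Machine$double.eps) {
    warning("constant frame cannot be normalized; returned unchanged")
    return(f)
  }
  (f - rng[1]) / (rng[2] - rng[1])
}

#' Threshold a frame into a binary mask
#'
#' @param f A frame.
#' @param threshold Intensity cut in `[0, 1]`, or `"otsu"` for an automatic
#'   cut (Otsu's method).
#' @param mode `"bright"` marks pixels above the threshold as foreground;
#'   `"dark"` marks pixels below it (blood cells are dark on a bright vessel).
#' @return A logical matrix, `TRUE` = foreground.
#' @export
binarize <- function(f, threshold, mode = c("bright", "dark")) {
  mode <- match.arg(mode)
  if (identical(threshold, "otsu")) threshold <- EBImage::otsu(f)
  if (mode == "bright") f > threshold else f < threshold
}

# Vectorized frontier flood fill. Small component counts keep the outer loop
# short; each frontier expansion is a vectorized neighbor lookup.
#' @keywords internal
label_components <- function(mask, connectivity = 8L) {
  h <- nrow(mask); w <- ncol(mask)
  lab <- matrix(0L, h, w)
  offs <- if (connectivity == 8L) {
    expand.grid(dy = -1:1, dx = -1:1)
  } else {
    data.frame(dy = c(-1, 1, 0, 0), dx = c(0, 0, -1, 1))
  }
  offs <- offs[!(offs$dy == 0 & offs$dx == 0), ]
  todo <- which(mask)
  nextlab <- 0L
  for (seed in todo) {
    if (lab[seed] != 0L) next
    nextlab <- nextlab + 1L
    lab[seed] <- nextlab
    frontier <- seed
    while (length(frontier) > 0L) {
      ys <- (frontier - 1L) %% h + 1L
      xs <- (frontier - 1L) %/% h + 1L
      nb <- integer(0)
      for (k in seq_len(nrow(offs))) {
        yy <- ys + offs$dy[k]; xx <- xs + offs$dx[k]
        ok <- yy >= 1L & yy <= h & xx >= 1L & xx <= w
        if (any(ok)) nb <- c(nb, (xx[ok] - 1L) * h + yy[ok])
      }
      nb <- unique(nb)
      nb <- nb[mask[nb] & lab[nb] == 0L]
      lab[nb] <- nextlab
      frontier <- nb
    }
  }
  lab
}

# Moore-neighbor border following with Jacob's stopping criterion. `start` is
# a (row, col) boundary pixel of the traced component, `back` the adjacent
# background pixel the trace enters from.
#' @keywords internal
trace_border <- function(lab, comp, start, back) {
  # clockwise neighbor order: N NE E SE S SW W NW
  dy <- c(-1L, -1L, 0L, 1L, 1L, 1L, 0L, -1L)
  dx <- c(0L, 1L, 1L, 1L, 0L, -1L, -1L, -1L)
  h <- nrow(lab); w <- ncol(lab)
  is_fg <- function(y, x) y >= 1L && y <= h && x >= 1L && x <= w && lab[y, x] == comp
  dir_of <- function(from, to) {
    d <- to - from
    which(dy == d[1] & dx == d[2])
  }
  cur <- start
  bdir <- dir_of(cur, back)
  pts <- vector("list", 64L)
  pts[[1L]] <- start
  npts <- 1L
  seen <- new.env(hash = TRUE, size = 256L)
  repeat {
    key <- as.character(((cur[2] - 1L) * h + cur[1]) * 8L + bdir)
    if (!is.null(seen[[key]])) break  # directed state revisited: loop closed
    seen[[key]] <- TRUE
    found <- FALSE
    for (k in 1:8) {
      d <- (bdir - 1L + k - 1L) %% 8L + 1L  # clockwise from just after backtrack
      yy <- cur[1] + dy[d]; xx <- cur[2] + dx[d]
      if (is_fg(yy, xx)) {
        # new backtrack: the neighbor scanned just before the hit
        dprev <- (d - 2L) %% 8L + 1L
        nb <- c(cur[1] + dy[dprev], cur[2] + dx[dprev])
        cur <- c(yy, xx)
        bdir <- dir_of(cur, nb)
        found <- TRUE
        break
      }
    }
    if (!found) break  # isolated pixel
    if (all(cur == start)) break
    npts <- npts + 1L
    if (npts > length(pts)) pts <- c(pts, vector("list", length(pts)))
    pts[[npts]] <- cur
  }
  unname(do.call(rbind, pts[seq_len(npts)]))
}

#' @keywords internal
shoelace_area <- function(pts) {
  if (nrow(pts) < 3) return(0)
  y <- pts[, 1]; x <- pts[, 2]
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}

#' Trace all object contours of a binary mask
#'
#' Border following in the style of the classic binary-image algorithm of
#' Suzuki and Abe: every 8-connected foreground component contributes its
#' outer border, every hole (4-connected background component fully enclosed
#' by foreground) contributes an inner border, and each contour carries its
#' containment level (0 = outermost object border, 1 = hole border inside it,
#' 2 = object border inside that hole, ...). Contours are returned in raster
#' order of their topmost-leftmost pixel, so the output is deterministic.
#'
#' @param mask A logical matrix.
#' @return A tibble with one row per contour: `contour` (id), `level`,
#'   `type` (`"outer"`/`"hole"`), `component` (foreground component id),
#'   `n_points`, `area` (shoelace polygon area through the border pixel
#'   centers), `n_pixels` (estimated filled pixel count, boundary included),
#'   `y0`, `x0`, `height`, `width` (0-based bounding box) and `points`
#'   (list-column of (row, col) matrices, 1-based).
#' @export
trace_contours <- function(mask) {
  stopifnot(is.logical(mask), is.matrix(mask))
  empty <- tibble::tibble(contour = integer(), level = integer(),
                          type = character(), component = integer(),
                          n_points = integer(), area = numeric(),
                          n_pixels = numeric(), y0 = integer(), x0 = integer(),
                          height = integer(), width = integer(),
                          points = list())
  if (!any(mask)) return(empty)
  h <- nrow(mask); w <- ncol(mask)
  fg <- label_components(mask, 8L)
  bg <- label_components(!mask, 4L)
  border_bg <- unique(c(bg[1, ], bg[h, ], bg[, 1], bg[, w]))
  border_bg <- border_bg[border_bg != 0L]
  nfg <- max(fg)
  # topmost-leftmost pixel per fg component (raster order = column-major scan
  # transposed; use row-major raster: min row, then min col)
  fg_start <- lapply(seq_len(nfg), function(cmp) {
    idx <- which(fg == cmp)
    ys <- (idx - 1L) %% h + 1L; xs <- (idx - 1L) %/% h + 1L
    ymin <- min(ys)
    c(ymin, min(xs[ys == ymin]))
  })
  # holes: background components not reaching the image border
  hole_ids <- setdiff(unique(as.vector(bg[bg != 0L])), border_bg)
  hole_start <- lapply(hole_ids, function(bcmp) {
    idx <- which(bg == bcmp)
    ys <- (idx - 1L) %% h + 1L; xs <- (idx - 1L) %/% h + 1L
    ymin <- min(ys)
    c(ymin, min(xs[ys == ymin]))
  })
  # enclosing fg component of each hole: the pixel directly above the hole's
  # topmost-leftmost pixel is necessarily foreground
  hole_parent <- vapply(hole_start, function(p) fg[p[1] - 1L, p[2]], integer(1))
  # levels: fg component level = 0 if its surrounding background touches the
  # image frame, else grandparent level + 2 (object inside a hole)
  fg_level <- rep(NA_integer_, nfg)
  surround_bg <- vapply(seq_len(nfg), function(cmp) {
    p <- fg_start[[cmp]]
    if (p[1] == 1L || p[2] == 1L) return(0L)  # touches frame edge region
    up <- bg[p[1] - 1L, p[2]]
    lf <- bg[p[1], p[2] - 1L]
    if (up != 0L) up else lf
  }, integer(1))
  resolve_level <- function(cmp) {
    if (!is.na(fg_level[cmp])) return(fg_level[cmp])
    sb <- surround_bg[cmp]
    lev <- if (sb == 0L || sb %in% border_bg) 0L else {
      hp <- hole_parent[match(sb, hole_ids)]
      resolve_level(hp) + 2L
    }
    fg_level[cmp] <<- lev
    lev
  }
  for (cmp in seq_len(nfg)) resolve_level(cmp)

  rows <- list()
  for (cmp in seq_len(nfg)) {
    st <- fg_start[[cmp]]
    pts <- trace_border(fg, cmp, st, c(st[1], st[2] - 1L))
    rows[[length(rows) + 1L]] <- list(level = fg_level[cmp], type = "outer",
                                      component = cmp, points = pts)
  }
  for (k in seq_along(hole_ids)) {
    hp <- hole_start[[k]]
    st <- c(hp[1] - 1L, hp[2])  # fg pixel above the hole
    pts <- trace_border(fg, hole_parent[k], st, hp)
    rows[[length(rows) + 1L]] <- list(level = fg_level[hole_parent[k]] + 1L,
                                      type = "hole",
                                      component = hole_parent[k], points = pts)
  }
  # deterministic raster order of the starting pixel
  starts <- t(vapply(rows, function(r) r$points[1, ], numeric(2)))
  ord <- order(starts[, 1], starts[, 2])
  rows <- rows[ord]
  out <- purrr::map_dfr(seq_along(rows), function(i) {
    r <- rows[[i]]
    pts <- r$points
    area <- shoelace_area(pts)
    npts <- nrow(unique(pts))
    tibble::tibble(
      contour = i, level = as.integer(r$level), type = r$type,
      component = as.integer(r$component), n_points = nrow(pts),
      area = area,
      n_pixels = if (r$type == "outer") area + npts / 2 + 1 else area - npts / 2 + 1,
      y0 = as.integer(min(pts[, 1]) - 1L), x0 = as.integer(min(pts[, 2]) - 1L),
      height = as.integer(diff(range(pts[, 1])) + 1L),
      width = as.integer(diff(range(pts[, 2])) + 1L),
      points = list(pts))
  })
  out
}

#' Rectangular region of interest
#'
#' 0-based, half-open: `x0`/`y0` are the first column/row inside the ROI,
#' `width`/`height` the extent. Minimum size 4x4.
#'
#' @param x0,y0 Top-left corner (0-based column, row).
#' @param width,height Extent in pixels (>= 4).
#' @return An object of class `roi_rect`.
#' @export
roi_rect <- function(x0, y0, width, height) {
  stopifnot(x0 >= 0, y0 >= 0)
  if (width < 4 || height < 4) {
    stop("ROI must be at least 4x4 pixels", call. = FALSE)
  }
  structure(list(x0 = as.integer(x0), y0 = as.integer(y0),
                 width = as.integer(width), height = as.integer(height)),
            class = "roi_rect")
}

#' @export
print.roi_rect <- function(x, ...) {
  cat(sprintf("<roi_rect> x0=%d y0=%d width=%d height=%d\n",
              x$x0, x$y0, x$width, x$height))
  invisible(x)
}

#' Crop a frame (or matrix) to an ROI
#'
#' @param f A frame or any matrix of matching dimensions.
#' @param roi An [roi_rect()] lying fully inside `f`.
#' @return The cropped matrix of dimensions `height` x `width`.
#' @export
apply_roi <- function(f, roi) {
  stopifnot(inherits(roi, "roi_rect"))
  if (roi$x0 + roi$width > ncol(f) || roi$y0 + roi$height > nrow(f)) {
    stop("ROI exceeds frame bounds", call. = FALSE)
  }
  f[(roi$y0 + 1L):(roi$y0 + roi$height), (roi$x0 + 1L):(roi$x0 + roi$width),
    drop = FALSE]
}

#' Motion-energy mask over the moving blood column
#'
#' Time-averages the optical flow across all consecutive frame pairs,
#' thresholds the averaged motion, and closes small gaps with a 3x3
#' morphological closing. On a stabilized clip the only coherent motion is
#' the blood column, so the mask localizes the vessel. The default
#' `"coherent"` statistic thresholds the magnitude of the time-averaged
#' displacement *vector*, under which incoherent sensor-noise flow in the
#' background averages toward zero while directed blood flow does not;
#' `"magnitude"` averages the per-pair magnitudes instead, which rectifies
#' noise and is kept only for comparison.
#'
#' @param clip A [video_clip()] (stabilize first if the recording is shaky).
#' @param flow_threshold Absolute floor (px/frame) of the support threshold;
#'   the effective cut is `max(flow_threshold, 0.5 * q95)` of the averaged
#'   motion, i.e. the flow's half-maximum support.
#' @param params [farneback_params()] for the underlying flow.
#' @param statistic `"coherent"` or `"magnitude"` (see above).
#' @return A logical matrix.
#' @export
motion_mask <- function(clip, flow_threshold = 0.2, params = farneback_params(),
                        statistic = c("coherent", "magnitude")) {
  stopifnot(inherits(clip, "video_clip"))
  statistic <- match.arg(statistic)
  n <- n_frames(clip)
  # detection flow: single pyramid level. The mask needs to know *where*
  # coherent motion is, not how fast it is; multi-level flow smears the
  # coarse-level estimate far beyond the vessel, while single-level flow has
  # the tightest spatial support (fast motion saturates in magnitude but
  # still clears any sensible threshold).
  params$pyramid_levels <- 1L
  accu <- accv <- accm <- matrix(0, nrow(clip$frames[[1]]), ncol(clip$frames[[1]]))
  for (i in seq_len(n - 1L)) {
    fl <- farneback_flow(clip$frames[[i]], clip$frames[[i + 1L]], params)
    accu <- accu + fl$u; accv <- accv + fl$v
    accm <- accm + sqrt(fl$u^2 + fl$v^2)
  }
  avg <- if (statistic == "coherent") {
    sqrt(accu^2 + accv^2) / (n - 1L)
  } else {
    accm / (n - 1L)
  }
  # support cut: absolute floor plus half of the near-peak (95th percentile)
  # averaged motion -- the full-width-at-half-maximum support of the moving
  # column, which stays tight however fast the flow is
  thr_eff <- max(flow_threshold, 0.5 * stats::quantile(avg, 0.95, names = FALSE))
  mm <- avg >= thr_eff
  # closing bridges gaps between cells; opening then removes speckle and the
  # thin chains that would otherwise attach background noise to the vessel
  k <- EBImage::makeBrush(3L, "box")
  cleaned <- EBImage::opening(EBImage::closing(mm * 1, k), k)
  # deconvolve the support dilation of the flow's averaging window: the
  # thresholded support overshoots the moving column by roughly one window
  # sigma (plus the closing's one-pixel dilation) on every side, so erode it
  # back by that much
  er <- as.integer(round((params$window - 1) / 4)) + 1L
  while (er > 0L) {
    shrunk <- EBImage::erode(cleaned, EBImage::makeBrush(2L * er + 1L, "box"))
    if (any(shrunk > 0.5)) { cleaned <- shrunk; break }
    er <- er - 1L  # a thin or fragmented support must not erode to nothing
  }
  matrix(cleaned > 0.5, nrow(mm), ncol(mm))
}

#' Automatic vessel ROI from motion
#'
#' Takes the largest-area outer contour of the [motion_mask()], expands its
#' bounding rectangle by a 2 px margin and clips to the frame. Fails with an
#' instruction to supply a manual ROI when no motion is detected (the same
#' fallback a user would take on a low-contrast recording).
#'
#' @inheritParams motion_mask
#' @return An [roi_rect()].
#' @export
auto_roi <- function(clip, flow_threshold = 0.2, params = farneback_params()) {
  mm <- motion_mask(clip, flow_threshold, params)
  ct <- trace_contours(mm)
  ct <- ct[ct$type == "outer", , drop = FALSE]
  if (nrow(ct) == 0L) {
    stop("no moving region found; supply a manual ROI", call. = FALSE)
  }
  best <- ct[which.max(ct$n_pixels), ]
  h <- nrow(mm); w <- ncol(mm)
  # coverage-trimmed bounding box: a stray noise blob that happens to connect
  # to the vessel component adds rows/columns with near-zero mask coverage,
  # which would inflate a raw bounding box; keep only rows/columns covered at
  # >= 20% of the peak coverage
  sub <- mm[(best$y0 + 1L):(best$y0 + best$height),
            (best$x0 + 1L):(best$x0 + best$width), drop = FALSE]
  rcov <- rowSums(sub); ccov <- colSums(sub)
  rk <- which(rcov >= 0.2 * max(rcov)); ck <- which(ccov >= 0.2 * max(ccov))
  by0 <- best$y0 + rk[1] - 1L; by1 <- best$y0 + rk[length(rk)]
  bx0 <- best$x0 + ck[1] - 1L; bx1 <- best$x0 + ck[length(ck)]
  x0 <- max(0L, bx0 - 2L); y0 <- max(0L, by0 - 2L)
  x1 <- min(w, bx1 + 2L); y1 <- min(h, by1 + 2L)
  roi_rect(x0, y0, x1 - x0, y1 - y0)
}

#' Intersection-over-union of two ROIs
#'
#' @param a,b [roi_rect()] objects.
#' @return IoU in `[0, 1]`.
#' @export
roi_iou <- function(a, b) {
  ix <- max(0, min(a$x0 + a$width, b$x0 + b$width) - max(a$x0, b$x0))
  iy <- max(0, min(a$y0 + a$height, b$y0 + b$height) - max(a$y0, b$y0))
  inter <- ix * iy
  inter / (a$width * a$height + b$width * b$height - inter)
}
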