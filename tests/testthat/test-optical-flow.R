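test_that("gradients: constant fields, ramps, and the brightness-constancy identity", {
  const <- matrix(0.4, 16, 16)
  g <- gradients(const, const)
  expect_true(all(g$fx == 0) && all(g$fy == 0) && all(g$ft == 0))
  # x-ramp, static: fx = 1/width on interior, fy = 0
  w <- 32
  ramp <- matrix(rep((1:w) / w, each = 16), 16, w)
  g <- gradients(ramp, ramp)
  expect_equal(g$fx[5, 5:28], rep(1 / w, 24), tolerance = 1e-12)
  expect_true(all(abs(g$fy) < 1e-12))
  # ramp shifted by one px: ft = -fx * u with u = 1 on the interior
  shifted <- circshift(ramp, 1, 0)
  g2 <- gradients(ramp, shifted)
  interior <- 5:25
  expect_equal(g2$ft[8, interior], -g2$fx[8, interior], tolerance = 1e-9)
})

test_that("polynomial expansion recovers an exact quadratic and is linear in offsets", {
  h <- 21; w <- 21; cx <- 11; cy <- 11
  g <- hemoflow:::coord_grids(h, w)
  X <- g$x - cx; Y <- g$y - cy
  sc <- 200  # keep the synthetic quadratic within display range
  I <- (X^2 + 2 * X * Y + 3 * Y^2 + 4 * X + 5 * Y + 60) / sc
  e <- polynomial_expansion(I, 5, 1.1)
  expect_equal(e$A11[cy, cx] * sc, 1, tolerance = 1e-6)
  expect_equal(e$A12[cy, cx] * sc, 1, tolerance = 1e-6)
  expect_equal(e$A22[cy, cx] * sc, 3, tolerance = 1e-6)
  expect_equal(e$B1[cy, cx] * sc, 4, tolerance = 1e-6)
  expect_equal(e$B2[cy, cx] * sc, 5, tolerance = 1e-6)
  expect_equal(e$C[cy, cx] * sc, 60, tolerance = 1e-6)
  # at any interior pixel the local linear term is the analytic gradient
  for (p in list(c(8, 7), c(14, 13))) {
    bx <- (2 * X[p[1], p[2]] + 2 * Y[p[1], p[2]] + 4) / sc
    expect_equal(e$B1[p[1], p[2]], bx, tolerance = 1e-6)
  }
  # constant frame: A = b = 0, c = value
  ec <- polynomial_expansion(matrix(0.7, 15, 15), 5, 1.1)
  expect_lt(max(abs(ec$A11), abs(ec$A12), abs(ec$A22), abs(ec$B1), abs(ec$B2)), 1e-10)
  expect_equal(ec$C[8, 8], 0.7, tolerance = 1e-10)
  # adding a constant shifts only c
  e2 <- polynomial_expansion(I + 0.1, 5, 1.1)
  expect_equal(e2$C - e$C, matrix(0.1, h, w), tolerance = 1e-9)
  expect_equal(e2$A11, e$A11, tolerance = 1e-12)
  expect_equal(e2$B2, e$B2, tolerance = 1e-12)
})

test_that("displacement solve: identity, closed-form single pixel, shifted quadratic", {
  h <- 40; w <- 40
  g <- hemoflow:::coord_grids(h, w)
  f1 <- ((g$x - 20)^2 + (g$y - 20)^2) / 1600
  e1 <- polynomial_expansion(f1)
  d0 <- displacement_from_expansions(e1, e1, window = 15)
  expect_lt(max(abs(d0$u), abs(d0$v)), 1e-9)
  # b2 = b1 - 2 A d with A = I, b2 - b1 = (-2, -4) has the unique solution (1, 2)
  mk <- function(b1, b2) {
    structure(list(A11 = matrix(1, 1, 1), A12 = matrix(0, 1, 1),
                   A22 = matrix(1, 1, 1), B1 = matrix(b1[1], 1, 1),
                   B2 = matrix(b1[2], 1, 1), C = matrix(0, 1, 1),
                   poly_n = 5L, poly_sigma = 1.1), class = "poly_expansion")
  }
  e_a <- mk(c(0, 0)); e_b <- mk(c(-2, -4))
  d <- displacement_from_expansions(e_a, e_b, window = 1)
  expect_equal(c(d$u[1, 1], d$v[1, 1]), c(1, 2), tolerance = 1e-12)
  # analytic quadratic translated by (0.6, -0.4)
  f2 <- ((g$x - 20 - 0.6)^2 + (g$y - 20 + 0.4)^2) / 1600
  e2 <- polynomial_expansion(f2)
  d2 <- displacement_from_expansions(e1, e2, window = 15)
  interior <- 10:30
  expect_lt(abs(mean(d2$u[interior, interior]) - 0.6), 0.05)
  expect_lt(abs(mean(d2$v[interior, interior]) + 0.4), 0.05)
})

test_that("zero motion yields zero flow; translations match the block-matching oracle", {
  a <- textured_frame(96, seed = 21)
  f0 <- farneback_flow(a, a)
  expect_lt(max(abs(f0$u), abs(f0$v)), 1e-6)
  int <- 17:80
  # integer translation
  b <- circshift(a, 3, 1)
  fl <- farneback_flow(a, b)
  expect_lt(abs(median(fl$u[int, int]) - 3), 0.2)
  expect_lt(abs(median(fl$v[int, int]) - 1), 0.2)
  o <- brute_shift(a, b)
  expect_lt(abs(median(fl$u[int, int]) - o$dx), 0.25)
  expect_lt(abs(median(fl$v[int, int]) - o$dy), 0.25)
  # sub-pixel translation via Fourier shift
  bs <- fourier_shift(a, -0.5, 0.25)
  bs <- pmin(pmax(bs, 0), 1)
  fs <- farneback_flow(a, bs)
  expect_lt(abs(median(fs$u[int, int]) + 0.5), 0.15)
  expect_lt(abs(median(fs$v[int, int]) - 0.25), 0.15)
})

test_that("flow obeys the expected symmetries", {
  a <- textured_frame(96, seed = 23)
  b <- circshift(a, 2, 1)
  fl <- farneback_flow(a, b)
  int <- 17:80
  # left-right flip negates u, preserves v
  flip <- function(m) m[, ncol(m):1]
  ff <- farneback_flow(flip(a), flip(b))
  expect_lt(abs(median(ff$u[int, int]) + median(fl$u[int, int])), 0.1)
  expect_lt(abs(median(ff$v[int, int]) - median(fl$v[int, int])), 0.1)
  # constant intensity offset leaves the flow unchanged
  off <- farneback_flow(pmin(a + 0.1, 1), pmin(b + 0.1, 1))
  expect_lt(abs(median(off$u[int, int]) - median(fl$u[int, int])), 0.05)
})

test_that("brightness-constancy residual is small on recovered synthetic flow", {
  a <- textured_frame(96, seed = 29)
  b <- circshift(a, 2, -1)
  fl <- farneback_flow(a, b)
  g <- gradients(a, b)
  int <- 17:80
  resid <- abs(g$fx * fl$u + g$fy * fl$v + g$ft)[int, int]
  expect_lt(mean(resid[fl$valid[int, int]]), 0.02)
})

test_that("flow error grows monotonically with added noise", {
  a <- textured_frame(96, seed = 31)
  b <- circshift(a, 2, 1)
  int <- 17:80
  sigmas <- c(0, 0.02, 0.05, 0.1)
  errs <- vapply(seq_along(sigmas), function(k) {
    set.seed(40 + k)
    an <- pmin(pmax(a + matrix(rnorm(96^2, 0, sigmas[k]), 96, 96), 0), 1)
    bn <- pmin(pmax(b + matrix(rnorm(96^2, 0, sigmas[k]), 96, 96), 0), 1)
    fl <- farneback_flow(an, bn)
    mean(sqrt((fl$u[int, int] - 2)^2 + (fl$v[int, int] - 1)^2))
  }, numeric(1))
  expect_gt(suppressWarnings(cor(sigmas, errs, method = "spearman")), 0)
})

test_that("directional components sum horizontal and vertical planes", {
  mkflow <- function(u, v) structure(list(u = u, v = v,
                                          valid = matrix(TRUE, nrow(u), ncol(u))),
                                     class = "flow_field")
  f1 <- mkflow(matrix(1, 4, 4), matrix(-1, 4, 4))
  f2 <- mkflow(matrix(2, 4, 4), matrix(1, 4, 4))
  single <- directional_components(f1)
  expect_equal(single$H, f1$u)
  expect_equal(single$V, f1$v)
  both <- directional_components(list(f1, f2))
  expect_equal(both$H, matrix(3, 4, 4))
  expect_equal(both$V, matrix(0, 4, 4))
  expect_error(directional_components(list()), "at least one")
})

test_that("frames too small for the pyramid reduce levels with a warning", {
  a <- textured_frame(16, seed = 33)
  expect_warning(farneback_flow(a, a, farneback_params(pyramid_levels = 4)),
                 "pyramid")
})
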