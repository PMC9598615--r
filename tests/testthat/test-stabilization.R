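test_that("rigid transform algebra: compose with inverse is identity", {
  set.seed(4)
  for (i in 1:20) {
    t <- rigid_transform(runif(1, -5, 5), runif(1, -5, 5), runif(1, -0.2, 0.2))
    id <- compose_rigid(t, invert_rigid(t))
    expect_lt(abs(id$dx), 1e-9)
    expect_lt(abs(id$dy), 1e-9)
    expect_lt(abs(id$dtheta), 1e-9)
  }
})

test_that("identical frames give the identity transform; constant frames flag low confidence", {
  a <- textured_frame(64, seed = 2)
  t <- estimate_rigid_transform(a, a, rotation = FALSE)
  expect_lt(abs(t$dx) + abs(t$dy), 0.02)
  flat <- estimate_rigid_transform(matrix(0.5, 32, 32), matrix(0.5, 32, 32))
  expect_true(flat$low_confidence)
  expect_equal(c(flat$dx, flat$dy, flat$dtheta), c(0, 0, 0))
})

test_that("translation recovery matches the exhaustive search oracle within 0.1 px", {
  a <- textured_frame(128, seed = 3)
  b <- circshift(a, 3, -2)
  t <- estimate_rigid_transform(a, b)
  expect_lt(abs(t$dx - 3), 0.1)
  expect_lt(abs(t$dy + 2), 0.1)
  expect_lt(abs(t$dtheta), 0.01)
  oracle <- brute_shift(a, b)
  expect_lt(abs(t$dx - oracle$dx), 0.15)
  expect_lt(abs(t$dy - oracle$dy), 0.15)
})

test_that("rotation recovery within 0.005 rad against a grid-search oracle", {
  a <- textured_frame(128, seed = 5)
  b <- hemoflow:::warp_rigid(a, rigid_transform(0, 0, 0.05))
  t <- estimate_rigid_transform(a, b)
  expect_lt(abs(t$dtheta - 0.05), 0.005)
  # oracle: coarse grid search over angles maximizing correlation
  score <- vapply(seq(0, 0.1, by = 0.01), function(th) {
    bb <- hemoflow:::warp_rigid(b, rigid_transform(0, 0, -th))
    stats::cor(as.vector(a[20:108, 20:108]), as.vector(bb[20:108, 20:108]))
  }, numeric(1))
  expect_equal(which.max(score), 6L)  # 0.05 rad wins the grid
})

test_that("trajectory smoothing is a truncated centered moving average", {
  traj <- lapply(c(0, 2, 4), function(d) rigid_transform(dx = d))
  sm <- smooth_trajectory(traj, 3)
  expect_equal(vapply(sm$cumulative, `[[`, numeric(1), "dx"), c(1, 2, 3))
  expect_error(smooth_trajectory(traj, 2), "odd")
  # window 1 is the identity; constant trajectories are fixed points
  expect_equal(tidy(smooth_trajectory(traj, 1)),
               tidy(structure(list(cumulative = traj), class = "trajectory")))
  const <- replicate(7, rigid_transform(1, -2, 0.01), simplify = FALSE)
  sm2 <- smooth_trajectory(const, 5)
  expect_equal(vapply(sm2$cumulative, `[[`, numeric(1), "dy"), rep(-2, 7))
})

test_that("stabilizing an already-static clip is a near no-op and preserves shape", {
  clip <- static_clip(textured_frame(96, seed = 7), n = 6)
  st <- stabilize(clip, window = 5, rotation = FALSE)
  expect_equal(n_frames(st$clip), 6)
  expect_equal(dim(st$clip$frames[[1]]), dim(clip$frames[[1]]))
  for (i in 1:6) {
    expect_lt(max(abs(st$clip$frames[[i]] - clip$frames[[i]])), 0.02)
  }
  # 2-frame clip with window 1 is valid and unsmoothed
  c2 <- static_clip(textured_frame(64, seed = 8), n = 2)
  st2 <- stabilize(c2, window = 1, rotation = FALSE)
  expect_equal(n_frames(st2$clip), 2)
})

test_that("stabilization removes >= 90% of injected jitter on textured scenes", {
  base <- static_clip(textured_frame(256, seed = 11), n = 24)
  jit <- add_camera_jitter(base, amplitude = 5, seed = 21)
  st <- stabilize(jit$clip, window = 15, rotation = FALSE)
  interframe <- function(clip) {
    mean(vapply(2:n_frames(clip), function(i) {
      t <- estimate_rigid_transform(clip$frames[[i - 1]], clip$frames[[i]],
                                    rotation = FALSE)
      sqrt(t$dx^2 + t$dy^2)
    }, numeric(1)))
  }
  before <- interframe(jit$clip)
  after <- interframe(st$clip)
  expect_gt(before, 2)  # jitter really was injected
  expect_lt(after, 0.1 * before)
})

test_that("injected shifts are recovered within 0.2 px by the transform estimator", {
  base <- static_clip(textured_frame(128, sigma = 3, seed = 13), n = 8)
  jit <- add_camera_jitter(base, amplitude = 3, seed = 5)
  for (i in 2:8) {
    est <- estimate_rigid_transform(base$frames[[1]], jit$clip$frames[[i]],
                                    rotation = FALSE)
    expect_lt(abs(est$dx - jit$transforms[[i]]$dx), 0.2)
    expect_lt(abs(est$dy - jit$transforms[[i]]$dy), 0.2)
  }
})
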