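test_that("forward/back projection match the dense slab-clipping oracle", {
  set.seed(41)
  for (mode in c("parallel2d", "fan2d")) {
    g <- oracle_geom(mode)
    A <- dense_system_matrix(g)
    x <- matrix(runif(64), 8, 8)
    fp <- forward_project(x, g)
    expect_lt(max(abs(fp - rayvec_to_proj(A %*% as.numeric(x), g))), 1e-12)

    y <- matrix(runif(nrow(fp) * ncol(fp)), nrow(fp), ncol(fp))
    bp <- back_project(y, g)
    expect_lt(max(abs(bp - array(t(A) %*% proj_to_rayvec(y), dim = c(8, 8)))),
              1e-12)
  }
})

test_that("sart_weights equal the oracle row/column sums and are nonnegative", {
  for (mode in c("parallel2d", "fan2d")) {
    g <- oracle_geom(mode)
    A <- dense_system_matrix(g)
    w <- sart_weights(g)
    expect_lt(max(abs(proj_to_rayvec(w$row_sums) - rowSums(A))), 1e-12)
    expect_lt(max(abs(as.numeric(w$col_sums) - colSums(A))), 1e-12)
    expect_true(all(w$row_sums >= 0) && all(w$col_sums >= 0))
    # per-angle restriction: rows of that angle, columns only from its rays
    w2 <- sart_weights(g, angle_idx = 2)
    expect_equal(as.numeric(w2$row_sums), w$row_sums[2, ])
    rays2 <- 13 + (1:13)
    expect_lt(max(abs(as.numeric(w2$col_sums) - colSums(A[rays2, ]))), 1e-12)
  }
})

test_that("adjointness holds to 1e-10 on randomized 16x16 geometries", {
  set.seed(7)
  for (rep in 1:5) {
    mode <- sample(c("parallel2d", "fan2d"), 1)
    g <- scan_geometry(mode,
                       angles = sort(runif(10, 0, 360)),
                       volume_shape = c(16, 16),
                       voxel_size = runif(1, 0.5, 2),
                       detector_pixel_counts = sample(10:40, 1),
                       detector_pixel_pitch = runif(1, 0.5, 2))
    x <- array(rnorm(256), dim = c(16, 16))
    y <- matrix(rnorm(length(g$angles) * g$detector_pixel_counts[1]),
                length(g$angles), g$detector_pixel_counts[1])
    lhs <- sum(forward_project(x, g) * y)
    rhs <- sum(x * back_project(y, g))
    expect_lt(abs(lhs - rhs) / max(abs(lhs), 1e-300), 1e-10)
  }
})

test_that("adjointness holds for cone3d on a small grid", {
  set.seed(8)
  g <- scan_geometry("cone3d", angles = make_angles(360, 8, 5),
                     volume_shape = c(10, 10, 6), voxel_size = 1,
                     detector_pixel_counts = c(12, 8),
                     detector_pixel_pitch = 1.3)
  x <- array(rnorm(600), dim = c(10, 10, 6))
  y <- matrix(rnorm(8 * 96), 8, 96)
  lhs <- sum(forward_project(x, g) * y)
  rhs <- sum(x * back_project(y, g))
  expect_lt(abs(lhs - rhs) / abs(lhs), 1e-10)
})

test_that("forward projection is linear and zero on zero volumes", {
  g <- oracle_geom("fan2d")
  z <- matrix(0, 8, 8)
  expect_true(all(forward_project(z, g) == 0))
  expect_true(all(back_project(forward_project(z, g), g) == 0))
  set.seed(9)
  x1 <- matrix(runif(64), 8, 8); x2 <- matrix(runif(64), 8, 8)
  expect_equal(forward_project(2.5 * x1 - x2, g),
               2.5 * forward_project(x1, g) - forward_project(x2, g),
               tolerance = 1e-12)
})

test_that("a central parallel ray through a uniform square integrates its side", {
  # one ray, one angle, perpendicular to a side of an s-mm square
  s <- 6
  g <- scan_geometry("parallel2d", angles = 0, volume_shape = c(6, 6),
                     voxel_size = 1, detector_pixel_counts = 1,
                     detector_pixel_pitch = 1)
  expect_equal(as.numeric(forward_project(matrix(1, 6, 6), g)), s)
})

test_that("rays missing the volume contribute exactly zero", {
  g <- scan_geometry("parallel2d", angles = c(0, 45),
                     volume_shape = c(4, 4), voxel_size = 1,
                     detector_pixel_counts = 40, detector_pixel_pitch = 1)
  fp <- forward_project(matrix(1, 4, 4), g)
  # detector much wider than the grid: outer pixels are exact zeros
  expect_true(all(fp[, c(1:10, 31:40)] == 0))
  w <- sart_weights(g)
  expect_true(all(w$row_sums[, c(1:10, 31:40)] == 0))
})

test_that("shape mismatches are rejected", {
  g <- oracle_geom()
  expect_error(forward_project(matrix(0, 4, 4), g), "shape")
  expect_error(back_project(matrix(0, 2, 2), g), "b|proj")
})
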