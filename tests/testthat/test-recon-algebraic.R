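test_that("nonneg_project clips negatives and is idempotent", {
  x <- matrix(c(-1, 0, 2, -0.5), 2, 2)
  px <- nonneg_project(x)
  expect_equal(px, matrix(c(0, 0, 2, 0), 2, 2))
  expect_equal(nonneg_project(px), px)
  expect_equal(nonneg_project(-abs(x)), matrix(0, 2, 2))
})

test_that("sart_sweep: zero residual, one-voxel closed form, residual decrease", {
  w <- tiny_world(n = 16, n_views = 20)
  # consistent data: update is exactly zero
  x1 <- sart_sweep(w$truth, w$b, w$geom, beta = 1)
  expect_equal(x1, w$truth, tolerance = 1e-12)

  # one-voxel one-ray system solves exactly in one step
  g1 <- scan_geometry("parallel2d", angles = 0, volume_shape = c(1, 1),
                      voxel_size = 3, detector_pixel_counts = 1,
                      detector_pixel_pitch = 1)
  b1 <- matrix(2.4, 1, 1)   # L = 3, so x = b / L = 0.8
  expect_equal(as.numeric(sart_sweep(matrix(0, 1, 1), b1, g1, beta = 1)),
               0.8)

  # one sweep strictly reduces the residual on noiseless data
  x0 <- array(0, dim = c(16, 16))
  r0 <- sqrt(sum((forward_project(x0, w$geom) - w$b)^2))
  xs <- sart_sweep(x0, w$b, w$geom, beta = 1)
  r1 <- sqrt(sum((forward_project(xs, w$geom) - w$b)^2))
  expect_lt(r1, r0)
  expect_error(sart_sweep(x0, w$b, w$geom, beta = 0), "beta")
  expect_error(sart_sweep(matrix(0, 4, 4), w$b, w$geom), "shape")
})

test_that("os_sart reduces to sart_sweep / SIRT-like limits, deterministically", {
  w <- tiny_world(n = 16, n_views = 12)
  x0 <- array(0, dim = c(16, 16))
  expect_equal(os_sart(x0, w$b, w$geom, n_subsets = 12, n_iter = 1,
                       beta = 0.8),
               sart_sweep(x0, w$b, w$geom, beta = 0.8))
  # SIRT-like full-data update decreases the residual for small beta
  x_sirt <- os_sart(x0, w$b, w$geom, n_subsets = 1, n_iter = 3, beta = 0.3)
  expect_lt(sqrt(sum((forward_project(x_sirt, w$geom) - w$b)^2)),
            sqrt(sum(w$b^2)))
  expect_identical(os_sart(x0, w$b, w$geom, 4, 2, 0.9),
                   os_sart(x0, w$b, w$geom, 4, 2, 0.9))
  expect_error(os_sart(x0, w$b, w$geom, n_subsets = 13), "n_subsets")
})

test_that("estimate_delta recovers a uniform disk value and has a positive floor", {
  spec <- phantom_spec(list(list(center = c(0, 0), semi_axes = c(0.4, 0.4),
                                 intensity = 0.02)), c(32, 32))
  disk <- render_phantom(spec)
  geom <- scan_geometry("fan2d", angles = make_angles(360, 30),
                        volume_shape = c(32, 32), voxel_size = 5,
                        detector_pixel_counts = 32,
                        detector_pixel_pitch = 10)
  d <- estimate_delta(forward_project(disk, geom), geom)
  expect_lt(abs(d - 0.02) / 0.02, 0.2)
  # degenerate input falls back to the strictly positive floor
  expect_equal(estimate_delta(matrix(0, 30, 32), geom), 1e-8)
})

test_that("cgls agrees with dense normal-equations least squares", {
  g <- oracle_geom("fan2d", n = 8, n_angles = 10, nd = 12, pitch = 1.2)
  A <- dense_system_matrix(g)      # 120 x 64, full column rank
  set.seed(31)
  y <- rnorm(nrow(A))
  b <- rayvec_to_proj(y, g)
  x_ls <- solve(crossprod(A), crossprod(A, y))
  x_cg <- cgls(b, g, n_iter = 200, stop_on_increase = FALSE)
  expect_lt(sqrt(sum((as.numeric(x_cg) - x_ls)^2)) / sqrt(sum(x_ls^2)), 1e-6)
})

test_that("cgls residuals are non-increasing and zero data gives zero image", {
  g <- oracle_geom("parallel2d", n = 8, n_angles = 7, nd = 10, pitch = 1)
  z <- matrix(0, 7, 10)
  expect_equal(cgls(z, g, n_iter = 5), array(0, dim = c(8, 8)),
               ignore_attr = "iterations")
  set.seed(32)
  b <- matrix(runif(70), 7, 10)
  res <- vapply(1:8, function(k) {
    x <- cgls(b, g, n_iter = k, stop_on_increase = FALSE)
    sqrt(sum((forward_project(x, g) - b)^2))
  }, numeric(1))
  expect_true(all(diff(res) <= 1e-8))
})
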