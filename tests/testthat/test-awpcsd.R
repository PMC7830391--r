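test_that("awpcsd_params validates the hyperparameter ranges", {
  p <- awpcsd_params(epsilon = 100, ng = 5, delta = 0.01)
  expect_s3_class(p, "awpcsd_params")
  expect_equal(p$beta, 1); expect_equal(p$beta_red, 0.99)
  expect_error(awpcsd_params(-1, 5, 0.01), "epsilon")
  expect_error(awpcsd_params(1, 0, 0.01), "ng")
  expect_error(awpcsd_params(1, 5, 0), "delta")
  expect_error(awpcsd_params(1, 5, 0.01, beta = 1.2), "beta")
  expect_error(awpcsd_params(1, 5, 0.01, beta_red = 1), "beta_red")
})

test_that("beta decays geometrically and gates the run length", {
  w <- tiny_world(n = 16, n_views = 10)
  p <- awpcsd_params(epsilon = 0, ng = 2, delta = 0.01, beta = 0.5,
                     beta_red = 0.6, max_iter = 50, beta_floor = 0.05)
  r <- awpcsd(b = w$b, geom = w$geom, params = p)
  expect_equal(r$trace$beta, 0.5 * 0.6^(seq_len(nrow(r$trace)) - 1))
  expect_equal(r$stop_reason, "beta_floor")
  # stops exactly when beta * beta_red^n first falls below the floor
  n_expected <- which(0.5 * 0.6^(1:50) < 0.05)[1]
  expect_equal(nrow(r$trace), n_expected)
})

test_that("a huge epsilon skips the SART phase and leaves POCS images nonneg", {
  w <- tiny_world(n = 16, n_views = 10)
  set.seed(33)
  x0 <- nonneg_project(array(rnorm(256, 0.01, 0.005), dim = c(16, 16)))
  p <- awpcsd_params(epsilon = 1e30, ng = 3, delta = 0.01, max_iter = 4)
  r <- awpcsd(x0 = x0, b = w$b, geom = w$geom, params = p)
  # dd^2 never exceeds epsilon: data phase inert, only TV acts, and the
  # residual trace is frozen at its initial value
  expect_equal(r$trace$dd, rep(r$trace$dd[1], 4), tolerance = 1e-10)
  expect_true(all(r$trace$dd[1]^2 < 1e30))

  # the POCS projection precedes the TV phase, so any negative excursion
  # of the emitted image is bounded by that iteration's TV displacement
  p2 <- awpcsd(b = w$b, geom = w$geom,
               params = awpcsd_params(0, 2, 0.01, max_iter = 3))
  expect_gte(min(p2$image), -max(p2$trace$dtv))
})

test_that("iterating improves a noiseless 32x32 reconstruction", {
  w <- tiny_world(n = 32, n_views = 50)
  delta <- estimate_delta(w$b, w$geom)
  p <- awpcsd_params(epsilon = 0, ng = 10, delta = delta, max_iter = 30)
  r30 <- awpcsd(b = w$b, geom = w$geom, params = p)
  r1 <- awpcsd(b = w$b, geom = w$geom, params = p, n_outer = 1)
  expect_lt(relative_error(r30$image, w$truth),
            relative_error(r1$image, w$truth))
})

test_that("pausing and resuming reproduces the uninterrupted run exactly", {
  w <- tiny_world(n = 16, n_views = 20,
                  noise = ct_noise_model(seed = 4))
  p <- awpcsd_params(epsilon = 0, ng = 4, delta = 0.02, max_iter = 12)
  full <- awpcsd(b = w$b, geom = w$geom, params = p)
  part <- awpcsd(b = w$b, geom = w$geom, params = p, n_outer = 5)
  expect_true(is.na(part$stop_reason))
  rest <- awpcsd(b = w$b, geom = w$geom, params = p, state = part$state)
  expect_identical(rest$image, full$image)
  expect_equal(rest$trace, full$trace)
  expect_equal(rest$stop_reason, full$stop_reason)
  # resuming a terminated run is a no-op
  again <- awpcsd(b = w$b, geom = w$geom, params = p, state = rest$state)
  expect_identical(again$image, rest$image)
})

test_that("trace records the TV step control and cosine", {
  w <- tiny_world(n = 16, n_views = 10)
  p <- awpcsd_params(epsilon = 0, ng = 2, delta = 0.01, max_iter = 3)
  r <- awpcsd(b = w$b, geom = w$geom, params = p)
  expect_named(r$trace, c("iter", "dd", "awtv", "beta", "eta", "dtv", "c"))
  expect_equal(r$trace$eta[1], 1)
  expect_true(all(r$trace$eta > 0 & r$trace$eta <= 10))
  expect_true(all(abs(r$trace$c) <= 1))
  expect_output(print(r), "awpcsd_result")
})
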