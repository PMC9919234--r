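test_that("prediction follows the constant-velocity transition", {
  p0 <- kf_model_params(sigma_alpha = 0)
  st <- kf_state(c(1, 0, 2, 0), diag(4) * 0.1, time = 0)
  pre <- kf_predict(st, dt = 0.7, p0)
  expect_equal(pre$state, c(1, 0, 2, 0))

  st2 <- kf_state(c(0, 1, 0, 2), diag(4) * 0, time = 0)
  pre2 <- kf_predict(st2, dt = 0.5, p0)
  expect_equal(pre2$state, c(0.5, 1, 1.0, 2))
  expect_equal(pre2$covariance, matrix(0, 4, 4))

  expect_error(kf_predict(st, dt = 0, p0), "dt")
})

test_that("process noise matches the random-acceleration closed form", {
  # dt = 0.2, sigma_alpha,x = 1: upper-left block is
  # [[dt^4/4, dt^3/2], [dt^3/2, dt^2]] recomputed independently
  p <- kf_model_params(sigma_alpha = c(1, 0))
  st <- kf_state(rep(0, 4), diag(4), time = 0)
  pre <- kf_predict(st, dt = 0.2, p)
  Q <- attr(pre, "process_noise")
  dt <- 0.2
  expect_equal(Q[1:2, 1:2],
               matrix(c(dt^4 / 4, dt^3 / 2, dt^3 / 2, dt^2), 2, 2),
               tolerance = 1e-12)
  expect_equal(Q[1:2, 1:2], matrix(c(4e-4, 4e-3, 4e-3, 4e-2), 2, 2))
  expect_equal(Q[3:4, 3:4], matrix(0, 2, 2))
})

test_that("update honours the perfect- and uninformative-observation limits", {
  pre <- kf_state(c(1, 0.5, 2, -0.5), diag(c(1, 1, 1, 1)), time = 1)
  z <- c(3, 4)
  post <- kf_update(pre, kf_observation(1, z, diag(2) * 1e-12))
  expect_lt(max(abs(post$state[c(1, 3)] - z)), 1e-6)

  post2 <- kf_update(pre, kf_observation(1, z, diag(2) * 1e6))
  expect_lt(max(abs(post2$state - pre$state)), 1e-3)
})

test_that("the scalar case reduces to precision-weighted Gaussian fusion", {
  for (k in 1:20) {
    set.seed(k)
    pvar <- stats::runif(1, 0.1, 4)
    rvar <- stats::runif(1, 0.1, 4)
    mu <- stats::rnorm(1); z <- stats::rnorm(1)
    pre <- kf_state(c(mu, 0, 0, 0), diag(c(pvar, 0, 0, 0)), time = 0)
    post <- kf_update(pre, kf_observation(0, c(z, 0), diag(c(rvar, rvar))))
    want <- (mu / pvar + z / rvar) / (1 / pvar + 1 / rvar)
    expect_equal(post$state[1], want, tolerance = 1e-12)
    wantvar <- 1 / (1 / pvar + 1 / rvar)
    expect_equal(post$covariance[1, 1], wantvar, tolerance = 1e-12)
  }
})

test_that("innovation identity and covariance symmetry hold along a run", {
  sc <- rectangle_lap_scenario()
  tr <- build_reference_trajectory(sc, 10)
  radar <- simulate_radar_track(tr, seed = 21)
  st <- kf_state(c(radar$x[1], 0, radar$y[1], 0), diag(4), time = radar$t[1])
  p <- kf_model_params()
  for (i in 2:60) {
    st <- kf_predict(st, radar$t[i] - radar$t[i - 1], p)
    obs <- kf_observation(radar$t[i], c(radar$x[i], radar$y[i]), diag(2) * 0.0225)
    st <- kf_update(st, obs)
    d <- attr(st, "diagnostics")
    expect_identical(d$innovation, obs$z - d$predicted_observation)
    expect_lt(max(abs(st$covariance - t(st$covariance))), 1e-12)
    expect_true(all(diag(st$covariance) >= 0))
  }
})

test_that("simultaneous sequential updates match the stacked batch update", {
  set.seed(31)
  for (k in 1:25) {
    A <- matrix(stats::rnorm(16), 4)
    P <- crossprod(A) + diag(4) * 0.1
    x <- stats::rnorm(4)
    z1 <- stats::rnorm(2); z2 <- stats::rnorm(2)
    R1 <- diag(stats::runif(2, 0.01, 1))
    R2 <- diag(stats::runif(2, 0.01, 1))
    s1 <- kf_update(kf_state(x, P, 0), kf_observation(0, z1, R1))
    s2 <- kf_update(s1, kf_observation(0, z2, R2))
    want <- oracle_batch_update(x, P, z1, R1, z2, R2)
    expect_lt(max(abs(s2$state - want$state)), 1e-9)
    expect_lt(max(abs(s2$covariance - (want$cov + t(want$cov)) / 2)), 1e-9)
  }
})

test_that("fusing with an empty depth track equals the radar-only run", {
  sc <- rectangle_lap_scenario()
  tr <- build_reference_trajectory(sc, 10)
  radar <- simulate_radar_track(tr, seed = 8)
  empty <- sensor_track(numeric(0), numeric(0), numeric(0), sigma = 0.1,
                        sensor_id = "depth")
  expect_identical(kf_fuse_tracks(radar, empty),
                   kf_fuse_tracks(radar, empty[0, ]))
  f1 <- kf_fuse_tracks(radar, empty)
  # manual radar-only recursion
  p <- kf_model_params()
  st <- kf_state(c(radar$x[1], 0, radar$y[1], 0), diag(4), radar$t[1])
  st <- kf_update(st, kf_observation(radar$t[1], c(radar$x[1], radar$y[1]),
                                     diag(2) * 0.0225))
  for (i in 2:nrow(radar)) {
    st <- kf_predict(st, radar$t[i] - radar$t[i - 1], p)
    st <- kf_update(st, kf_observation(radar$t[i], c(radar$x[i], radar$y[i]),
                                       diag(2) * 0.0225))
  }
  expect_equal(as.numeric(f1[nrow(f1), c("x", "vx", "y", "vy")]),
               st$state, tolerance = 1e-12)
})

test_that("two-sensor fusion of a noiseless straight walk converges to the line", {
  sc <- line_scenario(speed = 0.8)
  tr <- build_reference_trajectory(sc, 10)
  radar <- track_from_traj(tr, sigma = 0.15)
  depth <- track_from_traj(tr[seq(1, nrow(tr), 3), ], sigma = 0.10,
                           sensor_id = "depth")
  # start the filter off the line: the fused track must pull back onto it
  p <- kf_model_params(initial_state = c(0, 0, 0.5, 0))
  fused <- kf_fuse_tracks(radar, depth, p)
  err <- abs(fused$y)
  expect_lt(err[length(err)], err[1])
  expect_lt(max(abs(fused$y[fused$t > 5])), 1e-3)
  expect_lt(max(abs(fused$x - fused$t * 0.8)[fused$t > 5]), 0.05)
})

test_that("zero process noise on noiseless constant-velocity data recovers the velocity", {
  sc <- line_scenario(speed = 0.6)
  tr <- build_reference_trajectory(sc, 10)
  radar <- track_from_traj(tr, sigma = 0.15)
  fused <- kf_fuse_tracks(radar, radar[0, ], kf_model_params(sigma_alpha = 0))
  expect_lt(abs(fused$vx[51] - 0.6), 1e-3)
  expect_lt(abs(fused$vy[51]), 1e-3)
})

test_that("empty input yields an empty fused track with a warning", {
  e <- sensor_track(numeric(0), numeric(0), numeric(0))
  expect_warning(f <- kf_fuse_tracks(e, e), "no observations")
  expect_identical(nrow(f), 0L)
})
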