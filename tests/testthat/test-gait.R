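test_that("a stationary track yields an all-zero motion indicator", {
  n <- 50
  tr <- data.frame(t = (0:(n - 1)) / 10, x = rep(1, n), y = rep(2, n))
  m <- detect_motion(tr)
  expect_true(all(m$value == 0L))
  closed <- morphological_close(m, 0.45)
  expect_true(all(closed$value == 0L))
  expect_true(is.na(mean_walking_speed(tr, closed)))
})

test_that("motion detection matches the direct windowed-displacement rule", {
  sc <- line_scenario(speed = 0.5)
  tr <- build_reference_trajectory(sc, 10)
  m <- detect_motion(tr, motion_config(T_m = 0.45, D = 0.1))
  want <- oracle_motion(tr$t, tr$x, tr$y, 0.45, 0.1)
  expect_identical(m$value, want)
  # at 0.5 m/s a full 0.45 s window displaces 0.225 m > 0.1 m (scaled):
  # every sample after the first is flagged
  expect_true(all(m$value[-1] == 1L))

  # also on an irregular noisy track
  set.seed(4)
  tr2 <- data.frame(t = cumsum(stats::runif(80, 0.05, 0.2)),
                    x = cumsum(stats::rnorm(80, 0, 0.1)),
                    y = cumsum(stats::rnorm(80, 0, 0.1)))
  m2 <- detect_motion(tr2)
  expect_identical(m2$value, oracle_motion(tr2$t, tr2$x, tr2$y, 0.45, 0.1))
})

test_that("walk-pause-walk time in motion is close to the scripted moving time", {
  # walk 5 s at 0.6, pause 6 s, walk 5 s
  t <- seq(0, 16, by = 0.1)
  x <- ifelse(t <= 5, 0.6 * t, ifelse(t <= 11, 3, 3 + 0.6 * (t - 11)))
  tr <- data.frame(t = t, x = x, y = 0)
  motion <- morphological_close(detect_motion(tr), 0.45)
  tm <- gaitfuse:::indicator_time(motion)
  expect_lt(abs(tm - 10), 0.45 + 0.1)
})

test_that("closing obeys the morphology laws and fills short gaps", {
  ind <- gaitfuse:::binary_indicator((0:19) / 10, rep(1L, 20), "motion")
  expect_identical(morphological_close(ind, 0.45)$value, rep(1L, 20))

  v <- c(1L, 1L, 1L, 1L, 0L, 0L, 1L, 1L, 1L, 1L)
  ind2 <- gaitfuse:::binary_indicator((0:9) / 10, v, "motion")
  expect_identical(morphological_close(ind2, 0.45)$value, rep(1L, 10))

  set.seed(10)
  for (k in 1:50) {
    v <- as.integer(stats::runif(60) < 0.5)
    ind <- gaitfuse:::binary_indicator((0:59) / 10, v, "motion")
    closed <- morphological_close(ind, 0.45)
    # extensive
    expect_true(all(closed$value >= v))
    # idempotent
    expect_identical(morphological_close(closed, 0.45)$value, closed$value)
    # increasing: adding 1s never removes 1s
    w <- v; w[sample(60, 5)] <- 1L
    closed_w <- morphological_close(
      gaitfuse:::binary_indicator((0:59) / 10, w, "motion"), 0.45)
    expect_true(all(closed_w$value >= closed$value))
  }
})

test_that("turn counting finds isolated corners", {
  # straight walk: no turns
  sc <- line_scenario()
  tr <- build_reference_trajectory(sc, 10)
  expect_identical(attr(detect_turns(tr), "n_turns"), 0L)

  # single 90-degree corner: one turn (90 > 60 degrees)
  scL <- scenario_config(rbind(c(0, 0), c(3, 0), c(3, 3)), 0.7,
                         sensor_rates = c(radar = 10, depth = 10))
  trL <- build_reference_trajectory(scL, 10)
  expect_identical(attr(detect_turns(trL), "n_turns"), 1L)

  # one rectangle lap traversing four corners: four turns
  for (v in c(0.5, 0.7, 1.0)) {
    trR <- build_reference_trajectory(rectangle_lap_scenario(speed = v), 10)
    expect_identical(attr(detect_turns(trR), "n_turns"), 4L)
  }
})

test_that("turn detection is invariant under global rotation", {
  trR <- build_reference_trajectory(rectangle_lap_scenario(), 10)
  for (ang in c(0.3, 1.2, 2.5)) {
    rot <- data.frame(t = trR$t,
                      x = cos(ang) * trR$x - sin(ang) * trR$y,
                      y = sin(ang) * trR$x + cos(ang) * trR$y)
    expect_identical(attr(detect_turns(rot), "n_turns"), 4L)
  }
})

test_that("travelled distance is the cumulative segment-norm sum", {
  expect_equal(travelled_distance(data.frame(x = c(0, 3), y = c(0, 4))), 5)
  expect_equal(travelled_distance(data.frame(x = 1, y = 1)), 0)
  expect_equal(travelled_distance(data.frame(x = rep(2, 9), y = rep(3, 9))), 0)
  set.seed(17)
  xy <- matrix(stats::rnorm(200), ncol = 2)
  tr <- data.frame(x = xy[, 1], y = xy[, 2])
  expect_equal(travelled_distance(tr), oracle_polyline_length(xy),
               tolerance = 1e-9)
  # rigid-motion invariance
  ang <- 0.77
  rot <- data.frame(x = cos(ang) * tr$x - sin(ang) * tr$y + 5,
                    y = sin(ang) * tr$x + cos(ang) * tr$y - 2)
  expect_equal(travelled_distance(rot), travelled_distance(tr),
               tolerance = 1e-9)
})

test_that("mean walking speed recovers the scripted speed on noiseless walks", {
  for (v in c(0.5, 1.0)) {
    sc <- line_scenario(length_m = 10, speed = v)
    tr <- build_reference_trajectory(sc, 10)
    motion <- morphological_close(detect_motion(tr), 0.45)
    sp <- mean_walking_speed(tr, motion)
    expect_lt(abs(sp - v) / v, 0.02)
  }
  expect_error(mean_walking_speed(data.frame(t = 1:3, x = 1:3, y = 1:3),
                                  gaitfuse:::binary_indicator(1:2, c(0L, 1L), "motion")),
               "length")
})

test_that("track smoothing is exact on constants and linear ramps", {
  tr <- data.frame(t = (0:40) / 10, x = rep(2, 41), y = rep(-1, 41))
  expect_equal(smooth_track(tr, 0.5), tr)

  ramp <- data.frame(t = (0:40) / 10, x = (0:40) * 0.08, y = -(0:40) * 0.03)
  sm <- smooth_track(ramp, 0.5)
  interior <- 4:37
  expect_equal(sm$x[interior], ramp$x[interior], tolerance = 1e-12)
  expect_equal(sm$y[interior], ramp$y[interior], tolerance = 1e-12)
  # a window spanning a single sample is the identity
  expect_equal(smooth_track(ramp, 0.05), ramp)
})

test_that("smoothing never lengthens a noiseless cornered path", {
  trR <- build_reference_trajectory(rectangle_lap_scenario(), 10)
  for (w in c(0.3, 0.5, 1.0)) {
    sm <- smooth_track(trR, w)
    expect_lte(travelled_distance(sm), travelled_distance(trR) + 1e-12)
  }
})

test_that("gait summary combines the parameter estimates coherently", {
  trR <- build_reference_trajectory(rectangle_lap_scenario(speed = 0.7), 10)
  gs <- gait_summary(trR)
  expect_identical(gs$n_turns, 4L)
  expect_identical(gs$n_turns, length(gs$turn_intervals))
  expect_equal(gs$distance, travelled_distance(trR))
  expect_equal(gs$mean_speed, gs$distance / gs$time_in_motion)
  expect_lt(abs(gs$mean_speed - 0.7) / 0.7, 0.02)
})
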