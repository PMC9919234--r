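test_that("zero-noise radar simulation reproduces the reference exactly", {
  tr <- build_reference_trajectory(line_scenario(), 10)
  rt <- simulate_radar_track(tr, radar_noise_config(noise_std = 0), seed = 3)
  expect_equal(rt$x, tr$x)
  expect_equal(rt$y, tr$y)
  expect_equal(rt$t, tr$t)
})

test_that("radar noise has the configured stationary std and autocorrelation", {
  sc <- scenario_config(rbind(c(0, 0), c(1000, 0)), walking_speed = 1)
  tr <- build_reference_trajectory(sc, 10) # 10^4 samples
  white <- simulate_radar_track(
    tr, radar_noise_config(noise_std = 0.1, red_noise_coefficient = 0,
                           smoothing_window = 1), seed = 7)
  res <- white$x - tr$x
  expect_lt(abs(stats::sd(res) - 0.1) / 0.1, 0.05)
  expect_lt(abs(mean(res)), 0.01)

  red <- simulate_radar_track(
    tr, radar_noise_config(noise_std = 0.1, red_noise_coefficient = 0.95,
                           smoothing_window = 1), seed = 7)
  res <- red$x - tr$x
  rho1 <- stats::acf(res, lag.max = 1, plot = FALSE)$acf[2]
  expect_lt(abs(rho1 - 0.95), 0.03)
})

test_that("degenerate depth model reproduces the reference at the depth rate", {
  sc <- line_scenario(rates = c(radar = 10, depth = 30))
  tr <- build_reference_trajectory(sc, 10)
  dt <- simulate_depth_track(
    tr, depth_model_config(ellipse_semi_axes = c(1e-12, 1e-12),
                           sine_amplitude = 0), sc)
  ref <- interpolate_trajectory(tr, dt$t)
  expect_equal(dt$x, ref$x, tolerance = 1e-9)
  expect_equal(dt$y, ref$y, tolerance = 1e-9)
  expect_identical(nrow(dt), as.integer(floor(attr(tr, "duration") * 30)) + 1L)
})

test_that("reported depth point is the visible-side ellipse boundary point", {
  # person walking east, due north of the sensor: the reported point is
  # pulled toward the sensor by the minor semi-axis
  sc <- scenario_config(rbind(c(-1, 5), c(1, 5)), 0.5,
                        sensor_rates = c(radar = 10, depth = 10),
                        depth_sensor_position = c(0, 0))
  tr <- build_reference_trajectory(sc, 10)
  cfg <- depth_model_config(ellipse_semi_axes = c(0.25, 0.15),
                            sine_amplitude = 0)
  dt <- simulate_depth_track(tr, cfg, sc)
  i <- which.min(abs(dt$x)) # sample nearest to being due north
  expect_equal(dt$y[i], 5 - 0.15, tolerance = 1e-6)

  # general geometry against the brute-force boundary search
  for (k in 1:5) {
    centre <- c(1 + k / 3, 2 - k / 5)
    heading <- k * 0.7
    sensor <- c(-1, -2)
    got <- {
      scg <- scenario_config(rbind(centre, centre + 0.3 * c(cos(heading), sin(heading))),
                             0.5, sensor_rates = c(radar = 10, depth = 10),
                             depth_sensor_position = sensor)
      trg <- build_reference_trajectory(scg, 10)
      d <- simulate_depth_track(trg, cfg, scg)
      c(d$x[3], d$y[3]) # interior sample, heading parallel to the segment
    }
    want <- oracle_visible_point(
      c(trg$x[3], trg$y[3]), heading, 0.25, 0.15, sensor)
    expect_equal(got, want, tolerance = 1e-3)
  }
})

test_that("occlusion removal is exactly the geometric line-of-sight rule", {
  sc <- serpentine_scenario()
  tr <- build_reference_trajectory(sc, 10)
  cfg <- depth_model_config(ellipse_semi_axes = c(1e-12, 1e-12),
                            sine_amplitude = 0)
  dt <- simulate_depth_track(tr, cfg, sc, fragment = TRUE)
  full <- simulate_depth_track(tr, cfg, sc, fragment = FALSE)
  occluded_oracle <- vapply(seq_len(nrow(full)), function(i) {
    any(vapply(sc$obstacle_regions, function(ob)
      oracle_segment_hits_rect(sc$depth_sensor_position,
                               c(full$x[i], full$y[i]), ob), logical(1)))
  }, logical(1))
  # a dense-sampling oracle can miss rays grazing a rectangle corner; such
  # ties are accepted either way
  grazing <- vapply(seq_len(nrow(full)), function(i) {
    any(vapply(sc$obstacle_regions, function(ob) {
      corners <- rbind(c(ob[1], ob[3]), c(ob[1], ob[4]),
                       c(ob[2], ob[3]), c(ob[2], ob[4]))
      p <- sc$depth_sensor_position; q <- c(full$x[i], full$y[i])
      d <- q - p; L2 <- sum(d^2)
      min(apply(corners, 1, function(cn) {
        u <- max(0, min(1, sum((cn - p) * d) / L2))
        sqrt(sum((p + u * d - cn)^2))
      })) < 1e-3
    }, logical(1)))
  }, logical(1))
  removed <- !(full$t %in% dt$t)
  disagree <- removed != occluded_oracle
  expect_true(all(grazing[disagree]))
  expect_gt(sum(removed), 0)

  # a wall between sensor and the whole path blanks the track
  wall <- scenario_config(rbind(c(0, 2), c(4, 2)), 0.5,
                          sensor_rates = c(radar = 10, depth = 10),
                          obstacle_regions = list(c(-1, 5, 0.5, 1.5)),
                          depth_sensor_position = c(2, -1))
  trw <- build_reference_trajectory(wall, 10)
  dtw <- simulate_depth_track(trw, depth_model_config(), wall, fragment = TRUE)
  expect_identical(nrow(dtw), 0L)
})

test_that("segment/rectangle intersection matches a dense-sampling oracle on random geometries", {
  set.seed(99)
  for (k in 1:200) {
    p <- stats::runif(2, -2, 6); q <- stats::runif(2, -2, 6)
    r0 <- sort(stats::runif(2, -1, 5)); r1 <- sort(stats::runif(2, -1, 5))
    rect <- c(r0[1], r0[2], r1[1], r1[2])
    got <- gaitfuse:::segment_intersects_rect(p, q, rect)
    want <- oracle_segment_hits_rect(p, q, rect)
    # the dense oracle can only miss grazing contacts; skip near-ties
    if (got != want) {
      d <- min(abs(c(p[1] - rect[1:2], p[2] - rect[3:4],
                     q[1] - rect[1:2], q[2] - rect[3:4])))
      expect_lt(d, 1e-2)
    } else {
      expect_identical(got, want)
    }
  }
})

test_that("training-set generation honours the counts and fragment quota", {
  ts <- generate_training_set(training_scenarios(), n_per_traj = 40,
                              fragment_fraction = 0.5, seed = 13)
  expect_length(ts, 160L)
  frag <- vapply(ts, `[[`, logical(1), "fragmented")
  expect_identical(sum(frag), 80L)
  per_traj <- table(vapply(ts, `[[`, character(1), "scenario_id"))
  expect_true(all(per_traj == 40L))
  # fragmented tracks have gaps; unfragmented do not
  gaps <- vapply(ts, function(r) {
    full <- floor(attr(r$trajectory, "duration") * 10) + 1
    nrow(r$depth) < full
  }, logical(1))
  expect_true(all(gaps[frag]))
  expect_true(!any(gaps[!frag]))
})

test_that("generation is bit-identical under a fixed seed", {
  a <- generate_training_set(training_scenarios(), n_per_traj = 2,
                             fragment_fraction = 0.5, seed = 5)
  b <- generate_training_set(training_scenarios(), n_per_traj = 2,
                             fragment_fraction = 0.5, seed = 5)
  expect_identical(a, b)
  c2 <- generate_training_set(training_scenarios(), n_per_traj = 2,
                              fragment_fraction = 0.5, seed = 6)
  expect_false(identical(a, c2))
})
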