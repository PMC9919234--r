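# Shared fixtures: small scenarios and brute-force oracles used across the
# test files. Everything is generated in code; no stored data.

# straight east-bound walk
line_scenario <- function(length_m = 10, speed = 0.5,
                          rates = c(radar = 10, depth = 10)) {
  scenario_config(rbind(c(0, 0), c(length_m, 0)), walking_speed = speed,
                  sensor_rates = rates, depth_sensor_position = c(length_m / 2, -3))
}

# one full rectangle lap traversing all four corners (start mid-edge)
rectangle_lap_scenario <- function(speed = 0.7,
                                   rates = c(radar = 10, depth = 30)) {
  scenario_config(rbind(c(2.0, 0.5), c(3.5, 0.5), c(3.5, 3.5),
                        c(0.5, 3.5), c(0.5, 0.5), c(2.0, 0.5)),
                  walking_speed = speed, sensor_rates = rates,
                  depth_sensor_position = c(2, -1))
}

# serpentine walk among two obstacles (occluded evaluation geometry)
serpentine_scenario <- function(speed = 0.5,
                                rates = c(radar = 10, depth = 30)) {
  scenario_config(
    rbind(c(0.5, 0.5), c(3.5, 0.5), c(3.5, 1.5), c(0.5, 1.5),
          c(0.5, 2.5), c(3.5, 2.5), c(3.5, 3.5), c(0.5, 3.5)),
    walking_speed = speed, sensor_rates = rates,
    obstacle_regions = list(c(1.2, 1.8, 1.0, 1.4), c(2.2, 2.8, 2.2, 2.6)),
    depth_sensor_position = c(2, -1))
}

# noiseless sensor track straight from a trajectory
track_from_traj <- function(traj, sigma = 0.1, sensor_id = "radar") {
  sensor_track(traj$t, traj$x, traj$y, sigma = sigma, sensor_id = sensor_id)
}

# brute-force polyline length
oracle_polyline_length <- function(xy) {
  s <- 0
  for (i in 2:nrow(xy)) s <- s + sqrt(sum((xy[i, ] - xy[i - 1, ])^2))
  s
}

# brute-force segment/rectangle intersection: dense sampling along the
# segment, point-in-rectangle test
oracle_segment_hits_rect <- function(p, q, rect, n = 4001) {
  u <- seq(0, 1, length.out = n)
  x <- p[1] + u * (q[1] - p[1])
  y <- p[2] + u * (q[2] - p[2])
  any(x >= rect[1] & x <= rect[2] & y >= rect[3] & y <= rect[4])
}

# brute-force 1-D binary closing: explicit dilation (pad 0) then erosion
# (pad 1), both written as literal window loops
oracle_close <- function(v, len) {
  n <- length(v)
  hl <- (len - 1L) %/% 2L
  hr <- len - 1L - hl
  at <- function(w, i, pad) if (i >= 1L && i <= n) w[i] else pad
  dil <- integer(n)
  for (i in seq_len(n))
    dil[i] <- max(vapply((i - hl):(i + hr), at, integer(1), w = v, pad = 0L))
  ero <- integer(n)
  for (i in seq_len(n))
    ero[i] <- min(vapply((i - hl):(i + hr), at, integer(1), w = dil, pad = 1L))
  ero
}

# brute-force nearest ellipse-boundary point to a sensor along the
# sensor-to-centre direction: dense parameter sweep of the boundary
oracle_visible_point <- function(centre, heading, a, b, sensor, n = 200000) {
  phi <- seq(0, 2 * pi, length.out = n)
  ex <- a * cos(phi); ey <- b * sin(phi)
  x <- centre[1] + ex * cos(heading) - ey * sin(heading)
  y <- centre[2] + ex * sin(heading) + ey * cos(heading)
  # restrict to points on the sensor-to-centre line (within tolerance)
  d <- c(sensor[1] - centre[1], sensor[2] - centre[2])
  d <- d / sqrt(sum(d^2))
  along <- (x - centre[1]) * d[1] + (y - centre[2]) * d[2]
  perp <- abs((x - centre[1]) * d[2] - (y - centre[2]) * d[1])
  ok <- perp < 1e-4 & along > 0
  i <- which(ok)[which.min((x[ok] - sensor[1])^2 + (y[ok] - sensor[2])^2)]
  c(x[i], y[i])
}

# stacked-observation batch Kalman update for two simultaneous
# observations (4-row observation matrix), independent of kf_update
oracle_batch_update <- function(pre_state, pre_cov, z1, R1, z2, R2) {
  H1 <- matrix(c(1, 0, 0, 0, 0, 0, 1, 0), 2, 4, byrow = TRUE)
  H <- rbind(H1, H1)
  z <- c(z1, z2)
  R <- rbind(cbind(R1, matrix(0, 2, 2)), cbind(matrix(0, 2, 2), R2))
  S <- H %*% pre_cov %*% t(H) + R
  G <- pre_cov %*% t(H) %*% solve(S)
  list(state = as.numeric(pre_state + G %*% (z - H %*% pre_state)),
       cov = (diag(4) - G %*% H) %*% pre_cov)
}

# direct O(n^2) evaluation of the motion-detection rule, independent of
# detect_motion's moving-pointer implementation
oracle_motion <- function(t, x, y, T_m, D) {
  n <- length(t)
  b <- integer(n)
  for (i in 2:n) {
    cand <- which(t[seq_len(i - 1L)] >= t[i] - T_m)
    n0 <- if (length(cand)) cand[1] else i - 1L
    d <- sqrt((x[i] - x[n0])^2 + (y[i] - y[n0])^2)
    b[i] <- as.integer(d > (t[i] - t[n0]) / T_m * D)
  }
  b
}

# quick small training set shared by network tests (cached per session)
small_training_set <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- generate_training_set(training_scenarios(), n_per_traj = 6,
                                      fragment_fraction = 0.5, seed = 42)
    cache
  }
})
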