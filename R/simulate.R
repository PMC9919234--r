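#' Radar noise model configuration
#'
#' The synthetic radar track is the reference trajectory corrupted with
#' zero-mean red noise (first-order autoregressive, strongly autocorrelated)
#' and then smoothed with a centred moving-average filter, emulating the
#' preprocessing of impulse-radar position fixes.
#'
#' @param noise_std stationary standard deviation of the red noise per axis,
#'   in metres.
#' @param red_noise_coefficient AR(1) coefficient in `[0, 1)`; 0 gives white
#'   noise.
#' @param smoothing_window moving-average length in samples (>= 1); the
#'   window is centred and shrinks at the track edges.
#' @param obs_sigma observation-noise standard deviation, in metres, written
#'   into the per-sample covariance carried by the track (used by the Kalman
#'   fuser).
#' @return an object of class `radar_noise_config`.
#' @export
radar_noise_config <- function(noise_std = 0.10,
                               red_noise_coefficient = 0.95,
                               smoothing_window = 11L,
                               obs_sigma = 0.15) {
  if (noise_std < 0) stop("`noise_std` must be >= 0")
  if (red_noise_coefficient < 0 || red_noise_coefficient >= 1)
    stop("`red_noise_coefficient` must be in [0, 1)")
  if (smoothing_window < 1) stop("`smoothing_window` must be >= 1")
  structure(list(noise_std = noise_std,
                 red_noise_coefficient = red_noise_coefficient,
                 smoothing_window = as.integer(smoothing_window),
                 obs_sigma = obs_sigma),
            class = "radar_noise_config")
}

#' Depth-sensor silhouette model configuration
#'
#' The synthetic depth track models the silhouette of the walking person as
#' an ellipse (major axis along the walking direction) whose centre follows
#' a sine-shaped path oscillating laterally around the reference trajectory.
#' The reported position is the point of the ellipse boundary nearest the
#' depth sensor along the sensor-to-centre line, reproducing the bias of
#' depth cameras towards the visible side of the body.
#'
#' @param ellipse_semi_axes (a, b) semi-axes in metres; `a` along the walking
#'   direction.
#' @param sine_amplitude lateral oscillation amplitude in metres.
#' @param sine_period oscillation period in metres of arclength along the
#'   path.
#' @param fragment_fraction fraction of realisations fragmented by occlusion
#'   when generating a training set.
#' @param gap_mode `"geometric"` removes samples whose sensor-to-person line
#'   of sight crosses an obstacle; `"random"` removes random contiguous
#'   segments; `"auto"` uses geometric when the scenario has obstacles,
#'   random otherwise.
#' @param random_gaps parameters of the random mode: number of gap segments
#'   and their minimum/maximum length as fractions of the walk duration.
#' @param obs_sigma observation-noise standard deviation written into the
#'   per-sample covariance (used by the Kalman fuser).
#' @return an object of class `depth_model_config`.
#' @export
depth_model_config <- function(ellipse_semi_axes = c(0.25, 0.15),
                               sine_amplitude = 0.05,
                               sine_period = 1.2,
                               fragment_fraction = 0.5,
                               gap_mode = c("auto", "geometric", "random"),
                               random_gaps = c(n = 2, min_frac = 0.05,
                                               max_frac = 0.15),
                               obs_sigma = 0.10) {
  if (any(ellipse_semi_axes <= 0)) stop("ellipse semi-axes must be > 0")
  if (fragment_fraction < 0 || fragment_fraction > 1)
    stop("`fragment_fraction` must be in [0, 1]")
  if (sine_period <= 0) stop("`sine_period` must be > 0")
  structure(list(ellipse_semi_axes = as.numeric(ellipse_semi_axes),
                 sine_amplitude = sine_amplitude,
                 sine_period = sine_period,
                 fragment_fraction = fragment_fraction,
                 gap_mode = match.arg(gap_mode),
                 random_gaps = random_gaps,
                 obs_sigma = obs_sigma),
            class = "depth_model_config")
}

#' Construct a sensor track
#'
#' A sensor track is a data.frame with columns `t, x, y, sxx, sxy, syy`
#' (timestamps in seconds, positions in metres, per-sample observation-noise
#' covariance entries in square metres). Occlusion gaps are encoded by the
#' absence of rows.
#'
#' @param t,x,y numeric vectors of equal length; `t` strictly increasing.
#' @param sigma isotropic observation std in metres, or `NULL` if covariance
#'   columns are supplied directly.
#' @param sxx,sxy,syy covariance entries; default isotropic `sigma^2`.
#' @param sensor_id `"radar"` or `"depth"`.
#' @return an object of class `sensor_track`.
#' @export
sensor_track <- function(t, x, y, sigma = NULL,
                         sxx = NULL, sxy = NULL, syy = NULL,
                         sensor_id = "radar") {
  n <- length(t)
  if (length(x) != n || length(y) != n)
    stop("t, x, y must have equal length")
  if (n > 1 && any(diff(t) <= 0)) stop("timestamps must be strictly increasing")
  if (!is.null(sigma)) {
    sxx <- syy <- rep(sigma^2, n)
    sxy <- rep(0, n)
  }
  if (is.null(sxx)) { sxx <- syy <- rep(0, n); sxy <- rep(0, n) }
  tr <- data.frame(t = t, x = x, y = y, sxx = sxx, sxy = sxy, syy = syy)
  attr(tr, "sensor_id") <- sensor_id
  class(tr) <- c("sensor_track", "data.frame")
  tr
}

# Centred moving average with shrink-at-edges behaviour; window is a sample
# count. Left/right half-widths differ by one for even windows.
moving_average <- function(x, window) {
  n <- length(x)
  window <- as.integer(window)
  if (window <= 1L || n == 0L) return(x)
  hl <- (window - 1L) %/% 2L
  hr <- window - 1L - hl
  cs <- c(0, cumsum(x))
  i <- seq_len(n)
  lo <- pmax(1L, i - hl)
  hi <- pmin(n, i + hr)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# Stationary AR(1) ("red") noise of length n, coefficient a, stationary sd s.
red_noise <- function(n, a, s) {
  if (s == 0 || n == 0) return(numeric(n))
  w <- stats::rnorm(n)
  if (a == 0) return(s * w)
  e <- numeric(n)
  e[1] <- s * w[1]
  innov_sd <- s * sqrt(1 - a^2)
  for (i in seq_len(n)[-1]) e[i] <- a * e[i - 1] + innov_sd * w[i]
  e
}

#' Simulate an impulse-radar position track
#'
#' Corrupts each coordinate of the reference trajectory with zero-mean red
#' (AR(1)) noise of the configured stationary standard deviation and
#' applies a centred moving-average filter. The filter acts on the noise
#' sequence (the filter is linear, so this is the smoothing of the
#' corrupted signal minus the edge distortion of the noiseless path), which
#' keeps the zero-noise limit an exact identity. Deterministic under a
#' fixed seed.
#'
#' @param traj a `trajectory` (sampled at the radar rate).
#' @param cfg a [radar_noise_config()].
#' @param seed integer seed.
#' @return a `sensor_track` with `sensor_id = "radar"`.
#' @export
simulate_radar_track <- function(traj, cfg = radar_noise_config(), seed = 1L) {
  stopifnot(nrow(traj) > 0)
  old <- globalenv()$.Random.seed
  on.exit(restore_rng(old), add = TRUE)
  set.seed(seed)
  n <- nrow(traj)
  ex <- moving_average(red_noise(n, cfg$red_noise_coefficient, cfg$noise_std),
                       cfg$smoothing_window)
  ey <- moving_average(red_noise(n, cfg$red_noise_coefficient, cfg$noise_std),
                       cfg$smoothing_window)
  sensor_track(traj$t, traj$x + ex, traj$y + ey, sigma = cfg$obs_sigma,
               sensor_id = "radar")
}

restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}

# TRUE if segment p-q intersects (or lies inside) the axis-aligned rectangle
# c(xmin, xmax, ymin, ymax). Liang-Barsky clipping.
segment_intersects_rect <- function(p, q, rect) {
  d <- q - p
  t0 <- 0; t1 <- 1
  pp <- c(-d[1], d[1], -d[2], d[2])
  qq <- c(p[1] - rect[1], rect[2] - p[1], p[2] - rect[3], rect[4] - p[2])
  for (k in 1:4) {
    if (pp[k] == 0) {
      if (qq[k] < 0) return(FALSE)
    } else {
      r <- qq[k] / pp[k]
      if (pp[k] < 0) {
        if (r > t1) return(FALSE)
        if (r > t0) t0 <- r
      } else {
        if (r < t0) return(FALSE)
        if (r < t1) t1 <- r
      }
    }
  }
  TRUE
}

# Headings along a path from finite differences; zero-displacement steps
# carry the previous heading (0 before any motion).
path_headings <- function(x, y) {
  n <- length(x)
  dx <- diff(x); dy <- diff(y)
  th <- atan2(dy, dx)
  moved <- (dx != 0) | (dy != 0)
  last <- 0
  for (i in seq_len(n - 1L)) {
    if (moved[i]) last <- th[i] else th[i] <- last
  }
  c(th[1], th) # heading at sample i ~ heading of segment arriving at i
}

#' Simulate a depth-sensor position track
#'
#' Models the person's silhouette as an ellipse whose centre follows the
#' reference trajectory displaced laterally by
#' `sine_amplitude * sin(2 * pi * arclength / sine_period)`. The reported
#' position is the point of the ellipse boundary nearest the depth sensor on
#' the sensor-to-centre line. With `fragment = TRUE`, samples are removed
#' either where the sensor's line of sight to the person crosses an obstacle
#' (geometric mode) or in random contiguous segments (random mode).
#'
#' @param traj a `trajectory` (any rate; it is resampled at the depth rate).
#' @param cfg a [depth_model_config()].
#' @param scenario the [scenario_config()] providing the depth-sensor
#'   position, obstacles, and depth rate.
#' @param fragment logical; apply occlusion fragmentation.
#' @param seed integer seed (used by the random gap mode).
#' @param rate depth sampling rate in Hz; default from the scenario.
#' @return a `sensor_track` with `sensor_id = "depth"`; occluded samples are
#'   absent rows.
#' @export
simulate_depth_track <- function(traj, cfg = depth_model_config(), scenario,
                                 fragment = FALSE, seed = 1L, rate = NULL) {
  stopifnot(nrow(traj) > 0)
  if (is.null(rate)) rate <- unname(scenario$sensor_rates["depth"])
  sensor <- scenario$depth_sensor_position
  duration <- attr(traj, "duration")
  if (is.null(duration)) duration <- traj$t[nrow(traj)]
  n <- floor(duration * rate) + 1L
  t <- (seq_len(n) - 1L) / rate
  ref <- interpolate_trajectory(traj, t)
  s <- trajectory_arclength(ref)
  th <- path_headings(ref$x, ref$y)
  nx <- -sin(th); ny <- cos(th)  # unit normal (left of walking direction)
  off <- cfg$sine_amplitude * sin(2 * pi * s / cfg$sine_period)
  cx <- ref$x + off * nx
  cy <- ref$y + off * ny
  dxs <- sensor[1] - cx
  dys <- sensor[2] - cy
  dist <- sqrt(dxs^2 + dys^2)
  if (any(dist < 1e-9))
    stop("person position coincides with the depth sensor position")
  ux <- dxs / dist; uy <- dys / dist
  a <- cfg$ellipse_semi_axes[1]; b <- cfg$ellipse_semi_axes[2]
  # sensor-to-centre direction in the ellipse frame (major axis at heading)
  c1 <- ux * cos(th) + uy * sin(th)
  c2 <- -ux * sin(th) + uy * cos(th)
  u <- 1 / sqrt((c1 / a)^2 + (c2 / b)^2)
  px <- cx + u * ux
  py <- cy + u * uy
  keep <- rep(TRUE, n)
  if (fragment) {
    mode <- cfg$gap_mode
    if (mode == "auto")
      mode <- if (length(scenario$obstacle_regions) > 0) "geometric" else "random"
    if (mode == "geometric") {
      for (ob in scenario$obstacle_regions) {
        for (i in which(keep)) {
          if (segment_intersects_rect(sensor, c(cx[i], cy[i]), ob))
            keep[i] <- FALSE
        }
      }
    } else {
      old <- globalenv()$.Random.seed
      on.exit(restore_rng(old), add = TRUE)
      set.seed(seed)
      ng <- as.integer(cfg$random_gaps[["n"]])
      for (g in seq_len(ng)) {
        len <- stats::runif(1, cfg$random_gaps[["min_frac"]],
                            cfg$random_gaps[["max_frac"]]) * n
        start <- floor(stats::runif(1, 1, n - len))
        keep[seq(start, min(n, start + ceiling(len)))] <- FALSE
      }
    }
  }
  sensor_track(t[keep], px[keep], py[keep], sigma = cfg$obs_sigma,
               sensor_id = "depth")
}

# Derive n reproducible child seeds from a master seed without disturbing
# the caller's RNG stream.
derive_seeds <- function(seed, n) {
  old <- globalenv()$.Random.seed
  on.exit(restore_rng(old), add = TRUE)
  set.seed(seed)
  sample.int(2147483646L, n)
}

#' Generate a paired radar/depth training set
#'
#' For each scenario, generates `n_per_traj` realisations of a radar track
#' and a depth track over the same reference trajectory, both sampled at the
#' training rate (10 Hz by default). Exactly
#' `round(fragment_fraction * n_per_traj)` of the depth realisations per
#' scenario are fragmented by occlusion. Fully reproducible under `seed`.
#'
#' @param scenarios list of [scenario_config()] (or one config).
#' @param n_per_traj realisations per scenario.
#' @param fragment_fraction fraction of depth realisations fragmented.
#' @param seed master integer seed.
#' @param rate acquisition rate in Hz for both sensors (training data).
#' @param radar_cfg,depth_cfg noise/silhouette model configurations.
#' @return a list of records with elements `scenario_id`, `realisation`,
#'   `trajectory`, `radar`, `depth`, `fragmented`; class `training_set`.
#' @export
generate_training_set <- function(scenarios, n_per_traj = 40L,
                                  fragment_fraction = 0.5, seed = 1L,
                                  rate = 10,
                                  radar_cfg = radar_noise_config(),
                                  depth_cfg = depth_model_config()) {
  if (inherits(scenarios, "scenario_config")) scenarios <- list(scenarios)
  if (n_per_traj < 1L) stop("`n_per_traj` must be >= 1")
  ids <- names(scenarios)
  if (is.null(ids)) ids <- as.character(seq_along(scenarios))
  n_frag <- round(fragment_fraction * n_per_traj)
  seeds <- derive_seeds(seed, 2L * n_per_traj * length(scenarios))
  out <- vector("list", n_per_traj * length(scenarios))
  k <- 0L
  for (j in seq_along(scenarios)) {
    sc <- scenarios[[j]]
    traj <- build_reference_trajectory(sc, rate)
    for (r in seq_len(n_per_traj)) {
      k <- k + 1L
      fragmented <- r <= n_frag
      out[[k]] <- list(
        scenario_id = ids[j],
        realisation = r,
        trajectory = traj,
        radar = simulate_radar_track(traj, radar_cfg, seed = seeds[2L * k - 1L]),
        depth = simulate_depth_track(traj, depth_cfg, sc, fragment = fragmented,
                                     seed = seeds[2L * k], rate = rate),
        fragmented = fragmented)
    }
  }
  class(out) <- c("training_set", "list")
  out
}
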