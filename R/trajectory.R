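#' Scenario configuration for a walking experiment
#'
#' Describes one movement scenario: the waypoints of the reference path, the
#' constant walking speed, the per-sensor acquisition rates, the number of
#' walk realisations, the obstacles that may occlude the person from the
#' depth sensor, and the depth-sensor position.
#'
#' @param waypoints numeric matrix (or 2-column data.frame) of ordered
#'   waypoint coordinates in metres; at least two rows.
#' @param walking_speed walking speed in m/s (> 0).
#' @param sensor_rates named numeric vector with elements `radar` and `depth`,
#'   in Hz.
#' @param n_realisations number of walk realisations to simulate.
#' @param obstacle_regions list of axis-aligned rectangles, each
#'   `c(xmin, xmax, ymin, ymax)` in metres.
#' @param depth_sensor_position numeric (x, y) position of the depth sensor
#'   in metres.
#' @param seed integer seed attached to the scenario.
#' @return an object of class `scenario_config`.
#' @export
scenario_config <- function(waypoints,
                            walking_speed,
                            sensor_rates = c(radar = 10, depth = 30),
                            n_realisations = 1L,
                            obstacle_regions = list(),
                            depth_sensor_position = c(2, -1),
                            seed = 1L) {
  waypoints <- as.matrix(waypoints)
  storage.mode(waypoints) <- "double"
  if (ncol(waypoints) != 2L || nrow(waypoints) < 2L)
    stop("`waypoints` must be an n x 2 matrix with at least two rows")
  if (!is.numeric(walking_speed) || walking_speed <= 0)
    stop("`walking_speed` must be > 0")
  if (any(sensor_rates <= 0)) stop("`sensor_rates` must be > 0")
  if (n_realisations < 1L) stop("`n_realisations` must be >= 1")
  seglen <- sqrt(rowSums(diff(waypoints)^2))
  if (any(seglen == 0))
    stop("coincident consecutive waypoints at index ",
         which(seglen == 0)[1L], "; remove duplicates")
  for (ob in obstacle_regions) {
    if (length(ob) != 4L || ob[1] >= ob[2] || ob[3] >= ob[4])
      stop("each obstacle must be c(xmin, xmax, ymin, ymax) with xmin < xmax, ymin < ymax")
  }
  structure(
    list(waypoints = waypoints,
         walking_speed = as.numeric(walking_speed),
         sensor_rates = sensor_rates,
         n_realisations = as.integer(n_realisations),
         obstacle_regions = obstacle_regions,
         depth_sensor_position = as.numeric(depth_sensor_position),
         seed = as.integer(seed)),
    class = "scenario_config")
}

#' Reference trajectory sampled from a scenario
#'
#' Samples the polyline through the scenario waypoints at the constant
#' walking speed, emitting one position every `1/rate` seconds starting at
#' t = 0. The walk duration is the total path length divided by the speed,
#' so the emitted sample count is `floor(duration * rate) + 1`.
#'
#' @param config a [scenario_config()].
#' @param rate sampling rate in Hz.
#' @return a `trajectory`: data.frame with columns `t`, `x`, `y` and
#'   attributes `walking_speed` and `duration`.
#' @export
build_reference_trajectory <- function(config, rate) {
  stopifnot(inherits(config, "scenario_config"))
  if (!is.numeric(rate) || rate <= 0) stop("`rate` must be > 0")
  wp <- config$waypoints
  v <- config$walking_speed
  seglen <- sqrt(rowSums(diff(wp)^2))
  cumlen <- c(0, cumsum(seglen))
  total <- cumlen[length(cumlen)]
  duration <- total / v
  n <- floor(duration * rate) + 1L
  t <- (seq_len(n) - 1L) / rate
  s <- pmin(t * v, total)
  x <- stats::approx(cumlen, wp[, 1], xout = s)$y
  y <- stats::approx(cumlen, wp[, 2], xout = s)$y
  traj <- data.frame(t = t, x = x, y = y)
  attr(traj, "walking_speed") <- v
  attr(traj, "duration") <- duration
  attr(traj, "path_length") <- total
  class(traj) <- c("trajectory", "data.frame")
  traj
}

#' Arclength along a trajectory
#'
#' Cumulative Euclidean path length at each sample, starting at 0.
#'
#' @param traj a `trajectory` or any data.frame with `x`, `y` columns.
#' @return numeric vector, same length as the track.
#' @export
trajectory_arclength <- function(traj) {
  n <- nrow(traj)
  if (n < 2L) return(rep(0, n))
  c(0, cumsum(sqrt(diff(traj$x)^2 + diff(traj$y)^2)))
}

#' Linearly interpolate a trajectory at new timestamps
#'
#' @param traj a `trajectory`.
#' @param t numeric timestamps, within the trajectory time span.
#' @return data.frame with columns `t`, `x`, `y`.
#' @export
interpolate_trajectory <- function(traj, t) {
  data.frame(
    t = t,
    x = stats::approx(traj$t, traj$x, xout = t, rule = 2)$y,
    y = stats::approx(traj$t, traj$y, xout = t, rule = 2)$y)
}

# Waypoint sets approximating the four training paths (a rectangle, a
# serpentine, an L-shape and a diagonal) within a 4 m x 4 m monitored area.
# They are configuration, not constants: any scenario_config works.

#' Built-in training scenario geometries
#'
#' Four reference paths within a 4 m x 4 m area used, by default, for the
#' generation of the neural-network training data: a rectangle lap, a
#' serpentine, an L-shape, and a diagonal.
#'
#' @param walking_speed walking speed in m/s shared by all four scenarios.
#' @param depth_sensor_position (x, y) position of the depth sensor.
#' @return named list of four [scenario_config()] objects.
#' @export
training_scenarios <- function(walking_speed = 0.8,
                               depth_sensor_position = c(2, -1)) {
  wps <- list(
    rectangle = rbind(c(2.0, 0.5), c(3.5, 0.5), c(3.5, 3.5),
                      c(0.5, 3.5), c(0.5, 0.5), c(2.0, 0.5)),
    serpentine = rbind(c(0.5, 0.5), c(3.5, 0.5), c(3.5, 1.5), c(0.5, 1.5),
                       c(0.5, 2.5), c(3.5, 2.5), c(3.5, 3.5), c(0.5, 3.5)),
    lshape = rbind(c(0.5, 0.5), c(3.5, 0.5), c(3.5, 3.5)),
    diagonal = rbind(c(0.5, 0.5), c(3.5, 3.5)))
  lapply(wps, function(w)
    scenario_config(w, walking_speed = walking_speed,
                    sensor_rates = c(radar = 10, depth = 10),
                    depth_sensor_position = depth_sensor_position))
}
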