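#' Motion-detection configuration
#'
#' Motion is declared at sample `n` when the displacement over the trailing
#' window of length `T_m` exceeds the threshold `D`, scaled by the actual
#' window span (so partial windows at the start of a track are handled
#' proportionally).
#'
#' @param T_m window length in seconds.
#' @param D displacement threshold in metres.
#' @return an object of class `motion_config`.
#' @export
motion_config <- function(T_m = 0.45, D = 0.1) {
  if (T_m <= 0 || D <= 0) stop("T_m and D must be > 0")
  structure(list(T_m = T_m, D = D), class = "motion_config")
}

#' Turn-detection configuration
#'
#' A turn is declared when the absolute accumulated change of walking
#' direction over a trailing window of length `T_t` exceeds `Phi` (and is
#' below pi, excluding direction reversals that wrap past a half-turn
#' within the window).
#'
#' @param T_t window length in seconds.
#' @param Phi heading-change threshold in radians, in (0, pi).
#' @return an object of class `turn_config`.
#' @export
turn_config <- function(T_t = 1, Phi = 1.05) {
  if (T_t <= 0) stop("T_t must be > 0")
  if (Phi <= 0 || Phi >= pi) stop("Phi must be in (0, pi)")
  structure(list(T_t = T_t, Phi = Phi), class = "turn_config")
}

# earliest index n0 (1-based) with t[n0] >= t[n] - window, searched over
# 1..n-1; vectorised over all n with a moving pointer
trailing_window_starts <- function(t, window) {
  n <- length(t)
  n0 <- integer(n)
  ptr <- 1L
  for (i in seq_len(n)) {
    while (ptr < i && t[ptr] < t[i] - window) ptr <- ptr + 1L
    n0[i] <- min(ptr, max(1L, i - 1L))
  }
  n0
}

#' Detect intervals of motion
#'
#' Produces the binary motion indicator: `b[n] = 1` when the displacement
#' between sample `n` and the start of its trailing window exceeds
#' `(t[n] - t[n0]) / T_m * D`. The first sample is always 0.
#'
#' @param track data.frame with `t`, `x`, `y` (any track type).
#' @param cfg a [motion_config()].
#' @return a `binary_indicator`: data.frame `t`, `value` with attributes
#'   `kind = "motion"` and `closed = FALSE`.
#' @export
detect_motion <- function(track, cfg = motion_config()) {
  n <- nrow(track)
  if (n < 2L) stop("at least two samples required")
  if (any(diff(track$t) <= 0)) stop("timestamps must be strictly increasing")
  n0 <- trailing_window_starts(track$t, cfg$T_m)
  d <- sqrt((track$x - track$x[n0])^2 + (track$y - track$y[n0])^2)
  b <- as.integer(d > (track$t - track$t[n0]) / cfg$T_m * cfg$D)
  b[1] <- 0L
  binary_indicator(track$t, b, kind = "motion")
}

binary_indicator <- function(t, value, kind, closed = FALSE) {
  ind <- data.frame(t = t, value = as.integer(value))
  attr(ind, "kind") <- kind
  attr(ind, "closed") <- closed
  class(ind) <- c("binary_indicator", "data.frame")
  ind
}

# number of samples within a time interval `window` at the track's rate
structuring_element_length <- function(t, window) {
  if (length(t) < 2L) return(1L)
  step <- stats::median(diff(t))
  max(1L, as.integer(floor(window / step + 1e-9)) + 1L)
}

# binary dilation (max filter); outside-of-signal values count as 0
binary_dilate <- function(v, len) {
  if (len <= 1L) return(v)
  hl <- (len - 1L) %/% 2L
  hr <- len - 1L - hl
  n <- length(v)
  out <- integer(n)
  for (i in seq_len(n)) {
    lo <- max(1L, i - hl); hi <- min(n, i + hr)
    out[i] <- max(v[lo:hi])
  }
  out
}

# binary erosion (min filter); outside-of-signal values count as 1, so the
# closing is extensive at the borders
binary_erode <- function(v, len) {
  if (len <= 1L) return(v)
  hl <- (len - 1L) %/% 2L
  hr <- len - 1L - hl
  n <- length(v)
  out <- integer(n)
  for (i in seq_len(n)) {
    lo <- max(1L, i - hl); hi <- min(n, i + hr)
    out[i] <- min(v[lo:hi])
  }
  out
}

#' Morphological closing of a binary indicator
#'
#' Dilation followed by erosion with a flat structuring element whose
#' length equals the number of samples spanning `window` seconds at the
#' track's rate. Closing fills 0-gaps shorter than the element inside runs
#' of 1s; values outside the signal count as 0 for the dilation and 1 for
#' the erosion, which makes the operation extensive and idempotent also at
#' the borders.
#'
#' @param indicator a `binary_indicator`.
#' @param window structuring-element span in seconds.
#' @return the closed `binary_indicator` (`closed` attribute set).
#' @export
morphological_close <- function(indicator, window) {
  if (window <= 0) stop("`window` must be > 0")
  len <- structuring_element_length(indicator$t, window)
  v <- binary_erode(binary_dilate(indicator$value, len), len)
  binary_indicator(indicator$t, v, kind = attr(indicator, "kind"),
                   closed = TRUE)
}

# wrap angles into (-pi, pi]
wrap_angle <- function(a) {
  w <- (a + pi) %% (2 * pi) - pi
  w[w == -pi] <- pi
  w
}

#' Detect turns
#'
#' Estimates the walking direction at each step with the four-quadrant
#' arctangent of consecutive positions, wraps successive heading differences
#' into (-pi, pi], and flags sample `n` when the absolute sum of heading
#' changes over the trailing window `T_t` lies strictly between `Phi` and
#' pi. After morphological closing (element spanning `T_t`), the number of
#' turns is the number of rising edges of the closed indicator.
#'
#' @param track data.frame with `t`, `x`, `y`; at least three samples.
#' @param cfg a [turn_config()].
#' @return the closed `binary_indicator` with attributes `n_turns` and
#'   `turn_intervals` (list of `c(start, stop)` times).
#' @export
detect_turns <- function(track, cfg = turn_config()) {
  n <- nrow(track)
  if (n < 3L) stop("at least three samples required")
  th <- path_headings(track$x, track$y)[-1]       # heading of step into n, n>=2
  dth <- c(0, wrap_angle(diff(th)))               # heading change at n, n>=3
  cum <- c(0, 0, cumsum(dth[-1]))                 # cumulative over n>=3; len n
  n0 <- trailing_window_starts(track$t, cfg$T_t)
  # windowed sum over nu in (n0+2)..n of heading changes
  b <- integer(n)
  for (i in 3:n) {
    lo <- max(n0[i] + 2L, 3L)
    if (lo > i) next
    s <- cum[i] - cum[lo - 1L]
    b[i] <- as.integer(abs(s) > cfg$Phi && abs(s) < pi)
  }
  ind <- binary_indicator(track$t, b, kind = "turn")
  closed <- morphological_close(ind, cfg$T_t)
  edges <- diff(c(0L, closed$value))
  starts <- which(edges == 1L)
  stops <- which(diff(c(closed$value, 0L)) == -1L)
  attr(closed, "n_turns") <- length(starts)
  attr(closed, "turn_intervals") <- Map(function(a, b) c(closed$t[a], closed$t[b]),
                                        starts, stops)
  closed
}

#' Travelled distance along a track
#'
#' Sum of Euclidean distances between consecutive positions.
#'
#' @param track data.frame with `x`, `y`.
#' @return distance in metres (0 for a single sample).
#' @export
travelled_distance <- function(track) {
  if (nrow(track) < 2L) return(0)
  sum(sqrt(diff(track$x)^2 + diff(track$y)^2))
}

# total duration of 1-runs, with interval edges at midpoints between
# samples (clamped to the track ends)
indicator_time <- function(indicator) {
  v <- indicator$value
  t <- indicator$t
  n <- length(v)
  if (n == 0L || all(v == 0L)) return(0)
  mid <- c(t[1], (t[-n] + t[-1]) / 2, t[n])  # mid[i], mid[i+1] bracket sample i
  sum((mid[-1] - mid[-(n + 1)])[v == 1L])
}

#' Extract motion intervals and the time spent in motion
#'
#' @param indicator a closed motion `binary_indicator`.
#' @return list with `time_in_motion` (seconds) and `intervals` (list of
#'   `c(start, stop)` times).
#' @export
motion_intervals <- function(indicator) {
  v <- indicator$value
  starts <- which(diff(c(0L, v)) == 1L)
  stops <- which(diff(c(v, 0L)) == -1L)
  list(time_in_motion = indicator_time(indicator),
       intervals = Map(function(a, b) c(indicator$t[a], indicator$t[b]),
                       starts, stops))
}

#' Mean walking speed
#'
#' Travelled distance divided by the time spent in motion. With
#' `in_motion_only = TRUE` the distance sum is restricted to segments whose
#' endpoints are flagged as in motion.
#'
#' @param track data.frame with `t`, `x`, `y`.
#' @param motion the closed motion `binary_indicator`, aligned with `track`.
#' @param in_motion_only restrict the distance to in-motion segments.
#' @return speed in m/s, or `NA_real_` when no motion was detected.
#' @export
mean_walking_speed <- function(track, motion, in_motion_only = FALSE) {
  if (nrow(track) != nrow(motion)) stop("track and indicator lengths differ")
  tm <- indicator_time(motion)
  if (tm <= 0) return(NA_real_)
  if (in_motion_only) {
    seg <- sqrt(diff(track$x)^2 + diff(track$y)^2)
    use <- motion$value[-1] == 1L & motion$value[-nrow(track)] == 1L
    s <- sum(seg[use])
  } else {
    s <- travelled_distance(track)
  }
  s / tm
}

#' Smooth a track with a centred moving average
#'
#' Applies a centred moving-average filter of the given time span to each
#' coordinate; edge windows shrink, timestamps are unchanged. Used to
#' reduce the propagation of position-estimation errors into the gait
#' parameters.
#'
#' @param track data.frame with `t`, `x`, `y` (other columns preserved).
#' @param window filter span in seconds.
#' @return the smoothed track (same class).
#' @export
smooth_track <- function(track, window = 0.5) {
  if (window <= 0) stop("`window` must be > 0")
  len <- structuring_element_length(track$t, window)
  if (len %% 2L == 0L) len <- len - 1L
  track$x <- moving_average(track$x, len)
  track$y <- moving_average(track$y, len)
  track
}

#' Summarise the gait parameters of a track
#'
#' Runs motion detection (with closing), turn detection, travelled distance,
#' and mean-walking-speed estimation, returning the healthcare-related
#' summary.
#'
#' @param track data.frame with `t`, `x`, `y`.
#' @param motion_cfg a [motion_config()].
#' @param turn_cfg a [turn_config()].
#' @param smooth_window optional pre-smoothing span in seconds (`NULL` to
#'   skip).
#' @param in_motion_only restrict the distance to in-motion segments for the
#'   speed estimate.
#' @return a `gait_summary` list: `n_turns`, `distance`, `time_in_motion`,
#'   `mean_speed`, `motion_intervals`, `turn_intervals`.
#' @export
gait_summary <- function(track, motion_cfg = motion_config(),
                         turn_cfg = turn_config(), smooth_window = NULL,
                         in_motion_only = FALSE) {
  if (!is.null(smooth_window)) track <- smooth_track(track, smooth_window)
  motion <- morphological_close(detect_motion(track, motion_cfg),
                                motion_cfg$T_m)
  mi <- motion_intervals(motion)
  turns <- detect_turns(track, turn_cfg)
  structure(list(
    n_turns = attr(turns, "n_turns"),
    distance = travelled_distance(track),
    time_in_motion = mi$time_in_motion,
    mean_speed = mean_walking_speed(track, motion,
                                    in_motion_only = in_motion_only),
    motion_intervals = mi$intervals,
    turn_intervals = attr(turns, "turn_intervals")),
    class = "gait_summary")
}

#' @export
print.gait_summary <- function(x, ...) {
  cat("Gait summary\n")
  cat(sprintf("  turns          : %d\n", x$n_turns))
  cat(sprintf("  distance       : %.3f m\n", x$distance))
  cat(sprintf("  time in motion : %.2f s\n", x$time_in_motion))
  cat(sprintf("  mean speed     : %s m/s\n",
              if (is.na(x$mean_speed)) "undefined"
              else sprintf("%.3f", x$mean_speed)))
  invisible(x)
}
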