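#' Kalman-filter model parameters
#'
#' Parameters of the nearly-constant-velocity tracking model: the person
#' walks with an approximately constant velocity, perturbed by a small
#' zero-mean random acceleration with per-axis standard deviation
#' `sigma_alpha` between consecutive time instants.
#'
#' @param sigma_alpha per-axis acceleration std `(x, y)` in m/s^2; a scalar
#'   is recycled to both axes.
#' @param initial_state optional 4-vector `[x, vx, y, vy]`; when `NULL`, the
#'   filter initialises from the first observation with zero velocity.
#' @param initial_covariance 4x4 initial state covariance.
#' @return an object of class `kf_model_params`.
#' @export
kf_model_params <- function(sigma_alpha = 0.5,
                            initial_state = NULL,
                            initial_covariance = diag(c(1, 1, 1, 1))) {
  sigma_alpha <- rep(as.numeric(sigma_alpha), length.out = 2L)
  if (any(sigma_alpha < 0)) stop("`sigma_alpha` must be >= 0")
  P0 <- as.matrix(initial_covariance)
  if (!isTRUE(all.equal(P0, t(P0))) || any(diag(P0) < 0))
    stop("`initial_covariance` must be symmetric with nonnegative diagonal")
  structure(list(sigma_alpha = sigma_alpha,
                 initial_state = initial_state,
                 initial_covariance = P0),
            class = "kf_model_params")
}

#' Kalman-filter state
#'
#' @param state 4-vector `[x, vx, y, vy]` (metres, metres/second).
#' @param covariance symmetric 4x4 covariance matrix.
#' @param time timestamp in seconds.
#' @return an object of class `kf_state`.
#' @export
kf_state <- function(state, covariance, time = 0) {
  structure(list(state = as.numeric(state),
                 covariance = as.matrix(covariance),
                 time = time),
            class = "kf_state")
}

#' A single position observation
#'
#' @param time timestamp in seconds.
#' @param z 2-vector (x, y) in metres.
#' @param covariance 2x2 symmetric positive-definite observation-noise
#'   covariance.
#' @param source sensor identifier.
#' @return an object of class `kf_observation`.
#' @export
kf_observation <- function(time, z, covariance, source = "radar") {
  structure(list(time = time, z = as.numeric(z),
                 covariance = as.matrix(covariance), source = source),
            class = "kf_observation")
}

# state transition matrix for the [x, vx, y, vy] ordering
kf_transition_matrix <- function(dt) {
  F2 <- matrix(c(1, 0, dt, 1), 2, 2)
  rbind(cbind(F2, matrix(0, 2, 2)), cbind(matrix(0, 2, 2), F2))
}

# process-noise covariance: per-axis blocks [dt^4/4, dt^3/2; dt^3/2, dt^2]
# scaled by the axis acceleration variance
kf_process_noise <- function(dt, sigma_alpha) {
  blk <- matrix(c(dt^4 / 4, dt^3 / 2, dt^3 / 2, dt^2), 2, 2)
  rbind(cbind(blk * sigma_alpha[1]^2, matrix(0, 2, 2)),
        cbind(matrix(0, 2, 2), blk * sigma_alpha[2]^2))
}

kf_observation_matrix <- function() {
  matrix(c(1, 0, 0, 0,
           0, 0, 1, 0), 2, 4, byrow = TRUE)
}

symmetrise <- function(P) (P + t(P)) / 2

#' Kalman time update (prediction)
#'
#' Propagates the state estimate over `dt` seconds under the
#' nearly-constant-velocity model: `x_pre = F x`,
#' `P_pre = F P F' + Q`.
#'
#' @param state a [kf_state()].
#' @param dt time step in seconds (> 0).
#' @param params a [kf_model_params()].
#' @return a `kf_state` (the pre-estimate) with attribute `process_noise`
#'   holding the 4x4 `Q` used.
#' @export
kf_predict <- function(state, dt, params) {
  if (dt <= 0) stop("`dt` must be > 0")
  F <- kf_transition_matrix(dt)
  Q <- kf_process_noise(dt, params$sigma_alpha)
  pre <- kf_state(F %*% state$state,
                  symmetrise(F %*% state$covariance %*% t(F) + Q),
                  time = state$time + dt)
  attr(pre, "process_noise") <- Q
  pre
}

#' Kalman measurement update
#'
#' Folds one position observation into the pre-estimate: the innovation is
#' the observation minus the predicted observation, the gain weighs it by
#' the inverse innovation covariance, and the posterior covariance is
#' `(I - G H) P_pre`, symmetrised for numerical hygiene.
#'
#' @param pre a `kf_state` pre-estimate (output of [kf_predict()], or the
#'   previous posterior when the observation shares its timestamp).
#' @param obs a [kf_observation()] at the pre-estimate's time.
#' @return a `kf_state` posterior with attribute `diagnostics` (a list with
#'   `pre_state`, `pre_covariance`, `predicted_observation`, `innovation`,
#'   `innovation_covariance`, `gain`).
#' @export
kf_update <- function(pre, obs) {
  H <- kf_observation_matrix()
  zhat <- as.numeric(H %*% pre$state)
  innov <- obs$z - zhat
  S <- H %*% pre$covariance %*% t(H) + obs$covariance
  Sinv <- tryCatch(solve(S), error = function(e)
    stop("singular innovation covariance: ", conditionMessage(e)))
  G <- pre$covariance %*% t(H) %*% Sinv
  post_state <- pre$state + as.numeric(G %*% innov)
  post_cov <- symmetrise((diag(4) - G %*% H) %*% pre$covariance)
  post <- kf_state(post_state, post_cov, time = obs$time)
  attr(post, "diagnostics") <- list(
    pre_state = pre$state,
    pre_covariance = pre$covariance,
    predicted_observation = zhat,
    innovation = innov,
    innovation_covariance = S,
    gain = G)
  post
}

#' Fuse radar and depth tracks with a Kalman filter
#'
#' Merges the two asynchronous observation streams into one time-ordered
#' stream and runs the predict/update recursion, each observation weighted
#' by its own per-sample covariance. At identical timestamps, the radar
#' observation is processed first and the depth observation follows with no
#' intervening prediction (dt = 0), which is algebraically equivalent to a
#' single stacked-observation update. The posterior position (and velocity)
#' is emitted at every observation time.
#'
#' @param radar,depth `sensor_track` objects (either may be empty).
#' @param params a [kf_model_params()].
#' @return a `fused_track`: data.frame `t, x, y, vx, vy` with attribute
#'   `covariances` (list of 4x4 posterior covariances).
#' @export
kf_fuse_tracks <- function(radar, depth, params = kf_model_params()) {
  obs <- merge_observation_streams(radar, depth)
  if (length(obs) == 0L) {
    warning("no observations; returning empty fused track")
    out <- data.frame(t = numeric(0), x = numeric(0), y = numeric(0),
                      vx = numeric(0), vy = numeric(0))
    class(out) <- c("fused_track", "data.frame")
    return(out)
  }
  n <- length(obs)
  t <- numeric(n); x <- numeric(n); y <- numeric(n)
  vx <- numeric(n); vy <- numeric(n)
  covs <- vector("list", n)
  first <- obs[[1L]]
  if (is.null(params$initial_state)) {
    st <- kf_state(c(first$z[1], 0, first$z[2], 0),
                   params$initial_covariance, time = first$time)
  } else {
    st <- kf_state(params$initial_state, params$initial_covariance,
                   time = first$time)
  }
  st <- kf_update(st, first)
  t[1] <- first$time
  x[1] <- st$state[1]; vx[1] <- st$state[2]
  y[1] <- st$state[3]; vy[1] <- st$state[4]
  covs[[1]] <- st$covariance
  for (i in seq_len(n)[-1]) {
    ob <- obs[[i]]
    dt <- ob$time - st$time
    if (dt > 0) st <- kf_predict(st, dt, params)
    st <- kf_update(st, ob)
    t[i] <- ob$time
    x[i] <- st$state[1]; vx[i] <- st$state[2]
    y[i] <- st$state[3]; vy[i] <- st$state[4]
    covs[[i]] <- st$covariance
  }
  out <- data.frame(t = t, x = x, y = y, vx = vx, vy = vy)
  # one output row per time instant: at coincident radar/depth timestamps
  # keep the posterior after both updates
  keep <- c(diff(t) > 1e-9, TRUE)
  out <- out[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "covariances") <- covs[keep]
  class(out) <- c("fused_track", "data.frame")
  out
}

# time-ordered list of kf_observation; radar precedes depth on ties
merge_observation_streams <- function(radar, depth) {
  to_obs <- function(tr, src) {
    if (is.null(tr) || nrow(tr) == 0L) return(list())
    lapply(seq_len(nrow(tr)), function(i)
      kf_observation(tr$t[i], c(tr$x[i], tr$y[i]),
                     matrix(c(tr$sxx[i], tr$sxy[i], tr$sxy[i], tr$syy[i]), 2, 2),
                     source = src))
  }
  obs <- c(to_obs(radar, "radar"), to_obs(depth, "depth"))
  if (length(obs) == 0L) return(obs)
  times <- vapply(obs, `[[`, numeric(1), "time")
  src <- vapply(obs, `[[`, character(1), "source")
  obs[order(times, src != "radar")]
}
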