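#' Specification of a neural track fuser
#'
#' Both fusers take the four current sensor coordinates
#' `(x_radar, y_radar, x_depth, y_depth)` as exogenous inputs and emit one
#' fused `(x, y)` pair. The MLP maps each sample independently; the NARX
#' network additionally feeds its own two outputs back to the hidden layer
#' at the configured delays, so its estimate depends on the movement
#' history.
#'
#' @param kind `"mlp"` or `"narx"`.
#' @param n_hidden number of neurons in the single hidden layer (defaults:
#'   8 for the MLP, 6 for the NARX network).
#' @param feedback_delays positive integer output-feedback lags (NARX only;
#'   default `c(1, 2)`).
#' @param hidden_activation currently `"tanh"`.
#' @return an object of class `network_spec`.
#' @export
network_spec <- function(kind = c("mlp", "narx"), n_hidden = NULL,
                         feedback_delays = NULL,
                         hidden_activation = "tanh") {
  kind <- match.arg(kind)
  if (is.null(n_hidden)) n_hidden <- if (kind == "mlp") 8L else 6L
  if (kind == "mlp") {
    if (length(feedback_delays) > 0)
      stop("an MLP fuser has no feedback delays")
    feedback_delays <- integer(0)
  } else {
    if (is.null(feedback_delays)) feedback_delays <- c(1L, 2L)
    if (any(feedback_delays < 1))
      stop("feedback delays must be positive integers")
    feedback_delays <- sort(as.integer(feedback_delays))
  }
  structure(list(kind = kind,
                 n_inputs = 4L,
                 n_hidden = as.integer(n_hidden),
                 n_outputs = 2L,
                 feedback_delays = feedback_delays,
                 hidden_activation = hidden_activation),
            class = "network_spec")
}

#' Pair asynchronous radar and depth streams
#'
#' Builds one paired sample per radar timestamp. The depth channel is the
#' nearest-in-time depth sample within `window` seconds; when none exists
#' (occlusion), the last observed depth value is held and the `imputed`
#' flag is set; before any depth sample has been seen, the radar value is
#' used.
#'
#' @param radar,depth `sensor_track` objects; `radar` must be non-empty.
#' @param window pairing half-window in seconds; default 0.6 of the median
#'   radar sampling interval.
#' @return data.frame `t, xr, yr, xd, yd, imputed`.
#' @export
pair_sensor_streams <- function(radar, depth, window = NULL) {
  if (nrow(radar) == 0L) stop("radar track must be non-empty")
  if (is.null(window)) {
    step <- if (nrow(radar) > 1L) stats::median(diff(radar$t)) else 0.1
    window <- 0.6 * step
  }
  n <- nrow(radar)
  xd <- numeric(n); yd <- numeric(n)
  imputed <- logical(n)
  if (nrow(depth) == 0L) {
    xd <- radar$x; yd <- radar$y; imputed[] <- TRUE
  } else {
    dt_times <- depth$t
    idx <- findInterval(radar$t, dt_times)
    last_x <- NA_real_; last_y <- NA_real_
    for (i in seq_len(n)) {
      cand <- c(if (idx[i] >= 1L) idx[i], if (idx[i] < length(dt_times)) idx[i] + 1L)
      best <- cand[which.min(abs(dt_times[cand] - radar$t[i]))]
      if (length(best) == 1L && abs(dt_times[best] - radar$t[i]) <= window) {
        xd[i] <- depth$x[best]; yd[i] <- depth$y[best]
        last_x <- xd[i]; last_y <- yd[i]
      } else if (idx[i] >= 1L) {
        # hold the most recent depth sample at or before this time
        xd[i] <- depth$x[idx[i]]; yd[i] <- depth$y[idx[i]]
        imputed[i] <- TRUE
      } else if (!is.na(last_x)) {
        xd[i] <- last_x; yd[i] <- last_y
        imputed[i] <- TRUE
      } else {
        xd[i] <- radar$x[i]; yd[i] <- radar$y[i]
        imputed[i] <- TRUE
      }
    }
  }
  data.frame(t = radar$t, xr = radar$x, yr = radar$y,
             xd = xd, yd = yd, imputed = imputed)
}

# affine per-channel map onto [-1, 1] over the training range
fit_scaling <- function(M) {
  mn <- apply(M, 2, min)
  mx <- apply(M, 2, max)
  span <- mx - mn
  span[span == 0] <- 1
  list(min = mn, span = span)
}

apply_scaling <- function(M, sc) {
  sweep(sweep(M, 2, sc$min), 2, sc$span, "/") * 2 - 1
}

invert_scaling <- function(M, sc) {
  sweep(sweep((M + 1) / 2, 2, sc$span, "*"), 2, sc$min, "+")
}

nn_forward <- function(X, W) {
  A <- tanh(sweep(X %*% W$W1, 2, W$b1, "+"))
  list(A = A, Y = sweep(A %*% W$W2, 2, W$b2, "+"))
}

nn_gradients <- function(X, Y, W, fwd) {
  n <- nrow(X)
  dY <- 2 * (fwd$Y - Y) / (n * ncol(Y))
  dW2 <- t(fwd$A) %*% dY
  db2 <- colSums(dY)
  dA <- dY %*% t(W$W2)
  dZ <- dA * (1 - fwd$A^2)
  list(W1 = t(X) %*% dZ, b1 = colSums(dZ), W2 = dW2, b2 = db2)
}

nn_loss <- function(X, Y, W) {
  mean((nn_forward(X, W)$Y - Y)^2)
}

init_weights <- function(p, h, q) {
  list(W1 = matrix(stats::runif(p * h, -0.5, 0.5), p, h),
       b1 = stats::runif(h, -0.5, 0.5),
       W2 = matrix(stats::runif(h * q, -0.5, 0.5), h, q),
       b2 = rep(0, q))
}

# full-batch Adam on the weight list; returns the best-validation weights.
# `jitter` (optional) perturbs a copy of the training inputs each epoch —
# used to jitter the NARX feedback taps with fresh noise draws. `val_fn`
# scores candidate weights (default: open-loop MSE on Xval/Yval) and is
# evaluated every `val_every` epochs; the best-scoring weights are kept
# (early stopping after `patience` evaluations without improvement).
adam_train <- function(Xtr, Ytr, Xval, Yval, W, epochs, lr, patience,
                       jitter = NULL, val_fn = NULL, val_every = 1L) {
  if (is.null(val_fn)) val_fn <- function(W) nn_loss(Xval, Yval, W)
  m <- lapply(W, function(w) w * 0)
  v <- lapply(W, function(w) w * 0)
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  best <- W
  best_val <- val_fn(W)
  since <- 0L
  X0 <- Xtr
  for (ep in seq_len(epochs)) {
    if (!is.null(jitter)) Xtr <- jitter(X0)
    fwd <- nn_forward(Xtr, W)
    if (!all(is.finite(fwd$Y)))
      stop("training diverged: non-finite network output at epoch ", ep)
    g <- nn_gradients(Xtr, Ytr, W, fwd)
    for (k in names(W)) {
      m[[k]] <- b1 * m[[k]] + (1 - b1) * g[[k]]
      v[[k]] <- b2 * v[[k]] + (1 - b2) * g[[k]]^2
      mhat <- m[[k]] / (1 - b1^ep)
      vhat <- v[[k]] / (1 - b2^ep)
      W[[k]] <- W[[k]] - lr * mhat / (sqrt(vhat) + eps)
    }
    if (ep %% val_every == 0L || ep == epochs) {
      val <- val_fn(W)
      if (!is.finite(val))
        stop("training diverged: non-finite validation loss at epoch ", ep)
      if (val < best_val - 1e-12) {
        best_val <- val; best <- W; since <- 0L
      } else {
        since <- since + 1L
        if (since >= patience) break
      }
    }
  }
  list(weights = best, val_loss = best_val)
}

# closed-loop forward pass over one walk: X is the scaled exogenous input
# matrix, taps start from `seed_taps` (scaled), outputs are fed back at
# `lags`; returns the scaled output matrix
closed_loop_forward <- function(X, W, lags, seed_taps) {
  maxlag <- max(lags)
  n <- nrow(X)
  Y <- matrix(0, n, 2)
  for (i in seq_len(n)) {
    taps <- do.call(c, lapply(lags, function(L) {
      j <- i - L
      if (j >= 1L) Y[j, ] else seed_taps
    }))
    Y[i, ] <- nn_forward(matrix(c(X[i, ], taps), 1), W)$Y
  }
  Y
}

# Assemble (X, Y) matrices from a training_set. For the NARX network the
# reference outputs at the feedback lags are appended to the exogenous
# inputs (open-loop teacher forcing); rows without full lag history are
# dropped. Matrices are in physical units; scaling is applied by the
# caller.
build_training_matrices <- function(dataset, spec) {
  lags <- spec$feedback_delays
  maxlag <- if (length(lags)) max(lags) else 0L
  Xs <- list(); Ys <- list(); groups <- list()
  for (j in seq_along(dataset)) {
    rec <- dataset[[j]]
    paired <- pair_sensor_streams(rec$radar, rec$depth)
    ref <- interpolate_trajectory(rec$trajectory, paired$t)
    X <- cbind(paired$xr, paired$yr, paired$xd, paired$yd)
    Y <- cbind(ref$x, ref$y)
    if (maxlag > 0L) {
      n <- nrow(X)
      if (n <= maxlag) next
      fb <- do.call(cbind, lapply(lags, function(L)
        Y[seq_len(n - maxlag) + (maxlag - L), , drop = FALSE]))
      X <- cbind(X[(maxlag + 1):n, , drop = FALSE], fb)
      Y <- Y[(maxlag + 1):n, , drop = FALSE]
    }
    Xs[[length(Xs) + 1L]] <- X
    Ys[[length(Ys) + 1L]] <- Y
    groups[[length(groups) + 1L]] <- rep(j, nrow(X))
  }
  list(X = do.call(rbind, Xs), Y = do.call(rbind, Ys),
       group = unlist(groups))
}

#' Train a neural track fuser on a synthetic training set
#'
#' Scales inputs and targets channel-wise onto `[-1, 1]`, splits the walk
#' realisations into training and validation parts, and minimises the mean
#' squared error with a full-batch Adam optimiser, keeping the weights with
#' the best validation loss (early stopping). The NARX network is trained
#' open loop — the reference outputs are supplied at the feedback taps — and
#' applied closed loop. Reproducible under `seed`.
#'
#' @param spec a [network_spec()].
#' @param dataset a `training_set` from [generate_training_set()].
#' @param epochs maximum number of full-batch epochs.
#' @param lr Adam learning rate.
#' @param val_fraction fraction of realisations held out for validation.
#' @param patience epochs without validation improvement before stopping.
#' @param tap_noise standard deviation, in metres, of the zero-mean Gaussian
#'   jitter added to the feedback taps during NARX training. Pure teacher
#'   forcing presents the network with exact reference outputs at the taps,
#'   which the closed loop can never provide; jittering the taps makes the
#'   learned recursion robust to its own output errors and prevents
#'   closed-loop drift. Ignored for the MLP.
#' @param tap_noise_ar AR(1) coefficient of the tap jitter (the jitter is
#'   red, mimicking the slowly varying closed-loop output error).
#' @param refine number of scheduled-sampling refinement rounds for the
#'   NARX network: after the teacher-forced fit, the taps are replaced by
#'   the network's own closed-loop outputs (recomputed each round, no
#'   gradient through time) and training continues, so the tap
#'   distribution matches deployment. 0 disables refinement.
#' @param seed integer seed (weight initialisation, split, tap jitter).
#' @return a `trained_network`: list with `spec`, `weights`, `input_scaling`,
#'   `output_scaling`, `training_seed`, `training_loss` (MSE in m^2 on the
#'   training rows), `validation_loss` (scaled units).
#' @export
train_network <- function(spec, dataset, epochs = 2000L, lr = 0.01,
                          val_fraction = 0.2, patience = 400L,
                          tap_noise = 0.2, tap_noise_ar = 0.98,
                          refine = 2L, seed = 1L) {
  if (length(dataset) == 0L) stop("empty training set")
  mats <- build_training_matrices(dataset, spec)
  in_sc <- fit_scaling(mats$X[, 1:4, drop = FALSE])
  out_sc <- fit_scaling(mats$Y)
  Xs <- apply_scaling(mats$X[, 1:4, drop = FALSE], in_sc)
  old <- globalenv()$.Random.seed
  on.exit(restore_rng(old), add = TRUE)
  set.seed(seed)
  if (ncol(mats$X) > 4L) {
    nfb <- (ncol(mats$X) - 4L) / 2L
    fb <- mats$X[, -(1:4), drop = FALSE]
    for (k in seq_len(nfb)) {
      cols <- (2 * k - 1):(2 * k)
      fb[, cols] <- apply_scaling(fb[, cols, drop = FALSE], out_sc)
    }
    Xs <- cbind(Xs, fb)
  }
  Ys <- apply_scaling(mats$Y, out_sc)
  ids <- unique(mats$group)
  n_val <- max(1L, round(val_fraction * length(ids)))
  val_ids <- if (length(ids) > 1L) sample(ids, n_val) else ids
  val <- mats$group %in% val_ids & length(ids) > 1L
  if (!any(val)) val[seq_len(max(1L, nrow(Xs) %/% 5L))] <- TRUE
  jitter <- NULL
  if (ncol(Xs) > 4L && tap_noise > 0) {
    # Per-channel tap jitter scaled from metres into the [-1, 1] output
    # units, redrawn every epoch. The jitter is red (AR(1) within each
    # walk realisation) because closed-loop output errors vary slowly:
    # the network keeps its short-term trust in the taps but learns to
    # correct persistent offsets from the exogenous inputs.
    nfb <- (ncol(Xs) - 4L) / 2L
    sds <- rep(2 * tap_noise / out_sc$span, times = nfb)
    fb_cols <- 4L + seq_len(2L * nfb)
    runs <- rle(mats$group[!val])$lengths
    ar <- tap_noise_ar
    jitter <- function(X) {
      noise <- vapply(seq_along(fb_cols), function(j)
        unlist(lapply(runs, function(L) red_noise(L, ar, 1)),
               use.names = FALSE),
        numeric(nrow(X)))
      X[, fb_cols] <- X[, fb_cols] + noise %*% diag(sds, length(fb_cols))
      X
    }
  }
  W <- init_weights(ncol(Xs), spec$n_hidden, 2L)
  val_fn <- NULL; val_every <- 1L
  if (spec$kind == "narx") {
    # Model selection scores candidate weights in the mode the network is
    # deployed in: closed loop over the held-out walks, own outputs at the
    # taps. Evaluated periodically to bound the sequential-forward cost.
    lags <- spec$feedback_delays
    vg <- sort(unique(mats$group[val]))
    if (length(vg) > 8L) vg <- vg[round(seq(1, length(vg), length.out = 8))]
    val_walks <- lapply(vg, function(j) {
      rows <- which(mats$group == j)
      seed_xy <- apply_scaling(mats$X[rows[1], 1:2, drop = FALSE], out_sc)
      list(X = Xs[rows, 1:4, drop = FALSE], Y = Ys[rows, , drop = FALSE],
           seed = as.numeric(seed_xy))
    })
    val_fn <- function(W) {
      mean(vapply(val_walks, function(w) {
        Yhat <- closed_loop_forward(w$X, W, lags, w$seed)
        mean((Yhat - w$Y)^2)
      }, numeric(1)))
    }
    val_every <- 25L
  }
  fit <- adam_train(Xs[!val, , drop = FALSE], Ys[!val, , drop = FALSE],
                    Xs[val, , drop = FALSE], Ys[val, , drop = FALSE],
                    W, epochs = epochs, lr = lr,
                    patience = max(2L, as.integer(ceiling(patience / val_every))),
                    jitter = jitter, val_fn = val_fn, val_every = val_every)
  if (spec$kind == "narx" && refine > 0L) {
    # Scheduled-sampling refinement: rebuild the tap columns of the
    # training rows from the network's own closed-loop outputs, then
    # continue training from the current weights. Repeated so the tap
    # distribution tracks the improving network.
    lags <- spec$feedback_delays
    tg <- sort(unique(mats$group[!val]))
    tr_rows <- lapply(tg, function(j) which(mats$group == j))
    seeds_xy <- lapply(tr_rows, function(rows)
      as.numeric(apply_scaling(mats$X[rows[1], 1:2, drop = FALSE], out_sc)))
    tr_idx <- which(!val)
    for (it in seq_len(refine)) {
      Xref <- Xs
      for (k in seq_along(tg)) {
        rows <- tr_rows[[k]]
        Yhat <- closed_loop_forward(Xs[rows, 1:4, drop = FALSE],
                                    fit$weights, lags, seeds_xy[[k]])
        for (li in seq_along(lags)) {
          L <- lags[li]
          cols <- 4L + (2L * li - 1L):(2L * li)
          shifted <- rbind(
            matrix(rep(seeds_xy[[k]], each = min(L, nrow(Yhat))),
                   ncol = 2),
            Yhat[seq_len(max(0L, nrow(Yhat) - L)), , drop = FALSE])
          Xref[rows, cols] <- shifted
        }
      }
      fit <- adam_train(Xref[tr_idx, , drop = FALSE],
                        Ys[tr_idx, , drop = FALSE],
                        Xs[val, , drop = FALSE], Ys[val, , drop = FALSE],
                        fit$weights, epochs = max(200L, epochs %/% 2L),
                        lr = lr / 2,
                        patience = max(2L, as.integer(ceiling(patience / val_every))),
                        val_fn = val_fn, val_every = val_every)
    }
  }
  Yhat <- nn_forward(Xs[!val, , drop = FALSE], fit$weights)$Y
  train_mse <- mean((invert_scaling(Yhat, out_sc) -
                     mats$Y[!val, , drop = FALSE])^2)
  structure(list(spec = spec,
                 weights = fit$weights,
                 input_scaling = in_sc,
                 output_scaling = out_sc,
                 training_seed = as.integer(seed),
                 training_loss = train_mse,
                 validation_loss = fit$val_loss),
            class = "trained_network")
}

#' Apply a trained fuser to paired sensor samples
#'
#' The MLP maps every paired sample independently. The NARX network runs
#' closed loop: its own (scaled) outputs are fed back at the configured
#' delays; the taps before the first outputs exist are seeded from the
#' first radar position.
#'
#' @param net a `trained_network`.
#' @param samples paired samples from [pair_sensor_streams()].
#' @return a `fused_track` data.frame `t, x, y`.
#' @export
apply_network <- function(net, samples) {
  if (nrow(samples) == 0L) stop("no samples to fuse")
  spec <- net$spec
  X <- apply_scaling(cbind(samples$xr, samples$yr, samples$xd, samples$yd),
                     net$input_scaling)
  if (spec$kind == "mlp") {
    Y <- nn_forward(X, net$weights)$Y
  } else {
    lags <- spec$feedback_delays
    maxlag <- max(lags)
    n <- nrow(X)
    Y <- matrix(0, n, 2)
    seedrow <- apply_scaling(cbind(samples$xr[1], samples$yr[1]),
                             net$output_scaling)
    hist <- matrix(rep(seedrow, each = maxlag), maxlag, 2)
    for (i in seq_len(n)) {
      taps <- do.call(c, lapply(lags, function(L) {
        j <- i - L
        if (j >= 1L) Y[j, ] else hist[maxlag + j, ]
      }))
      Y[i, ] <- nn_forward(matrix(c(X[i, ], taps), 1), net$weights)$Y
    }
  }
  out <- as.data.frame(invert_scaling(Y, net$output_scaling))
  names(out) <- c("x", "y")
  out <- cbind(t = samples$t, out)
  class(out) <- c("fused_track", "data.frame")
  out
}

#' Fuse two sensor tracks with a trained network
#'
#' Convenience wrapper: pairs the streams and applies the network.
#'
#' @param net a `trained_network`.
#' @param radar,depth `sensor_track` objects.
#' @param window pairing window passed to [pair_sensor_streams()].
#' @return a `fused_track`.
#' @export
nn_fuse_tracks <- function(net, radar, depth, window = NULL) {
  apply_network(net, pair_sensor_streams(radar, depth, window = window))
}
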