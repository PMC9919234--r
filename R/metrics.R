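#' Position errors of an estimated track against a reference trajectory
#'
#' Interpolates the reference trajectory linearly at the estimate's
#' timestamps and subtracts it, giving per-sample absolute coordinate
#' errors and the Euclidean position error. Samples outside the reference
#' time span are dropped with a warning.
#'
#' @param estimate a track data.frame with `t`, `x`, `y` (fused or raw).
#' @param reference a `trajectory`.
#' @param realisation optional realisation identifier attached to the
#'   result.
#' @return an `error_sequence`: data.frame `t`, `dx`, `dy`, `dd`.
#' @export
position_errors <- function(estimate, reference, realisation = NA) {
  span <- range(reference$t)
  inside <- estimate$t >= span[1] - 1e-9 & estimate$t <= span[2] + 1e-9
  if (!all(inside)) {
    warning(sum(!inside), " sample(s) outside the reference time span dropped")
    estimate <- estimate[inside, , drop = FALSE]
  }
  if (nrow(estimate) == 0L)
    stop("no estimate samples within the reference time span")
  ref <- interpolate_trajectory(reference, estimate$t)
  dx <- estimate$x - ref$x
  dy <- estimate$y - ref$y
  err <- data.frame(t = estimate$t, dx = dx, dy = dy,
                    dd = sqrt(dx^2 + dy^2))
  attr(err, "realisation") <- realisation
  class(err) <- c("error_sequence", "data.frame")
  err
}

#' Empirical CDF of pooled position errors and uncertainty indicators
#'
#' Builds the exact step empirical cumulative distribution function of the
#' pooled position errors and the scalar indicators: AECDF (area under the
#' ECDF over `[0, 1]` m, integrated exactly over the step function), MEAE
#' (mean), MEDE (median), MAXE (maximum) and STDE (standard deviation,
#' `n - 1` denominator).
#'
#' @param errors an `error_sequence`, a list of them, or a bare numeric
#'   vector of position errors in metres.
#' @return an `ecdf_summary` list: `ecdf` (a [stats::ecdf()] function),
#'   `AECDF`, `MEAE`, `MEDE`, `MAXE`, `STDE`, `n`.
#' @export
ecdf_and_indicators <- function(errors) {
  d <- pool_errors(errors)
  if (length(d) == 0L) stop("no error values supplied")
  Fhat <- stats::ecdf(d)
  # exact area under the step ECDF on [0, 1]: integrate piecewise-constant
  # F between consecutive clamped order statistics
  ds <- sort(pmin(d, 1))
  M <- length(ds)
  knots <- c(0, ds, 1)
  heights <- c(0, seq_len(M) / M)  # F on [knots[i], knots[i+1])
  aecdf <- sum(diff(knots) * heights)
  structure(list(ecdf = Fhat,
                 AECDF = aecdf,
                 MEAE = mean(d),
                 MEDE = stats::median(d),
                 MAXE = max(d),
                 STDE = if (length(d) > 1L) stats::sd(d) else 0,
                 n = length(d)),
            class = "ecdf_summary")
}

pool_errors <- function(errors) {
  if (is.numeric(errors)) return(as.numeric(errors))
  if (inherits(errors, "error_sequence")) return(errors$dd)
  if (is.list(errors))
    return(unlist(lapply(errors, pool_errors), use.names = FALSE))
  stop("unsupported error container")
}

#' @export
print.ecdf_summary <- function(x, ...) {
  cat(sprintf("Position-error indicators (n = %d)\n", x$n))
  cat(sprintf("  MEAE  %.4f m\n  MEDE  %.4f m\n  MAXE  %.4f m\n  STDE  %.4f m\n  AECDF %.4f\n",
              x$MEAE, x$MEDE, x$MAXE, x$STDE, x$AECDF))
  invisible(x)
}

#' Mean error and error dispersion of gait parameters across realisations
#'
#' For each gait parameter (number of turns, travelled distance, mean
#' walking speed), computes the mean of the estimate-minus-reference error
#' (ME) and the standard deviation of that error (SE) over paired walk
#' realisations.
#'
#' @param estimates,references equal-length lists of `gait_summary`
#'   objects.
#' @return data.frame with columns `parameter`, `ME`, `SE`, `n`.
#' @export
parameter_errors <- function(estimates, references) {
  if (length(estimates) != length(references))
    stop("estimate and reference lists must have equal length")
  params <- c("n_turns", "distance", "mean_speed")
  rows <- lapply(params, function(p) {
    e <- vapply(estimates, function(s) as.numeric(s[[p]]), numeric(1))
    r <- vapply(references, function(s) as.numeric(s[[p]]), numeric(1))
    err <- e - r
    data.frame(parameter = p, ME = mean(err),
               SE = if (length(err) > 1L) stats::sd(err) else 0,
               n = length(err))
  })
  do.call(rbind, rows)
}
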