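#' Write a sensor or fused track to CSV
#'
#' Format: UTF-8, comma separated, dot decimal, mandatory header
#' `t,x,y,sxx,sxy,syy` (sensor tracks) or `t,x,y,vx,vy` (fused tracks with
#' velocities) or `t,x,y`. Gaps are encoded by absent rows. Values are
#' written with enough digits for a lossless round trip.
#'
#' @param track a track data.frame.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_track <- function(track, path) {
  df <- as.data.frame(track)
  cols <- intersect(c("t", "x", "y", "vx", "vy", "sxx", "sxy", "syy"),
                    names(df))
  df <- df[, cols, drop = FALSE]
  body <- if (nrow(df) == 0L) character(0) else
    do.call(mapply, c(list(FUN = function(...)
      paste(vapply(list(...), format_num, character(1)), collapse = ",")),
      df, SIMPLIFY = TRUE, USE.NAMES = FALSE))
  lines <- c(paste(cols, collapse = ","), body)
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

format_num <- function(v) {
  s <- formatC(v, format = "g", digits = 17)
  gsub(" ", "", s)
}

#' Read a track CSV
#'
#' Accepts the formats written by [write_track()] (LF or CRLF line
#' endings). Missing covariance columns are filled with zeros; malformed
#' rows are reported with their line number.
#'
#' @param path CSV file path.
#' @param sensor_id sensor identifier attached to the result.
#' @return a `sensor_track` (or plain track data.frame when velocity
#'   columns are present).
#' @export
read_track <- function(path, sensor_id = "radar") {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\r$", "", lines)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("empty track file: ", path)
  header <- strsplit(lines[1], ",", fixed = TRUE)[[1]]
  if (!all(c("t", "x", "y") %in% header))
    stop("malformed header in ", path, ": need at least t,x,y")
  body <- lines[-1]
  vals <- lapply(seq_along(body), function(i) {
    f <- strsplit(body[i], ",", fixed = TRUE)[[1]]
    if (length(f) != length(header))
      stop("malformed row at line ", i + 1L, " in ", path)
    v <- suppressWarnings(as.numeric(f))
    if (any(is.na(v)))
      stop("non-numeric value at line ", i + 1L, " in ", path)
    v
  })
  M <- do.call(rbind, vals)
  colnames(M) <- header
  df <- as.data.frame(M)
  if (all(c("vx", "vy") %in% header)) {
    class(df) <- c("fused_track", "data.frame")
    return(df)
  }
  sensor_track(df$t, df$x, df$y,
               sxx = if ("sxx" %in% header) df$sxx else NULL,
               sxy = if ("sxy" %in% header) df$sxy else NULL,
               syy = if ("syy" %in% header) df$syy else NULL,
               sensor_id = sensor_id)
}

#' Write a reference trajectory to CSV (`t,x,y`)
#' @param traj a `trajectory`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_trajectory <- function(traj, path) write_track(traj, path)

#' Save a trained network as JSON
#'
#' The file contains the full specification, weights, channel scalings and
#' training seed, so a saved model reproduces its outputs exactly.
#'
#' @param net a `trained_network`.
#' @param path output JSON path.
#' @return the path, invisibly.
#' @export
write_network <- function(net, path) {
  obj <- list(
    spec = net$spec[c("kind", "n_inputs", "n_hidden", "n_outputs",
                      "feedback_delays", "hidden_activation")],
    weights = lapply(net$weights, function(w)
      if (is.matrix(w)) list(dim = dim(w), data = as.numeric(w))
      else list(dim = NULL, data = as.numeric(w))),
    input_scaling = net$input_scaling,
    output_scaling = net$output_scaling,
    training_seed = net$training_seed,
    training_loss = net$training_loss,
    validation_loss = net$validation_loss)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Load a trained network from JSON
#' @param path JSON path written by [write_network()].
#' @return a `trained_network`.
#' @export
read_network <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  spec <- network_spec(kind = obj$spec$kind,
                       n_hidden = obj$spec$n_hidden,
                       feedback_delays = if (obj$spec$kind == "narx")
                         as.integer(obj$spec$feedback_delays) else NULL,
                       hidden_activation = obj$spec$hidden_activation)
  weights <- lapply(obj$weights, function(w) {
    if (!is.null(w$dim) && length(w$dim)) matrix(w$data, w$dim[1], w$dim[2])
    else as.numeric(w$data)
  })
  fix_sc <- function(sc) list(min = as.numeric(sc$min),
                              span = as.numeric(sc$span))
  structure(list(spec = spec, weights = weights,
                 input_scaling = fix_sc(obj$input_scaling),
                 output_scaling = fix_sc(obj$output_scaling),
                 training_seed = obj$training_seed,
                 training_loss = obj$training_loss,
                 validation_loss = obj$validation_loss),
            class = "trained_network")
}

#' Read a scenario configuration from YAML
#'
#' Expected keys: `waypoints` (list of `[x, y]`), `walking_speed`,
#' `sensor_rates` (`radar`, `depth`), `n_realisations`, `obstacle_regions`
#' (list of `[xmin, xmax, ymin, ymax]`), `depth_sensor_position`, `seed`.
#'
#' @param path YAML file path.
#' @return a [scenario_config()].
#' @export
read_scenario <- function(path) {
  y <- yaml::read_yaml(path)
  scenario_config(
    waypoints = do.call(rbind, lapply(y$waypoints, as.numeric)),
    walking_speed = y$walking_speed,
    sensor_rates = unlist(y$sensor_rates),
    n_realisations = if (is.null(y$n_realisations)) 1L else y$n_realisations,
    obstacle_regions = lapply(y$obstacle_regions, as.numeric),
    depth_sensor_position = as.numeric(y$depth_sensor_position),
    seed = if (is.null(y$seed)) 1L else y$seed)
}

#' Write a scenario configuration to YAML
#' @param scenario a [scenario_config()].
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_scenario <- function(scenario, path) {
  obj <- list(
    waypoints = lapply(seq_len(nrow(scenario$waypoints)),
                       function(i) as.numeric(scenario$waypoints[i, ])),
    walking_speed = scenario$walking_speed,
    sensor_rates = as.list(scenario$sensor_rates),
    n_realisations = scenario$n_realisations,
    obstacle_regions = lapply(scenario$obstacle_regions, as.numeric),
    depth_sensor_position = scenario$depth_sensor_position,
    seed = scenario$seed)
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' Write a gait summary (or any list) as canonical JSON
#'
#' @param x a `gait_summary` or plain list.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_summary_json <- function(x, path) {
  jsonlite::write_json(unclass(x), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
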