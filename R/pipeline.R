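#' Pipeline configuration
#'
#' Bundles everything one evaluation run needs: the movement scenario, the
#' fusion methods to apply, trained models (or instructions to train them),
#' the gait-extraction settings, and the output directory.
#'
#' @param scenario a [scenario_config()] describing the evaluation walks.
#' @param methods subset of `c("kf", "mlp", "narx")`.
#' @param models named list; for `"mlp"`/`"narx"` either a
#'   `trained_network`, a path to a model JSON, or `NULL` (train on the
#'   fly using `train`).
#' @param train list of training options used when a model is missing:
#'   `scenarios`, `n_per_traj`, `fragment_fraction`, `epochs`, `lr`.
#' @param kf_params a [kf_model_params()].
#' @param radar_cfg,depth_cfg sensor simulation configurations.
#' @param motion_cfg,turn_cfg gait-extraction configurations.
#' @param smooth_window smoothing span in seconds applied before gait
#'   extraction.
#' @param occlude fragment the simulated depth tracks.
#' @param out_dir output directory.
#' @param seed master integer seed.
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(scenario,
                            methods = c("kf", "mlp", "narx"),
                            models = list(),
                            train = list(),
                            kf_params = kf_model_params(),
                            radar_cfg = radar_noise_config(),
                            depth_cfg = depth_model_config(),
                            motion_cfg = motion_config(),
                            turn_cfg = turn_config(),
                            smooth_window = 0.5,
                            occlude = TRUE,
                            out_dir = tempfile("gaitfuse_run_"),
                            seed = 1L) {
  methods <- match.arg(methods, c("kf", "mlp", "narx"), several.ok = TRUE)
  if (length(methods) == 0L) stop("select at least one fusion method")
  train_defaults <- list(scenarios = NULL, n_per_traj = 40L,
                         fragment_fraction = 0.5, epochs = 2000L, lr = 0.01)
  train <- utils::modifyList(train_defaults, train)
  structure(list(scenario = scenario, methods = methods, models = models,
                 train = train, kf_params = kf_params,
                 radar_cfg = radar_cfg, depth_cfg = depth_cfg,
                 motion_cfg = motion_cfg, turn_cfg = turn_cfg,
                 smooth_window = smooth_window, occlude = occlude,
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "pipeline_config")
}

resolve_model <- function(config, method, stage_seed) {
  m <- config$models[[method]]
  if (inherits(m, "trained_network")) return(m)
  if (is.character(m)) return(read_network(m))
  tr <- config$train
  scen <- tr$scenarios
  if (is.null(scen)) scen <- training_scenarios()
  ts <- generate_training_set(scen, n_per_traj = tr$n_per_traj,
                              fragment_fraction = tr$fragment_fraction,
                              seed = stage_seed,
                              radar_cfg = config$radar_cfg,
                              depth_cfg = config$depth_cfg)
  train_network(network_spec(method), ts, epochs = tr$epochs, lr = tr$lr,
                seed = stage_seed)
}

#' Run the full simulate-fuse-extract-evaluate pipeline
#'
#' For every walk realisation of the scenario: simulates the radar and
#' depth tracks, fuses them with each selected method, smooths the position
#' sequences, extracts the gait parameters, and finally pools the position
#' errors and parameter errors per data source. All artefacts (tracks,
#' summaries, indicator files, a run manifest) are written under the
#' configured output directory; the run is fully reproducible from the
#' master seed.
#'
#' @param config a [pipeline_config()].
#' @return a `run_manifest` list: `config_hash`, `seed`, `files`,
#'   `position_indicators` (per source `ecdf_summary`), `parameter_errors`
#'   (per source data.frame), `gait` (per source list of summaries),
#'   `reference_gait`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  sc <- config$scenario
  nreal <- sc$n_realisations
  seeds <- derive_seeds(config$seed, 2L * nreal + 2L)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  files <- character(0)
  put <- function(rel) {
    p <- file.path(config$out_dir, rel)
    files <<- c(files, rel)
    p
  }

  traj <- stage("simulate", build_reference_trajectory(
    sc, unname(sc$sensor_rates["radar"])))
  write_trajectory(traj, put("reference.csv"))

  nets <- list()
  for (m in setdiff(config$methods, "kf"))
    nets[[m]] <- stage(paste0("train:", m),
                       resolve_model(config, m, seeds[2L * nreal + 1L]))
  for (m in names(nets)) write_network(nets[[m]], put(paste0("model_", m, ".json")))

  sources <- c("radar", "depth", config$methods)
  errors <- stats::setNames(vector("list", length(sources)), sources)
  gait <- stats::setNames(vector("list", length(sources)), sources)
  ref_gait <- vector("list", nreal)
  ref_summary <- gait_summary(traj, config$motion_cfg, config$turn_cfg)

  for (r in seq_len(nreal)) {
    radar <- stage("simulate", simulate_radar_track(
      traj, config$radar_cfg, seed = seeds[2L * r - 1L]))
    depth <- stage("simulate", simulate_depth_track(
      traj, config$depth_cfg, sc, fragment = config$occlude,
      seed = seeds[2L * r]))
    write_track(radar, put(sprintf("walk%03d_radar.csv", r)))
    write_track(depth, put(sprintf("walk%03d_depth.csv", r)))
    est <- list(radar = radar, depth = depth)
    for (m in config$methods) {
      fused <- stage(paste0("fuse:", m), switch(
        m,
        kf = kf_fuse_tracks(radar, depth, config$kf_params),
        nn_fuse_tracks(nets[[m]], radar, depth)))
      write_track(fused, put(sprintf("walk%03d_%s.csv", r, m)))
      est[[m]] <- fused
    }
    for (src in sources) {
      tr <- est[[src]]
      if (nrow(tr) < 3L) next
      errors[[src]] <- c(errors[[src]],
                         list(stage("evaluate",
                                    position_errors(tr, traj, realisation = r))))
      sm <- stage("smooth", smooth_track(tr, config$smooth_window))
      gait[[src]] <- c(gait[[src]],
                       list(stage("extract", gait_summary(
                         sm, config$motion_cfg, config$turn_cfg))))
    }
    ref_gait[[r]] <- ref_summary
  }

  indicators <- lapply(errors, function(e)
    if (length(e)) ecdf_and_indicators(e) else NULL)
  par_err <- lapply(sources, function(src) {
    g <- gait[[src]]
    if (length(g)) parameter_errors(g, ref_gait[seq_along(g)]) else NULL
  })
  names(par_err) <- sources

  results <- list(
    position_indicators = lapply(indicators, function(s)
      if (is.null(s)) NULL else s[c("AECDF", "MEAE", "MEDE", "MAXE", "STDE", "n")]),
    parameter_errors = lapply(par_err, function(d)
      if (is.null(d)) NULL else as.list(d)),
    reference_gait = ref_summary[c("n_turns", "distance", "time_in_motion",
                                   "mean_speed")])
  write_summary_json(results, put("results.json"))

  cfg_path <- file.path(config$out_dir, "config.json")
  jsonlite::write_json(serialise_config(config), cfg_path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  files <- c(files, "config.json")
  hash <- unname(tools::md5sum(cfg_path))

  manifest <- list(config_hash = hash, seed = config$seed,
                   package_version = as.character(utils::packageVersion("gaitfuse")),
                   files = files)
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  structure(c(manifest,
              list(position_indicators = indicators,
                   parameter_errors = par_err,
                   gait = gait,
                   reference_gait = ref_summary,
                   out_dir = config$out_dir)),
            class = "run_manifest")
}

serialise_config <- function(config) {
  sc <- config$scenario
  list(scenario = list(
         waypoints = apply(sc$waypoints, 1, as.numeric, simplify = FALSE),
         walking_speed = sc$walking_speed,
         sensor_rates = as.list(sc$sensor_rates),
         n_realisations = sc$n_realisations,
         obstacle_regions = sc$obstacle_regions,
         depth_sensor_position = sc$depth_sensor_position),
       methods = config$methods,
       radar_cfg = unclass(config$radar_cfg),
       depth_cfg = unclass(config$depth_cfg),
       kf = list(sigma_alpha = config$kf_params$sigma_alpha),
       motion_cfg = unclass(config$motion_cfg),
       turn_cfg = unclass(config$turn_cfg),
       smooth_window = config$smooth_window,
       occlude = config$occlude,
       seed = config$seed)
}
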