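#' Read and write run configurations
#'
#' A run configuration is one declarative YAML document with a fixed
#' set of top-level sections: `seed`, `output_dir`, `log_level`, and
#' the per-stage parameter blocks `simulation`, `render`, `analysis`,
#' `fit`. Unknown top-level keys are rejected (they are almost always
#' typos). Every run should persist the configuration it actually used
#' beside its outputs with [write_run_config()]; units are seconds,
#' micrometres and MTs/s throughout.
#'
#' @param path YAML file path.
#' @return A named list of class `run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  allowed <- c("seed", "output_dir", "log_level",
               "simulation", "render", "analysis", "fit")
  unknown <- setdiff(names(cfg), allowed)
  if (length(unknown))
    stop(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  structure(cfg, class = "run_config")
}

#' @rdname read_run_config
#' @param config a `run_config` (or plain named list with the allowed
#'   keys).
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Simulate, render and save one synthetic assay
#'
#' Convenience driver tying the simulator modules together: builds the
#' tracks, renders the tubulin (and optionally plus-end) channel,
#' writes TIFF stacks, ground truth and the driving trajectory under
#' `output_dir`, and persists the resolved configuration.
#'
#' @param config a [simulation_config()].
#' @param render a [render_settings()].
#' @param output_dir output directory (created if needed).
#' @param stem file-name stem; default "sim".
#' @return Invisibly, a named vector of the paths written.
#' @export
run_simulation <- function(config, render = render_settings(),
                           output_dir, stem = "sim") {
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate_tracks(config)
  gt <- ground_truth(sim, config)
  movies <- render_movie(sim, config, render)
  if (!inherits(movies, "movie_stack")) {
    paths <- c(tubulin = file.path(output_dir, paste0(stem, "_tubulin.tif")),
               eb1 = file.path(output_dir, paste0(stem, "_eb1.tif")))
    write_movie(movies$tubulin, paths[["tubulin"]])
    write_movie(movies$eb1, paths[["eb1"]])
  } else {
    paths <- c(tubulin = file.path(output_dir, paste0(stem, "_tubulin.tif")))
    write_movie(movies, paths[["tubulin"]])
  }
  truth <- write_ground_truth(gt, file.path(output_dir, stem))
  traj_path <- file.path(output_dir, paste0(stem, "_trajectory.csv"))
  write_trajectory(sim$trajectory, traj_path)
  cfg_path <- file.path(output_dir, paste0(stem, "_config.yaml"))
  write_run_config(list(seed = config$seed, output_dir = output_dir,
                        simulation = c(
                          list(kinetics = if (inherits(config$kinetics, "nucleation_kinetics"))
                                 Filter(Negate(is.null), unclass(config$kinetics))
                               else "trajectory-driven"),
                          unclass(config)[setdiff(names(config), "kinetics")]),
                        render = unclass(render)),
                   cfg_path)
  .log_msg("run_simulation: %d tracks, %d frames -> %s",
           nrow(sim$tracks), length(gt$frame_times), output_dir)
  invisible(c(paths, truth, trajectory = traj_path, config = cfg_path))
}
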