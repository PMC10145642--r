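#' Load a run configuration
#'
#' Reads a YAML configuration (or returns the defaults when `path` is NULL)
#' and builds the component configurations for the full pipeline. The
#' defaults are the tuned parameter set: Npar = 150, Nite = 150, k = 2,
#' positions in \[0, 255\], velocities in \[-5, 5\], Amax = 30, Gsize = 7,
#' inertia 1.3, c1 = c2 = 0.5, mutation rate 0.1, nc = 1000 superpixels.
#' Unknown keys are rejected so typos cannot silently fall back to
#' defaults.
#'
#' @param path Path to a YAML file, or NULL for pure defaults.
#' @return Object of class `run_config`: a list with `swarm`
#'   ([swarm_config()]), `superpixel` ([superpixel_config()]), `postprocess`
#'   ([postprocess_config()]), `clahe` (list with `clip_limit`,
#'   `tile_grid`), and `seed`.
#' @export
load_config <- function(path = NULL) {
  vals <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) stop(sprintf("config file not found: '%s'", path))
    vals <- yaml::read_yaml(path)
    if (is.null(vals)) vals <- list()
  }
  known <- c("n_particles", "n_iterations", "n_thresholds", "inertia", "c1",
             "c2", "mutation_rate", "archive_max", "grid_size", "grid_x",
             "v_max", "alpha", "objectives", "n_superpixels", "compactness",
             "max_iter", "e_tol", "min_roi_area", "smooth_radius",
             "fill_holes", "clip_limit", "tile_grid", "seed")
  bad <- setdiff(names(vals), known)
  if (length(bad)) {
    stop(sprintf("unknown config key(s): %s", paste(bad, collapse = ", ")))
  }
  pick <- function(key, default) if (!is.null(vals[[key]])) vals[[key]] else default
  swarm <- swarm_config(
    n_particles = pick("n_particles", 150L),
    n_iterations = pick("n_iterations", 150L),
    n_thresholds = pick("n_thresholds", 2L),
    inertia = pick("inertia", 1.3),
    c1 = pick("c1", 0.5), c2 = pick("c2", 0.5),
    mutation_rate = pick("mutation_rate", 0.1),
    archive_max = pick("archive_max", 30L),
    grid_size = pick("grid_size", 7L),
    grid_x = pick("grid_x", 10),
    v_max = pick("v_max", 5),
    alpha = pick("alpha", 2),
    objectives = pick("objectives", c("otsu", "kapur", "renyi"))
  )
  structure(
    list(
      swarm = swarm,
      superpixel = superpixel_config(
        n_superpixels = pick("n_superpixels", 1000L),
        compactness = pick("compactness", 10),
        max_iter = pick("max_iter", 10L),
        e_tol = pick("e_tol", 1)
      ),
      postprocess = postprocess_config(
        min_roi_area = pick("min_roi_area", 30L),
        smooth_radius = pick("smooth_radius", 2L),
        fill_holes = pick("fill_holes", TRUE)
      ),
      clahe = list(clip_limit = pick("clip_limit", 0.01),
                   tile_grid = pick("tile_grid", c(8L, 8L))),
      seed = pick("seed", 0L)
    ),
    class = "run_config"
  )
}

#' Write a run configuration to YAML
#'
#' Inverse of [load_config()]: `load_config(save_config(cfg, f))` restores
#' an identical configuration.
#'
#' @param cfg A `run_config`.
#' @param path Output YAML path.
#' @return Invisibly, `path`.
#' @export
save_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "run_config"))
  flat <- c(
    cfg$swarm[c("n_particles", "n_iterations", "n_thresholds", "inertia",
                "c1", "c2", "mutation_rate", "archive_max", "grid_size",
                "grid_x", "v_max", "alpha", "objectives")],
    cfg$superpixel[c("n_superpixels", "compactness", "max_iter", "e_tol")],
    cfg$postprocess[c("min_roi_area", "smooth_radius", "fill_holes")],
    cfg$clahe, list(seed = cfg$seed)
  )
  yaml::write_yaml(flat, path)
  invisible(path)
}
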