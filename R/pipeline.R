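# End-to-end scenario driver: config -> mesh -> resection -> coupled
# healing -> outputs. This is the programmatic core behind the command-line
# interface and the reproduction scripts.

#' Build the mesh described by a configuration
#'
#' Either generates the synthetic phantom of the config's `phantom` section
#' or reads the MSH file of its `mesh` section.
#'
#' @param config list from [load_config()].
#' @param seed optional override of the phantom seed.
#' @return a [labeled_mesh()].
#' @export
config_mesh <- function(config, seed = NULL) {
  if (!is.null(config$mesh)) {
    mi <- config$mesh
    return(read_mesh(mi$path, mi$region_map, mi$patch_map, scale = mi$scale))
  }
  if (is.null(config$phantom))
    stop("config has neither a phantom nor a mesh section", call. = FALSE)
  ph <- config$phantom
  generate_phantom(
    breast_radius = ph$breast_radius,
    slab_depth = ph$slab_depth,
    target_edge_length = ph$target_edge_length,
    fibro_fraction = ph$fibro_fraction %||% 0.25,
    seed = seed %||% ph$seed %||% 1L,
    slab_half_width = ph$slab_half_width %||% (1.6 * ph$breast_radius),
    jitter = ph$jitter %||% 0.15)
}

#' Run a full healing scenario from a configuration file
#'
#' The `demo` pipeline: build the mesh, apply the resection plan, run the
#' coupled healing-and-contraction simulation, and (optionally) write the
#' trajectory CSV and VTU snapshots.
#'
#' @param config a path to a YAML config or a list from [load_config()].
#' @param out_dir optional output directory for `trajectory.csv` and VTU
#'   snapshots.
#' @param seed optional phantom-seed override.
#' @param snapshots write per-cycle VTU snapshots (default `FALSE`).
#' @param quiet suppress progress output.
#' @return list with `mesh`, `result` (from [run_coupled()]) and `metrics`
#'   (from [contraction_metrics()]).
#' @export
run_scenario <- function(config, out_dir = NULL, seed = NULL,
                         snapshots = FALSE, quiet = TRUE) {
  if (is.character(config)) config <- load_config(config, quiet = quiet)
  mesh <- config_mesh(config, seed = seed)
  if (is.null(config$resection))
    stop("config has no resection section", call. = FALSE)
  mesh <- mark_resection(mesh, config$resection)
  g <- gravity_vector(config$gravity$pose, config$gravity$magnitude)
  snap_dir <- if (snapshots && !is.null(out_dir))
    file.path(out_dir, "snapshots") else NULL
  res <- run_coupled(mesh, config$bio, config$materials, config$schedule,
                     gravity = g, snapshot_dir = snap_dir, quiet = quiet)
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    write_trajectory_csv(res$trajectory, file.path(out_dir, "trajectory.csv"))
  }
  list(mesh = mesh, result = res, metrics = contraction_metrics(res$trajectory))
}
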