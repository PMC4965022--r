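# Gravity poses and the unloaded-configuration inverse problem. Imaging is
# performed under gravity (prone), so the mesh extracted from images is a
# loaded equilibrium; the reference (stress-free) configuration is
# recovered by a fixed-point inverse analysis, after which any pose follows
# from a forward gravity solve.

#' Forward gravity solve for a named pose
#'
#' @param mesh the unloaded (reference) [labeled_mesh()].
#' @param materials a [material_set()].
#' @param pose `"prone"`, `"supine"`, `"upright"` or `"none"`.
#' @param magnitude gravitational acceleration (m/s^2).
#' @param bcs optional boundary conditions (default [mech_bcs()]).
#' @param ... forwarded to [solve_static()].
#' @return a [mech_state()].
#' @export
forward_pose <- function(mesh, materials, pose, magnitude = 9.81,
                         bcs = NULL, ...) {
  g <- gravity_vector(pose, magnitude)
  solve_static(mesh, materials, bcs = bcs, gravity = g, ...)
}

#' Estimate the unloaded configuration from a loaded one
#'
#' Fixed-point (Sellier-type) iteration: starting from the acquired loaded
#' geometry as the reference guess, each iteration forward-solves gravity
#' and moves the reference nodes by the mismatch between the predicted
#' deformed shape and the acquired shape. Converges when the maximum nodal
#' mismatch drops below `tol`.
#'
#' @param loaded_mesh the acquired (gravity-loaded) [labeled_mesh()].
#' @param materials a [material_set()].
#' @param gravity gravity vector of the acquisition pose (m/s^2).
#' @param tol maximum nodal mismatch (m, default 1e-4).
#' @param max_iter iteration cap (default 20).
#' @param bcs optional boundary conditions.
#' @param relax update relaxation factor in (0, 1].
#' @param quiet suppress per-iteration output.
#' @return list with `mesh` (unloaded [labeled_mesh()]), `residuals`
#'   (per-iteration max mismatch, m) and `state` (last forward
#'   [mech_state()]).
#' @export
inverse_unloaded <- function(loaded_mesh, materials, gravity,
                             tol = 1e-4, max_iter = 20L, bcs = NULL,
                             relax = 1, quiet = TRUE) {
  x_target <- loaded_mesh$nodes
  ref <- loaded_mesh
  residuals <- numeric(0)
  init <- NULL
  for (it in seq_len(max_iter)) {
    st <- solve_static(ref, materials, bcs = bcs, gravity = gravity,
                       init = init,
                       n_increments = if (is.null(init)) 5L else 1L)
    mismatch <- ref$nodes + st$u - x_target
    r <- max(abs(mismatch))
    residuals <- c(residuals, r)
    if (!quiet)
      message(sprintf("  unload iteration %d: max mismatch %.3g m", it, r))
    if (r < tol)
      return(list(mesh = ref, residuals = residuals, state = st))
    ref$nodes <- ref$nodes - relax * mismatch
    v <- tet_volumes_signed(ref$nodes, ref$tets)
    if (any(v <= 0))
      stop("inverse error: reference update inverted ", sum(v <= 0),
           " element(s); reduce relax", call. = FALSE)
    init <- st$u
  }
  stop("inverse error: unloaded-state iteration did not reach tol = ",
       tol, " in ", max_iter, " iterations (residuals: ",
       paste(signif(residuals, 3), collapse = ", "), ")", call. = FALSE)
}
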