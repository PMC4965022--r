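# Partitioned two-timescale coupling: the biochemical solver advances with
# seconds-scale explicit steps on the fixed Lagrangian mesh; every
# mechanics interval (days-scale) the cell density eta is mapped to element
# damage and active stress and the quasi-static equilibrium is re-solved
# from the reference configuration. Coupling is one-directional (biology ->
# mechanics): the model is non-mechano-sensing, so no strain feeds back
# into the transport equations and the biology trajectory is independent of
# the mechanics.

#' Element damage from cell density
#'
#' `zeta = clamp(1 - mean(eta)/eta0, 0, 1 - zeta_eps)` with the element
#' value taken as the mean of its four nodal cell densities. Healthy
#' (non-wound) elements are forced to zero damage throughout.
#'
#' @param eta nodal cell density.
#' @param mesh a [labeled_mesh()].
#' @param eta0 reference cell density.
#' @param zeta_eps integrity floor (default 1e-3).
#' @return per-element damage vector.
#' @export
damage_from_density <- function(eta, mesh, eta0, zeta_eps = 1e-3) {
  eta_e <- (eta[mesh$tets[, 1L]] + eta[mesh$tets[, 2L]] +
            eta[mesh$tets[, 3L]] + eta[mesh$tets[, 4L]]) / 4
  z <- pmin(pmax(1 - eta_e / eta0, 0), 1 - zeta_eps)
  z[mesh$tet_region != "wound"] <- 0
  z
}

# element-mean normalised cell density (drives the active stress)
eta_norm_elements <- function(eta, mesh, eta0) {
  (eta[mesh$tets[, 1L]] + eta[mesh$tets[, 2L]] +
   eta[mesh$tets[, 3L]] + eta[mesh$tets[, 4L]]) / (4 * eta0)
}

#' Run the coupled healing-and-contraction simulation
#'
#' Alternates the two solvers to the healing horizon: biology advances by
#' `dt_mech` using explicit steps, then damage and active stress are
#' updated from the current cell density and the mechanics is re-solved
#' (warm-started from the previous cycle). The deformed wound volume is
#' recorded at every mechanics step.
#'
#' `dt_bio` is reduced if necessary so that it divides `dt_mech` exactly
#' and respects the stability bound of the explicit scheme on this mesh.
#'
#' @param mesh a [labeled_mesh()] with wound labels (see
#'   [mark_resection()]).
#' @param bio a [bio_params()].
#' @param materials a [material_set()].
#' @param sched a [schedule()].
#' @param gravity gravity vector (default none: the contraction metric is
#'   normalised and healing is simulated in the fixed supine frame).
#' @param snapshot_dir optional directory for per-cycle VTU snapshots.
#' @param quiet suppress progress messages.
#' @return list with `trajectory` (data.frame: day, wound_volume_m3,
#'   volume_fraction, mean_eta, mean_upsilon, mean_xi), `state` (final
#'   [species_state()]), `mech` (final [mech_state()]), `dt_bio_used`.
#' @export
run_coupled <- function(mesh, bio, materials, sched, gravity = c(0, 0, 0),
                        snapshot_dir = NULL, quiet = TRUE) {
  stopifnot(inherits(sched, "schedule"))
  if (!any(mesh$tet_region == "wound"))
    stop("mesh has no wound region; apply mark_resection() first",
         call. = FALSE)
  ops <- assemble_operators(mesh)
  # admissible biology step: requested, CFL, spectral bound, reaction rates
  dt_bio <- min(sched$dt_bio,
                cfl_max_dt(mesh, bio, sched$cfl_safety),
                stable_dt_operator(ops, bio, sched$cfl_safety),
                0.25 / max(bio$k, bio$ell, bio$lambda, bio$phi))
  nsub <- ceiling(sched$dt_mech / dt_bio)
  dt_bio <- sched$dt_mech / nsub
  ncycle <- round(sched$t_end / sched$dt_mech)
  if (!quiet)
    message(sprintf("coupled run: %d cycles of %g days, dt_bio = %.3g s (%d substeps)",
                    ncycle, sched$dt_mech / 86400, dt_bio, nsub))

  state <- initialize_state(mesh, bio)
  wflag <- wound_touching_nodes(mesh)
  welt <- mesh$tet_region == "wound"
  wvol0 <- sum(ops$vol[welt])

  wound_stats <- function(s, u) {
    vdef <- tet_volumes(mesh, u)[welt]
    em <- function(f) {
      fe <- (f[mesh$tets[welt, 1L]] + f[mesh$tets[welt, 2L]] +
             f[mesh$tets[welt, 3L]] + f[mesh$tets[welt, 4L]]) / 4
      sum(fe * ops$vol[welt]) / wvol0
    }
    c(wound_volume_m3 = sum(vdef),
      volume_fraction = sum(vdef) / wvol0,
      mean_eta = em(s$eta) / bio$eta0,
      mean_upsilon = em(s$upsilon) / bio$upsilon0,
      mean_xi = em(s$xi))
  }

  solve_cycle <- function(s, init) {
    zeta <- damage_from_density(s$eta, mesh, bio$eta0, materials$zeta_eps)
    etn <- eta_norm_elements(s$eta, mesh, bio$eta0)
    solve_static(mesh, materials, gravity = gravity, zeta = zeta,
                 eta_norm = etn, init = init,
                 n_increments = if (is.null(init)) 4L else 1L)
  }

  mech <- solve_cycle(state, NULL)
  rows <- list(c(day = 0, wound_stats(state, mech$u)))
  maybe_snapshot <- function(cyc, s, mech) {
    if (is.null(snapshot_dir)) return(invisible())
    if (!dir.exists(snapshot_dir))
      dir.create(snapshot_dir, recursive = TRUE)
    write_vtu(mesh, file.path(snapshot_dir, sprintf("heal_%03d.vtu", cyc)),
              point_data = list(eta = s$eta / bio$eta0,
                                sigma_c = s$sigma_c,
                                upsilon = s$upsilon / bio$upsilon0,
                                xi = s$xi, mu = s$mu,
                                displacement = mech$u),
              cell_data = list(zeta = mech$zeta, J = mech$J,
                               pressure = mech$pressure))
  }
  maybe_snapshot(0L, state, mech)

  for (cyc in seq_len(ncycle)) {
    for (s_ in seq_len(nsub))
      state <- explicit_step(state, dt_bio, ops, mesh, bio, wflag)
    mech <- solve_cycle(state, mech$u)
    day <- cyc * sched$dt_mech / 86400
    rows[[length(rows) + 1L]] <- c(day = day, wound_stats(state, mech$u))
    maybe_snapshot(cyc, state, mech)
    if (!quiet) {
      last <- rows[[length(rows)]]
      message(sprintf("  day %5.1f: V/V0 = %.4f, eta = %.3f, xi = %.3f",
                      day, last[["volume_fraction"]], last[["mean_eta"]],
                      last[["mean_xi"]]))
    }
  }
  trajectory <- as.data.frame(do.call(rbind, rows))
  list(trajectory = trajectory, state = state, mech = mech,
       dt_bio_used = dt_bio)
}

#' Contraction metrics of a wound-volume trajectory
#'
#' @param trajectory data.frame with columns `day` and `volume_fraction`
#'   (or `wound_volume_m3`), as produced by [run_coupled()].
#' @return list with `final_fraction` (percent of the initial wound volume
#'   remaining at the end), `day_max_rate` (day of the largest
#'   centred-difference contraction rate) and `plateau_day` (first day
#'   within 1% of the final volume).
#' @export
contraction_metrics <- function(trajectory) {
  if (nrow(trajectory) < 3L)
    stop("trajectory too short for contraction metrics", call. = FALSE)
  day <- trajectory$day
  v <- if ("volume_fraction" %in% names(trajectory))
    trajectory$volume_fraction else
      trajectory$wound_volume_m3 / trajectory$wound_volume_m3[1L]
  n <- length(v)
  vf <- v[n]
  # centred differences on the interior samples
  rate <- abs((v[3:n] - v[1:(n - 2L)]) / (day[3:n] - day[1:(n - 2L)]))
  day_max <- day[2:(n - 1L)][which.max(rate)]
  within <- abs(v - vf) <= 0.01 * vf
  # first day from which the series stays within the band
  stays <- rev(cumprod(rev(within))) > 0
  plateau_day <- day[which(stays)[1L]]
  list(final_fraction = 100 * vf, day_max_rate = day_max,
       plateau_day = plateau_day)
}

#' Write a healing trajectory as CSV
#'
#' @param trajectory data.frame from [run_coupled()].
#' @param path output CSV path.
#' @return invisibly `path`.
#' @export
write_trajectory_csv <- function(trajectory, path) {
  utils::write.csv(trajectory, path, row.names = FALSE)
  invisible(path)
}
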