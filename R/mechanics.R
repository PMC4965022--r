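# Quasi-static Total-Lagrangian finite-element solver. Displacements are
# linear on tetrahedra; the incompressibility constraint is treated with the
# mixed u/p formulation with element-wise constant pressure, statically
# condensed: for constant-gradient tetrahedra the condensation
# p_e = kappa (J_e - 1) is exact, so the assembled system involves only
# displacements and the pressure field is recovered after the solve.
# Boundary conditions follow the clinical model: traction-free skin (plus
# the membrane stiffness), fully fixed chest wall, zero axial (Z)
# displacement on the superior/inferior clip planes, traction-free lateral
# boundary.

#' Mechanical state
#'
#' @param u nodal displacement matrix (m).
#' @param pressure element pressure of the mixed formulation,
#'   `kappa (J - 1)` (Pa).
#' @param zeta per-element damage.
#' @param J per-element volume ratio.
#' @param converged logical.
#' @param log data.frame of Newton iterations.
#' @return object of class `mech_state`.
#' @export
mech_state <- function(u, pressure = NULL, zeta = NULL, J = NULL,
                       converged = NA, log = NULL) {
  structure(list(u = u, pressure = pressure, zeta = zeta, J = J,
                 converged = converged, log = log), class = "mech_state")
}

#' @export
print.mech_state <- function(x, ...) {
  cat("<mech_state> max |u| = ", format(max(abs(x$u)), digits = 4),
      " m; converged: ", x$converged, "\n", sep = "")
  invisible(x)
}

#' Standard boundary conditions of the breast model
#'
#' Chest patch: all displacement components fixed to zero. Clip planes
#' (superior/inferior): Z-component fixed to zero. Skin and lateral
#' boundary: traction-free (no constraint).
#'
#' @param mesh a [labeled_mesh()].
#' @param extra optional data.frame with columns `node`, `dof` (1-3),
#'   `value` appended to the standard set (later entries win).
#' @return data.frame with columns `node`, `dof`, `value`.
#' @export
mech_bcs <- function(mesh, extra = NULL) {
  chest <- unique(as.vector(
    mesh$boundary_tris[mesh$tri_patch == "chest", , drop = FALSE]))
  clips <- unique(as.vector(
    mesh$boundary_tris[mesh$tri_patch %in% c("clip_inferior",
                                             "clip_superior"), ,
                       drop = FALSE]))
  clips <- setdiff(clips, chest)
  bc <- rbind(
    if (length(chest))
      data.frame(node = rep(chest, each = 3L),
                 dof = rep(1:3, length(chest)), value = 0),
    if (length(clips))
      data.frame(node = clips, dof = 3L, value = 0))
  if (is.null(bc) && is.null(extra))
    stop("mesh has no constrained patches and no extra constraints",
         call. = FALSE)
  if (!is.null(extra)) bc <- rbind(bc, extra)
  bc[!duplicated(bc[, c("node", "dof")], fromLast = TRUE), , drop = FALSE]
}

# precompute everything constant during a Newton solve
mech_model <- function(mesh, materials, bcs = NULL, gravity = c(0, 0, 0),
                       zeta = NULL, eta_norm = NULL) {
  stopifnot(inherits(materials, "material_set"))
  geo <- element_gradients(mesh$nodes, mesh$tets)
  ne <- nrow(mesh$tets)
  nn <- nrow(mesh$nodes)
  reg <- mesh$tet_region
  pick <- function(field) {
    v <- numeric(ne)
    for (rn in c("adipose", "fibroglandular", "wound"))
      v[reg == rn] <- materials[[rn]][[field]]
    v
  }
  c1 <- pick("c1"); c2 <- pick("c2"); kappa <- pick("kappa")
  rho0 <- pick("rho0")

  wound <- reg == "wound"
  if (is.null(zeta)) zeta <- rep(0, ne)
  zeta <- pmin(pmax(zeta, 0), 1 - materials$zeta_eps)
  zeta[!wound] <- 0
  if (is.null(eta_norm)) eta_norm <- ifelse(wound, 0, 1)
  s_act_full <- materials$active$tau_f * materials$active$alpha_f *
    materials$active$eta0_f * eta_norm
  if (!materials$active_global) s_act_full[!wound] <- 0

  dmg <- 1 - zeta
  dmg_vol <- if (materials$damage_volumetric) dmg else rep(1, ne)

  # gravity consistent nodal load (reference volumes; dead load)
  f_grav <- matrix(0, nn, 3L)
  for (a in 1:4) {
    w <- rho0 * geo$vol / 4
    for (i in 1:3)
      f_grav[, i] <- f_grav[, i] +
        unname(rowsum_vec(w * gravity[i], mesh$tets[, a], nn))
  }
  # skin membrane: reference, thickness, mass
  skin_tris <- mesh$boundary_tris[mesh$tri_patch == "skin", , drop = FALSE]
  skin_pre <- NULL
  if (nrow(skin_tris)) {
    skin_pre <- membrane_reference(mesh$nodes, skin_tris)
    areas <- vapply(skin_pre, function(p) p$area, 0)
    wsk <- materials$skin$rho0 * mesh$skin_thickness * areas / 3
    for (a in 1:3) for (i in 1:3)
      f_grav[, i] <- f_grav[, i] +
        unname(rowsum_vec(wsk * gravity[i], skin_tris[, a], nn))
  }

  if (is.null(bcs)) bcs <- mech_bcs(mesh)
  fixed_dof <- 3L * (bcs$node - 1L) + bcs$dof
  free_dof <- setdiff(seq_len(3L * nn), fixed_dof)

  # global dof index pattern of the element stiffness triplets
  gdof <- matrix(0L, ne, 12L)
  for (a in 1:4) for (i in 1:3)
    gdof[, 3L * (a - 1L) + i] <- 3L * (mesh$tets[, a] - 1L) + i
  kI <- matrix(0L, ne, 144L)
  kJ <- matrix(0L, ne, 144L)
  for (r in 1:12) for (c_ in 1:12) {
    kI[, 12L * (r - 1L) + c_] <- gdof[, r]
    kJ[, 12L * (r - 1L) + c_] <- gdof[, c_]
  }

  # characteristic load magnitude for the absolute convergence floor
  force_scale <- sqrt(sum(f_grav^2)) +
    sum(abs(s_act_full) * geo$vol^(2 / 3))

  list(force_scale = force_scale,
       mesh = mesh, geo = geo, c1 = c1, c2 = c2, kappa = kappa,
       dmg = dmg, dmg_vol = dmg_vol, s_act = s_act_full, zeta = zeta,
       f_grav = f_grav, skin_tris = skin_tris, skin_pre = skin_pre,
       skin = materials$skin, thickness = mesh$skin_thickness,
       bcs = bcs, fixed_dof = fixed_dof, free_dof = free_dof,
       kI = as.vector(kI), kJ = as.vector(kJ), gdof = gdof, nn = nn)
}

rowsum_vec <- function(x, group, n) {
  out <- numeric(n)
  s <- rowsum(x, group)
  out[as.integer(rownames(s))] <- s
  out
}

# residual and tangent at displacement u with load factor gamma.
# R = f_int(u) - gamma * f_ext  (active stress also scaled by gamma)
assemble <- function(model, u, gamma = 1, want_tangent = TRUE) {
  mesh <- model$mesh
  tets <- mesh$tets
  g <- model$geo$grads
  vol <- model$geo$vol
  ne <- nrow(tets)
  F_ <- def_gradients(u, tets, g)
  kin <- kinematics(F_)
  ts <- tissue_stress(kin, model$c1, model$c2, model$kappa, model$dmg,
                      model$dmg_vol, gamma * model$s_act, want_tangent)
  S <- ts$S
  # P = F S (ne x 3 x 3)
  Sf <- array(0, c(ne, 3L, 3L))
  for (p in 1:6) {
    Sf[, VGT_I[p], VGT_J[p]] <- S[, p]
    Sf[, VGT_J[p], VGT_I[p]] <- S[, p]
  }
  P <- array(0, c(ne, 3L, 3L))
  for (i in 1:3) for (jx in 1:3)
    P[, i, jx] <- F_[, i, 1L] * Sf[, 1L, jx] + F_[, i, 2L] * Sf[, 2L, jx] +
      F_[, i, 3L] * Sf[, 3L, jx]
  f_int <- matrix(0, model$nn, 3L)
  for (a in 1:4) for (i in 1:3) {
    contrib <- vol * (P[, i, 1L] * g[, a, 1L] + P[, i, 2L] * g[, a, 2L] +
                      P[, i, 3L] * g[, a, 3L])
    f_int[, i] <- f_int[, i] + rowsum_vec(contrib, tets[, a], model$nn)
  }
  # skin membrane
  memb <- NULL
  if (!is.null(model$skin_pre)) {
    memb <- membrane_assemble(mesh$nodes, u, model$skin_tris, model$skin_pre,
                              model$skin, model$thickness, want_tangent)
    f_int <- f_int + memb$f
  }
  Rvec <- as.vector(t(f_int)) - gamma * as.vector(t(model$f_grav))

  out <- list(R = Rvec, J = ts$J, W = sum(vol * ts$W))
  if (!want_tangent) return(out)

  # element stiffness: material part B' D B + geometric part
  D <- ts$D
  B <- array(0, c(ne, 6L, 12L))
  for (a in 1:4) for (i in 1:3) {
    col <- 3L * (a - 1L) + i
    B[, 1L, col] <- F_[, i, 1L] * g[, a, 1L]
    B[, 2L, col] <- F_[, i, 2L] * g[, a, 2L]
    B[, 3L, col] <- F_[, i, 3L] * g[, a, 3L]
    B[, 4L, col] <- F_[, i, 1L] * g[, a, 2L] + F_[, i, 2L] * g[, a, 1L]
    B[, 5L, col] <- F_[, i, 1L] * g[, a, 3L] + F_[, i, 3L] * g[, a, 1L]
    B[, 6L, col] <- F_[, i, 2L] * g[, a, 3L] + F_[, i, 3L] * g[, a, 2L]
  }
  DB <- array(0, c(ne, 6L, 12L))
  for (p in 1:6) for (col in 1:12) {
    acc <- 0
    for (q in 1:6) acc <- acc + D[, p, q] * B[, q, col]
    DB[, p, col] <- acc
  }
  Ke <- array(0, c(ne, 12L, 12L))
  for (r in 1:12) for (col in r:12) {
    acc <- 0
    for (p in 1:6) acc <- acc + B[, p, r] * DB[, p, col]
    Ke[, r, col] <- acc
    if (col > r) Ke[, col, r] <- acc
  }
  # geometric stiffness: (G_a . S G_b) on the diagonal blocks
  for (a in 1:4) for (b in 1:4) {
    sg <- 0
    for (Jx in 1:3) for (Lx in 1:3)
      sg <- sg + g[, a, Jx] * Sf[, Jx, Lx] * g[, b, Lx]
    for (i in 1:3)
      Ke[, 3L * (a - 1L) + i, 3L * (b - 1L) + i] <-
        Ke[, 3L * (a - 1L) + i, 3L * (b - 1L) + i] + sg
  }
  xx <- as.vector(Ke * vol)   # recycles vol over the 144 slices
  K <- Matrix::sparseMatrix(i = model$kI, j = model$kJ, x = xx,
                            dims = c(3L * model$nn, 3L * model$nn))
  if (!is.null(memb))
    K <- K + Matrix::sparseMatrix(i = memb$ii, j = memb$jj, x = memb$xx,
                                  dims = c(3L * model$nn, 3L * model$nn))
  out$K <- K
  out
}

#' Solve the quasi-static equilibrium problem
#'
#' Newton iteration with incremental loading (gravity and active stress are
#' ramped together), automatic increment halving on divergence and a
#' backtracking line search. The converged state satisfies `det F > 0` in
#' every element.
#'
#' @param mesh a [labeled_mesh()].
#' @param materials a [material_set()].
#' @param bcs boundary conditions from [mech_bcs()] (default: standard
#'   chest/clip constraints).
#' @param gravity gravity vector (m/s^2), see [gravity_vector()].
#' @param zeta per-element damage (default zero).
#' @param eta_norm per-element normalised cell density for the active
#'   stress (default 0 in wound, 1 elsewhere).
#' @param init optional initial displacement (warm start).
#' @param n_increments initial number of load increments (warm starts use 1).
#' @param tol relative residual tolerance.
#' @param max_iter Newton iterations per increment.
#' @param max_cutbacks increment halvings before giving up.
#' @param quiet suppress progress output.
#' @return a [mech_state()].
#' @export
solve_static <- function(mesh, materials, bcs = NULL, gravity = c(0, 0, 0),
                         zeta = NULL, eta_norm = NULL, init = NULL,
                         n_increments = 5L, tol = 1e-8, max_iter = 25L,
                         max_cutbacks = 6L, quiet = TRUE) {
  model <- mech_model(mesh, materials, bcs, gravity, zeta, eta_norm)
  solve_static_model(model, init, n_increments, tol, max_iter, max_cutbacks,
                     quiet)
}

solve_static_model <- function(model, init = NULL, n_increments = 5L,
                               tol = 1e-8, max_iter = 25L, max_cutbacks = 6L,
                               quiet = TRUE) {
  nn <- model$nn
  u <- if (is.null(init)) matrix(0, nn, 3L) else as.matrix(init)
  uv <- as.vector(t(u))
  uv[model$fixed_dof] <- model$bcs$value
  free <- model$free_dof
  log_rows <- list()

  gamma_done <- 0
  dgamma <- 1 / n_increments
  cutbacks <- 0L
  while (gamma_done < 1 - 1e-12) {
    gamma <- min(1, gamma_done + dgamma)
    u <- matrix(uv, nn, 3L, byrow = TRUE)
    ok <- TRUE
    res0 <- NA
    rn_prev <- Inf
    uv_save <- uv
    for (it in seq_len(max_iter)) {
      asm <- tryCatch(assemble(model, u, gamma, want_tangent = TRUE),
                      error = function(e) e)
      if (inherits(asm, "error")) { ok <- FALSE; break }
      r <- asm$R[free]
      rn <- sqrt(sum(r^2))
      if (it == 1L) res0 <- max(rn, 1e-300)
      log_rows[[length(log_rows) + 1L]] <-
        c(gamma = gamma, iter = it, residual = rn)
      if (rn <= tol * res0 || rn <= 1e-10 * model$force_scale ||
          rn < 1e-13) break
      # accept a stagnating residual once the load is equilibrated to many
      # digits: very stiff systems floor out at solver rounding before the
      # nominal relative tolerance is reachable
      if (rn <= 1e-5 * res0 && rn > 0.9 * rn_prev) break
      rn_prev <- rn
      if (it == max_iter) { ok <- FALSE; break }
      du <- tryCatch(
        as.vector(Matrix::solve(asm$K[free, free, drop = FALSE], -r)),
        error = function(e) NULL)
      if (is.null(du) || any(!is.finite(du))) { ok <- FALSE; break }
      # backtracking on the residual norm
      step <- 1
      for (ls in 1:5) {
        uv_try <- uv
        uv_try[free] <- uv[free] + step * du
        u_try <- matrix(uv_try, nn, 3L, byrow = TRUE)
        a2 <- tryCatch(assemble(model, u_try, gamma, want_tangent = FALSE),
                       error = function(e) e)
        if (!inherits(a2, "error") &&
            sqrt(sum(a2$R[free]^2)) < rn * (1 - 1e-4 * step) || ls == 5L) {
          if (inherits(a2, "error")) { ok <- FALSE }
          break
        }
        step <- step / 2
      }
      if (!ok) break
      uv <- uv_try
      u <- matrix(uv, nn, 3L, byrow = TRUE)
    }
    if (ok) {
      gamma_done <- gamma
    } else {
      uv <- uv_save
      dgamma <- dgamma / 2
      cutbacks <- cutbacks + 1L
      if (cutbacks > max_cutbacks)
        stop("solver error: Newton failed to converge after ", cutbacks,
             " increment cutbacks (last load factor ", round(gamma, 4),
             ")", call. = FALSE)
    }
  }
  u <- matrix(uv, nn, 3L, byrow = TRUE)
  fin <- assemble(model, u, 1, want_tangent = FALSE)
  lg <- as.data.frame(do.call(rbind, log_rows))
  mech_state(u = u,
             pressure = model$kappa * model$dmg_vol * (fin$J - 1),
             zeta = model$zeta, J = fin$J, converged = TRUE, log = lg)
}

#' Reaction forces at constrained degrees of freedom
#'
#' Assembles the residual at a converged state; its value on the fixed dofs
#' equals the constraint reactions (global equilibrium: their sum balances
#' the applied loads).
#'
#' @param mesh,materials,bcs,gravity,zeta,eta_norm as in [solve_static()].
#' @param state a converged [mech_state()].
#' @return nodes x 3 matrix of reaction forces (zero at free dofs).
#' @export
reaction_forces <- function(mesh, materials, state, bcs = NULL,
                            gravity = c(0, 0, 0), zeta = NULL,
                            eta_norm = NULL) {
  model <- mech_model(mesh, materials, bcs, gravity, zeta, eta_norm)
  asm <- assemble(model, state$u, 1, want_tangent = FALSE)
  out <- matrix(0, model$nn, 3L)
  rv <- as.vector(t(out))
  rv[model$fixed_dof] <- asm$R[model$fixed_dof]
  matrix(rv, model$nn, 3L, byrow = TRUE)
}
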