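# Damage-scaled Mooney-Rivlin constitutive model with isotropic fibroblast
# active stress, evaluated in vectorised form over all elements at once.
#
#   W = (1 - zeta) [c1 (I1bar - 3) + c2 (I2bar - 3)] + kappa/2 (J - 1)^2
#
# The integrity factor (1 - zeta) scales the isochoric part only; the
# volumetric penalty stays intact so the fluid-filled wound remains
# quasi-incompressible (a `damage_volumetric` switch scales it too, for
# sensitivity studies). The second Piola-Kirchhoff stress is the exact
# derivative S = dW/dE and the material tangent is the exact second
# derivative, both assembled in Voigt form (11, 22, 33, 12, 13, 23 with
# engineering shear strains).

# Voigt index pairs
VGT_I <- c(1L, 2L, 3L, 1L, 1L, 2L)
VGT_J <- c(1L, 2L, 3L, 2L, 3L, 3L)

# deformation gradients for all elements: F[e, i, j] = d x_i / d X_j
def_gradients <- function(u, tets, grads) {
  ne <- dim(grads)[1L]
  F_ <- array(0, c(ne, 3L, 3L))
  for (i in 1:3) for (j in 1:3) {
    acc <- if (i == j) rep(1, ne) else rep(0, ne)
    for (a in 1:4) acc <- acc + u[tets[, a], i] * grads[, a, j]
    F_[, i, j] <- acc
  }
  F_
}

# batched kinematics: C (Voigt), inverse, invariants, J
kinematics <- function(F_) {
  ne <- dim(F_)[1L]
  Cv <- matrix(0, ne, 6L)
  for (p in 1:6) {
    i <- VGT_I[p]; j <- VGT_J[p]
    Cv[, p] <- F_[, 1L, i] * F_[, 1L, j] + F_[, 2L, i] * F_[, 2L, j] +
      F_[, 3L, i] * F_[, 3L, j]
  }
  J <- F_[, 1L, 1L] * (F_[, 2L, 2L] * F_[, 3L, 3L] - F_[, 2L, 3L] * F_[, 3L, 2L]) -
       F_[, 1L, 2L] * (F_[, 2L, 1L] * F_[, 3L, 3L] - F_[, 2L, 3L] * F_[, 3L, 1L]) +
       F_[, 1L, 3L] * (F_[, 2L, 1L] * F_[, 3L, 2L] - F_[, 2L, 2L] * F_[, 3L, 1L])
  I1 <- Cv[, 1L] + Cv[, 2L] + Cv[, 3L]
  trC2 <- Cv[, 1L]^2 + Cv[, 2L]^2 + Cv[, 3L]^2 +
    2 * (Cv[, 4L]^2 + Cv[, 5L]^2 + Cv[, 6L]^2)
  I2 <- 0.5 * (I1^2 - trC2)
  # inverse of symmetric C via cofactors; det C = J^2
  detC <- J^2
  Civ <- matrix(0, ne, 6L)
  Civ[, 1L] <- (Cv[, 2L] * Cv[, 3L] - Cv[, 6L]^2) / detC
  Civ[, 2L] <- (Cv[, 1L] * Cv[, 3L] - Cv[, 5L]^2) / detC
  Civ[, 3L] <- (Cv[, 1L] * Cv[, 2L] - Cv[, 4L]^2) / detC
  Civ[, 4L] <- (Cv[, 5L] * Cv[, 6L] - Cv[, 4L] * Cv[, 3L]) / detC
  Civ[, 5L] <- (Cv[, 4L] * Cv[, 6L] - Cv[, 5L] * Cv[, 2L]) / detC
  Civ[, 6L] <- (Cv[, 4L] * Cv[, 5L] - Cv[, 1L] * Cv[, 6L]) / detC
  list(C = Cv, Cinv = Civ, I1 = I1, I2 = I2, J = J)
}

# stress + tangent + energy density for all elements.
# c1, c2, kappa, dmg (1-zeta), dmg_vol, s_act are per-element vectors.
tissue_stress <- function(kin, c1, c2, kappa, dmg, dmg_vol, s_act,
                          want_tangent = TRUE) {
  Cv <- kin$C; Ci <- kin$Cinv; I1 <- kin$I1; I2 <- kin$I2; J <- kin$J
  ne <- length(J)
  if (any(J <= 0))
    stop("inverted-element error: det F <= 0 in ", sum(J <= 0), " element(s)",
         call. = FALSE)
  a <- J^(-2 / 3); b <- J^(-4 / 3)
  Iv <- matrix(rep(c(1, 1, 1, 0, 0, 0), each = ne), ne, 6L)

  # energy density
  W <- dmg * (c1 * (a * I1 - 3) + c2 * (b * I2 - 3)) +
    dmg_vol * kappa / 2 * (J - 1)^2

  # S = 2 dW/dC (+ isotropic active stress)
  T1 <- Iv - (I1 / 3) * Ci
  T2 <- I1 * Iv - Cv - (2 * I2 / 3) * Ci
  p_ <- dmg_vol * kappa * (J - 1)
  S <- 2 * dmg * c1 * a * T1 + 2 * dmg * c2 * b * T2 + (J * p_) * Ci
  S[, 1:3] <- S[, 1:3] + s_act

  out <- list(S = S, W = W, J = J)
  if (!want_tangent) return(out)

  # material tangent D = 2 dS/dC in Voigt form. Collecting the exact
  # derivative into dyad (X (x) Y), symmetrised-identity (A (.) A) and
  # constant blocks, with per-element coefficient vectors:
  #   D =  co_dyad (Ci (x) Ci) + co_sym4 (Ci (.) Ci)
  #      + co_ICi (I (x) Ci + Ci (x) I) + co_CCi (C (x) Ci + Ci (x) C)
  #      + co_II (I (x) I) + co_isym Isym
  c1d <- dmg * c1 * a
  c2d <- dmg * c2 * b
  co_dyad <- 4 * I1 * c1d / 9 + 16 * I2 * c2d / 9 + J * (p_ + J * dmg_vol * kappa)
  co_sym4 <- 4 * I1 * c1d / 3 + 8 * I2 * c2d / 3 - 2 * J * p_
  co_ICi <- -(4 * c1d / 3 + 8 * I1 * c2d / 3)
  co_CCi <- 8 * c2d / 3
  co_II <- 4 * c2d
  co_isym <- -4 * c2d

  D <- array(0, c(ne, 6L, 6L))
  for (p in 1:6) for (q in 1:6) {
    I_ <- VGT_I[p]; J_ <- VGT_J[p]; K_ <- VGT_I[q]; L_ <- VGT_J[q]
    # Ci as a full tensor accessor from Voigt storage
    ci_ <- function(i, j) Ci[, voigt_pos(i, j)]
    acc <- co_dyad * Ci[, p] * Ci[, q] +
      co_sym4 * 0.5 * (ci_(I_, K_) * ci_(J_, L_) + ci_(I_, L_) * ci_(J_, K_)) +
      co_ICi * (Iv[, p] * Ci[, q] + Ci[, p] * Iv[, q]) +
      co_CCi * (Cv[, p] * Ci[, q] + Ci[, p] * Cv[, q]) +
      co_II * Iv[, p] * Iv[, q]
    if (p == q) acc <- acc + co_isym * (if (p <= 3) 1 else 0.5)
    D[, p, q] <- acc
  }
  out$D <- D
  out
}

# Voigt position of tensor indices (i, j)
voigt_pos <- function(i, j) {
  if (i == j) return(i)
  s <- i + j
  if (s == 3L) 4L else if (s == 4L) 5L else 6L
}

#' Strain-energy density of damaged breast tissue
#'
#' Evaluates `W = (1 - zeta) [c1 (I1bar - 3) + c2 (I2bar - 3)] +
#' kappa/2 (J - 1)^2` for one deformation gradient. The integrity factor
#' scales the isochoric term only (see [material_set()] for the switch that
#' also scales the volumetric part).
#'
#' @param F_ 3x3 deformation gradient (`det F > 0`).
#' @param material list with `c1`, `c2`, `kappa` (one region of a
#'   [material_set()]).
#' @param zeta damage in `[0, 1)`.
#' @param damage_volumetric scale the volumetric term too (default `FALSE`).
#' @return energy density in J/m^3.
#' @export
strain_energy_tissue <- function(F_, material, zeta = 0,
                                 damage_volumetric = FALSE) {
  Fa <- array(F_, c(1L, 3L, 3L))
  Fa[1L, , ] <- F_
  kin <- kinematics(Fa)
  if (kin$J <= 0) stop("inverted-element error: det F <= 0", call. = FALSE)
  ts <- tissue_stress(kin, material$c1, material$c2, material$kappa,
                      1 - zeta, if (damage_volumetric) 1 - zeta else 1,
                      0, want_tangent = FALSE)
  as.numeric(ts$W)
}

#' Second Piola-Kirchhoff stress of damaged breast tissue
#'
#' Passive stress by exact differentiation of [strain_energy_tissue()],
#' plus the isotropic fibroblast active stress
#' `S_active = tau_f alpha_f (eta/eta0) eta0_f I` applied in the wound.
#'
#' @param F_ 3x3 deformation gradient.
#' @param material list with `c1`, `c2`, `kappa`.
#' @param zeta damage in `[0, 1)`.
#' @param eta_norm normalised cell density `eta/eta0` (drives the active
#'   stress).
#' @param in_wound logical: apply the active stress here.
#' @param active list with `tau_f`, `alpha_f`, `eta0_f` (default: no active
#'   stress).
#' @param damage_volumetric scale the volumetric term too.
#' @return symmetric 3x3 stress tensor (Pa).
#' @export
pk2_stress <- function(F_, material, zeta = 0, eta_norm = 0,
                       in_wound = FALSE, active = NULL,
                       damage_volumetric = FALSE) {
  s_act <- 0
  if (in_wound && !is.null(active))
    s_act <- active$tau_f * active$alpha_f * eta_norm * active$eta0_f
  Fa <- array(0, c(1L, 3L, 3L))
  Fa[1L, , ] <- F_
  kin <- kinematics(Fa)
  ts <- tissue_stress(kin, material$c1, material$c2, material$kappa,
                      1 - zeta, if (damage_volumetric) 1 - zeta else 1,
                      s_act, want_tangent = FALSE)
  v <- ts$S[1L, ]
  matrix(c(v[1L], v[4L], v[5L],
           v[4L], v[2L], v[6L],
           v[5L], v[6L], v[3L]), 3L, 3L)
}
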