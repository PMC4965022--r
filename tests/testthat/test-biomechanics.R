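# independent scalar energy evaluation used as the FD oracle for the stress
W_of_C <- function(C, mat, zeta) {
  J <- sqrt(det(C))
  I1 <- sum(diag(C))
  I2 <- 0.5 * (I1^2 - sum(C * C))
  (1 - zeta) * (mat$c1 * (J^(-2 / 3) * I1 - 3) +
                mat$c2 * (J^(-4 / 3) * I2 - 3)) +
    mat$kappa / 2 * (J - 1)^2
}

test_that("tissue strain energy is objective and damage-scaled", {
  mat <- list(c1 = 120, c2 = 30, kappa = 1.5e4)
  expect_equal(strain_energy_tissue(diag(3), mat, zeta = 0), 0)
  expect_equal(strain_energy_tissue(diag(3), mat, zeta = 0.7), 0)

  # pure rotation stores no energy
  Rt <- rigid_transform(0.7, axis = c(1, 2, 3))$R
  expect_equal(strain_energy_tissue(Rt, mat), 0, tolerance = 1e-12)

  # simple shear: damage halves the isochoric part, volumetric unchanged
  Fs <- diag(3); Fs[1, 2] <- 0.1
  W0 <- strain_energy_tissue(Fs, mat, zeta = 0)
  Wd <- strain_energy_tissue(Fs, mat, zeta = 0.5)
  # J = 1 in simple shear, so the whole energy is isochoric here
  expect_equal(Wd, W0 / 2, tolerance = 1e-12)
  # with a volumetric stretch the kappa term survives damage untouched
  Fv <- diag(c(1.1, 1, 1))
  kap_term <- mat$kappa / 2 * (1.1 - 1)^2
  W1 <- strain_energy_tissue(Fv, mat, zeta = 0)
  W2 <- strain_energy_tissue(Fv, mat, zeta = 0.5)
  expect_equal(W2 - kap_term, (W1 - kap_term) / 2, tolerance = 1e-10)
  # inverted configurations are rejected
  expect_error(strain_energy_tissue(diag(c(-1, 1, 1)), mat), "inverted")
})

test_that("PK2 stress is the exact derivative of the strain energy", {
  mat <- list(c1 = 120, c2 = 30, kappa = 1.5e4)
  expect_equal(pk2_stress(diag(3), mat), matrix(0, 3, 3))

  # central finite difference of W with respect to E (= C/2 shift)
  set.seed(2)
  F_ <- diag(3) + matrix(rnorm(9, 0, 0.05), 3, 3)
  zeta <- 0.3
  S <- pk2_stress(F_, mat, zeta = zeta)
  C <- t(F_) %*% F_
  eps <- 1e-6
  S_fd <- matrix(0, 3, 3)
  for (i in 1:3) for (j in i:3) {
    dC <- matrix(0, 3, 3)
    dC[i, j] <- dC[j, i] <- eps        # symmetric C perturbation
    Wp <- W_of_C(C + dC, mat, zeta)
    Wm <- W_of_C(C - dC, mat, zeta)
    g <- (Wp - Wm) / (2 * eps)
    # S = 2 dW/dC; the symmetric perturbation hits one diagonal entry but
    # both off-diagonal entries
    S_fd[i, j] <- S_fd[j, i] <- if (i == j) 2 * g else g
  }
  expect_equal(S, S_fd, tolerance = 1e-6)

  # the active stress is an isotropic addition proportional to eta/eta0
  act <- list(tau_f = 2e-10, alpha_f = 1.5, eta0_f = 1e13)
  Sa <- pk2_stress(F_, mat, zeta = zeta, eta_norm = 0.5, in_wound = TRUE,
                   active = act)
  expect_equal(Sa - S, diag(3) * 2e-10 * 1.5 * 0.5 * 1e13,
               tolerance = 1e-10)
  # and vanishes outside the wound
  expect_equal(pk2_stress(F_, mat, zeta = zeta, eta_norm = 0.5,
                          in_wound = FALSE, active = act), S)
})

test_that("skin membrane forces vanish for undeformed and rotated shells", {
  m <- supported_box()
  skin <- material_set()$skin
  u0 <- matrix(0, nrow(m$nodes), 3)
  expect_equal(max(abs(skin_membrane_force(m, u0, skin))), 0)

  # rigid rotation + translation of the whole shell
  tr <- rigid_transform(0.4, axis = c(1, 0, 1), shift = c(0.01, 0, -0.02))
  u_rig <- m$nodes %*% t(tr$R) - m$nodes +
    matrix(tr$t, nrow(m$nodes), 3, byrow = TRUE)
  f <- skin_membrane_force(m, u_rig, skin)
  expect_lt(max(abs(f)), 1e-10)
})

test_that("membrane tension matches the analytic plane-stress evaluation", {
  # one triangle under equibiaxial stretch lambda
  lam <- 1.2
  nodes <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)) * 0.01
  tris <- matrix(1:3, 1)
  skin <- list(alpha = 3e3, beta = 5, c2 = 1e3)
  pre <- bctsim:::membrane_reference(nodes, tris)
  u <- nodes * (lam - 1)
  # Cs = lam^2 I: invariants with incompressible thickness lam3 = lam^-2
  d <- lam^4
  I1t <- 2 * lam^2 + 1 / d
  I2t <- d + 2 * lam^2 / d
  # S = 2 [alpha beta e^{beta(I1-3)} g1 + c2 g2], g1/g2 diagonal here
  g1 <- 1 - 1 / (d * lam^2)
  g2 <- (d - (2 * lam^2) / d) / lam^2 + 1 / d
  S_exact <- 2 * (skin$alpha * skin$beta * exp(skin$beta * (I1t - 3)) * g1 +
                  skin$c2 * g2)
  mc <- bctsim:::membrane_constitutive(diag(2) * lam^2, skin)
  expect_equal(mc$S, diag(2) * S_exact, tolerance = 1e-10)
  # (the membrane tangent is exercised against finite differences through
  # the full-assembly check below, which includes the skin shell)
})

test_that("assembled tangent matches finite differences of the residual", {
  set.seed(42)
  m <- supported_box(n = 2L, L = 0.01)
  mats <- material_set()
  model <- bctsim:::mech_model(m, mats, gravity = c(0, -9.81, 0))
  u <- matrix(rnorm(3 * nrow(m$nodes), 0, 2e-4), ncol = 3)
  asm <- bctsim:::assemble(model, u, 1)
  K <- as.matrix(asm$K)
  expect_lt(max(abs(K - t(K))) / max(abs(K)), 1e-12)
  uv <- as.vector(t(u))
  nd <- length(uv)
  eps <- 1e-7
  Kfd <- matrix(0, nd, nd)
  for (j in seq_len(nd)) {
    up <- uv; up[j] <- up[j] + eps
    um <- uv; um[j] <- um[j] - eps
    Rp <- bctsim:::assemble(model, matrix(up, ncol = 3, byrow = TRUE), 1,
                            want_tangent = FALSE)$R
    Rm <- bctsim:::assemble(model, matrix(um, ncol = 3, byrow = TRUE), 1,
                            want_tangent = FALSE)$R
    Kfd[, j] <- (Rp - Rm) / (2 * eps)
  }
  expect_lt(max(abs(K - Kfd)) / max(abs(Kfd)), 1e-5)
})

test_that("unconstrained tangent has exactly six rigid-body modes", {
  m <- box_mesh(2L, 2L, 2L, 0.01, 0.01, 0.01)
  m$tri_patch[] <- "lateral"                  # nothing constrained, no skin
  mats <- material_set()
  model <- bctsim:::mech_model(
    m, mats, bcs = data.frame(node = 1L, dof = 1L, value = 0))
  model$fixed_dof <- integer(0)               # truly unconstrained
  model$free_dof <- seq_len(3L * nrow(m$nodes))
  asm <- bctsim:::assemble(model, matrix(0, nrow(m$nodes), 3), 0)
  ev <- eigen(as.matrix(asm$K), symmetric = TRUE, only.values = TRUE)$values
  scale <- max(ev)
  expect_equal(sum(abs(ev) < 1e-9 * scale), 6L)
  expect_true(all(ev > -1e-9 * scale))
})

test_that("zero load gives zero displacement and weight is balanced by reactions", {
  m <- supported_box()
  mats <- material_set(adipose = list(c1 = 1000, c2 = 250, kappa = 1e5,
                                      rho0 = 1000))
  st0 <- solve_static(m, mats, gravity = c(0, 0, 0))
  expect_equal(max(abs(st0$u)), 0)

  g <- c(0, -9.81, 0)
  st <- solve_static(m, mats, gravity = g)
  expect_true(all(st$J > 0))
  rf <- reaction_forces(m, mats, st, gravity = g)
  skin_area <- sum(vapply(
    bctsim:::membrane_reference(m$nodes,
                                m$boundary_tris[m$tri_patch == "skin", ]),
    function(p) p$area, 0))
  weight <- (1000 * region_volume(m) +
             mats$skin$rho0 * m$skin_thickness * skin_area) * 9.81
  expect_equal(sum(rf[, 2]), weight, tolerance = 1e-8)
})

test_that("uniaxial stretch reproduces the incompressible Mooney-Rivlin closed form", {
  L <- 0.01; lam <- 1.3
  c1 <- 100; c2 <- 25
  mb <- box_mesh(2L, 2L, 2L, L, L, L)
  mb$tri_patch[] <- "lateral"
  nodes <- mb$nodes
  tolc <- 1e-12
  ex <- rbind(
    data.frame(node = which(nodes[, 3] < tolc), dof = 3L, value = 0),
    data.frame(node = which(nodes[, 3] > L - tolc), dof = 3L,
               value = (lam - 1) * L),
    data.frame(node = which(nodes[, 1] < tolc), dof = 1L, value = 0),
    data.frame(node = which(nodes[, 2] < tolc), dof = 2L, value = 0))
  mats <- material_set(adipose = list(c1 = c1, c2 = c2, kappa = 1e4 * c1,
                                      rho0 = 1000))
  bcs <- mech_bcs(mb, extra = ex)
  st <- solve_static(mb, mats, bcs = bcs, n_increments = 6L)
  rf <- reaction_forces(mb, mats, st, bcs = bcs)
  Fz <- sum(rf[nodes[, 3] > L - tolc, 3])
  lx <- 1 + max(st$u[nodes[, 1] > L - tolc, 1]) / L
  ly <- 1 + max(st$u[nodes[, 2] > L - tolc, 2]) / L
  sigma <- Fz / (lx * ly * L^2)               # Cauchy stress on deformed area
  sigma_exact <- 2 * (c1 + c2 / lam) * (lam^2 - 1 / lam)
  expect_equal(sigma, sigma_exact, tolerance = 0.01)
  # near-incompressibility at kappa/c1 = 1e4
  expect_lt(abs(max(st$J) - 1), 5e-3)
})

test_that("penalty strength drives the volume change to zero monotonically", {
  m <- supported_box(n = 2L)
  g <- c(0, -9.81, 0)
  dv <- vapply(c(1e2, 1e3, 1e4), function(ratio) {
    mats <- material_set(adipose = list(c1 = 200, c2 = 50,
                                        kappa = 200 * ratio, rho0 = 1000))
    st <- solve_static(m, mats, gravity = g)
    abs(region_volume(m, displacement = st$u) - region_volume(m)) /
      region_volume(m)
  }, 0)
  expect_true(all(diff(dv) < 0))
  expect_lt(dv[3], 0.5e-2)
})

test_that("element pressure reports the condensed mixed-formulation unknown", {
  m <- supported_box(n = 2L)
  mats <- material_set(adipose = list(c1 = 500, c2 = 125, kappa = 5e4,
                                      rho0 = 1000))
  st <- solve_static(m, mats, gravity = c(0, -9.81, 0))
  expect_equal(st$pressure, mats$adipose$kappa * (st$J - 1),
               tolerance = 1e-12)
})
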