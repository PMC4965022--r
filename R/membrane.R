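# Veronda-Westmann skin membrane: the dermis/epidermis is a thin,
# incompressible, hyperelastic shell over the skin patch, discretised with
# constant-strain membrane triangles integrated over the (constant) skin
# thickness. Through-thickness incompressibility is enforced exactly by the
# plane-stress substitution lambda3^2 = 1 / det(Cs):
#
#   I1tilde = tr(Cs) + 1/det(Cs)
#   I2tilde = det(Cs) + tr(Cs)/det(Cs)
#   W_skin  = alpha [exp(beta (I1tilde - 3)) - 1] + c2 (I2tilde - 3)
#
# with Cs the 2x2 in-plane right Cauchy-Green tensor.

# local reference frame + 2D shape gradients for each skin triangle
membrane_reference <- function(nodes, tris) {
  n <- nrow(tris)
  pre <- vector("list", n)
  for (t in seq_len(n)) {
    X <- nodes[tris[t, ], , drop = FALSE]
    e1 <- X[2L, ] - X[1L, ]
    e2 <- X[3L, ] - X[1L, ]
    nrm <- c(e1[2L] * e2[3L] - e1[3L] * e2[2L],
             e1[3L] * e2[1L] - e1[1L] * e2[3L],
             e1[1L] * e2[2L] - e1[2L] * e2[1L])
    A2 <- sqrt(sum(nrm^2))           # 2 * area
    if (A2 <= 0) stop("degenerate skin triangle ", t, call. = FALSE)
    t1 <- e1 / sqrt(sum(e1^2))
    nn <- nrm / A2
    t2 <- c(nn[2L] * t1[3L] - nn[3L] * t1[2L],
            nn[3L] * t1[1L] - nn[1L] * t1[3L],
            nn[1L] * t1[2L] - nn[2L] * t1[1L])
    # 2D reference coordinates of the three vertices
    P <- cbind(c(0, sum(e1 * t1), sum(e2 * t1)),
               c(0, 0, sum(e2 * t2)))
    # gradients of the linear shape functions in the 2D frame
    detJ <- (P[2L, 1L] - P[1L, 1L]) * (P[3L, 2L] - P[1L, 2L]) -
      (P[3L, 1L] - P[1L, 1L]) * (P[2L, 2L] - P[1L, 2L])
    G <- matrix(0, 3L, 2L)
    G[2L, ] <- c(P[3L, 2L] - P[1L, 2L], P[1L, 1L] - P[3L, 1L]) / detJ
    G[3L, ] <- c(P[1L, 2L] - P[2L, 2L], P[2L, 1L] - P[1L, 1L]) / detJ
    G[1L, ] <- -(G[2L, ] + G[3L, ])
    pre[[t]] <- list(G = G, area = A2 / 2)
  }
  pre
}

# 2x2 membrane PK2 stress and (optional) tangent from Cs in Voigt order
# (11, 22, 12) with engineering shear. Returns energy density too.
membrane_constitutive <- function(Cs, skin, want_tangent = TRUE) {
  a_ <- skin$alpha; b_ <- skin$beta; c2 <- skin$c2
  tr <- Cs[1L, 1L] + Cs[2L, 2L]
  d <- Cs[1L, 1L] * Cs[2L, 2L] - Cs[1L, 2L]^2
  if (d <= 0) stop("degenerate membrane deformation", call. = FALSE)
  Ci <- matrix(c(Cs[2L, 2L], -Cs[1L, 2L], -Cs[1L, 2L], Cs[1L, 1L]),
               2L, 2L) / d
  I1t <- tr + 1 / d
  I2t <- d + tr / d
  Id <- diag(2L)
  expb <- exp(b_ * (I1t - 3))
  W <- a_ * (expb - 1) + c2 * (I2t - 3)
  g1 <- Id - Ci / d                      # d I1t / d Cs
  g2 <- (d - tr / d) * Ci + Id / d       # d I2t / d Cs
  S <- 2 * (a_ * b_ * expb * g1 + c2 * g2)
  out <- list(S = S, W = W)
  if (!want_tangent) return(out)
  # fourth-order blocks as 3x3 Voigt (tensor components; engineering shear)
  vI <- c(1L, 2L, 1L); vJ <- c(1L, 2L, 2L)
  outer6 <- function(X, Y) {
    M <- matrix(0, 3L, 3L)
    for (p in 1:3) for (q in 1:3)
      M[p, q] <- X[vI[p], vJ[p]] * Y[vI[q], vJ[q]]
    M
  }
  sym4 <- function(A) {
    M <- matrix(0, 3L, 3L)
    for (p in 1:3) for (q in 1:3)
      M[p, q] <- 0.5 * (A[vI[p], vI[q]] * A[vJ[p], vJ[q]] +
                        A[vI[p], vJ[q]] * A[vJ[p], vI[q]])
    M
  }
  # dg1/dCs = (1/d)(Ci (x) Ci) + (1/d)(Ci (.) Ci)
  dg1 <- outer6(Ci, Ci) / d + sym4(Ci) / d
  # dg2/dCs = Ci (x) (d Ci - I/d + (tr/d) Ci) - (d - tr/d)(Ci (.) Ci)
  #           - (1/d) I (x) Ci
  dg2 <- outer6(Ci, d * Ci - Id / d + (tr / d) * Ci) -
    (d - tr / d) * sym4(Ci) - outer6(Id, Ci) / d
  g1v <- c(g1[1L, 1L], g1[2L, 2L], g1[1L, 2L])
  # D = 2 dS/dCs = dS/dE with engineering shear strain
  out$D <- 4 * (a_ * b_^2 * expb * (g1v %o% g1v) +
                a_ * b_ * expb * dg1 + c2 * dg2)
  out
}

# internal force and tangent contribution of the skin membrane.
# u: nodal displacement matrix; returns list(f = sparse-ready triplets or
# dense accumulation, K triplets) via the supplied accumulators.
membrane_assemble <- function(nodes, u, tris, pre, skin, thickness,
                              want_tangent = TRUE) {
  nn <- nrow(nodes)
  f <- matrix(0, nn, 3L)
  ntri <- nrow(tris)
  ii <- jj <- xx <- vector("list", ntri)
  W_total <- 0
  for (t in seq_len(ntri)) {
    idx <- tris[t, ]
    G <- pre[[t]]$G
    x <- nodes[idx, , drop = FALSE] + u[idx, , drop = FALSE]
    Fm <- t(x) %*% G                   # 3x2 membrane deformation gradient
    Cs <- t(Fm) %*% Fm
    mc <- membrane_constitutive(Cs, skin, want_tangent)
    w <- thickness * pre[[t]]$area
    W_total <- W_total + w * mc$W
    FS <- Fm %*% mc$S                  # 3x2
    for (a in 1:3)
      f[idx[a], ] <- f[idx[a], ] + w * as.vector(FS %*% G[a, ])
    if (!want_tangent) next
    # element tangent 9x9: material + geometric
    B <- matrix(0, 3L, 9L)             # Voigt(3) x (node, comp)
    for (a in 1:3) for (i in 1:3) {
      col <- 3L * (a - 1L) + i
      B[1L, col] <- Fm[i, 1L] * G[a, 1L]
      B[2L, col] <- Fm[i, 2L] * G[a, 2L]
      B[3L, col] <- Fm[i, 1L] * G[a, 2L] + Fm[i, 2L] * G[a, 1L]
    }
    Ke <- w * (t(B) %*% mc$D %*% B)
    Sg <- G %*% mc$S %*% t(G)          # 3x3 node-pair geometric factor
    for (a in 1:3) for (b in 1:3) {
      ra <- 3L * (a - 1L); rb <- 3L * (b - 1L)
      Ke[ra + 1L, rb + 1L] <- Ke[ra + 1L, rb + 1L] + w * Sg[a, b]
      Ke[ra + 2L, rb + 2L] <- Ke[ra + 2L, rb + 2L] + w * Sg[a, b]
      Ke[ra + 3L, rb + 3L] <- Ke[ra + 3L, rb + 3L] + w * Sg[a, b]
    }
    gdof <- as.vector(t(outer(3L * (idx - 1L), 1:3, "+")))
    ii[[t]] <- rep(gdof, times = 9L)
    jj[[t]] <- rep(gdof, each = 9L)
    xx[[t]] <- as.vector(Ke)
  }
  list(f = f, ii = unlist(ii), jj = unlist(jj), xx = unlist(xx),
       W = W_total)
}

#' Skin membrane internal forces
#'
#' Nodal internal-force contribution of the Veronda-Westmann skin shell for
#' a given displacement field. Zero for the undeformed shell and for rigid
#' rotations (the model depends on the in-plane stretch only).
#'
#' @param mesh a [labeled_mesh()] with a skin patch.
#' @param u nodal displacement matrix (nodes x 3).
#' @param skin list with `alpha`, `beta`, `c2` (see [material_set()]).
#' @param thickness membrane thickness (m); defaults to the mesh's skin
#'   thickness.
#' @return nodes x 3 matrix of internal forces (N).
#' @export
skin_membrane_force <- function(mesh, u, skin, thickness = NULL) {
  if (is.null(thickness)) thickness <- mesh$skin_thickness
  tris <- mesh$boundary_tris[mesh$tri_patch == "skin", , drop = FALSE]
  if (!nrow(tris)) stop("mesh has no skin patch", call. = FALSE)
  pre <- membrane_reference(mesh$nodes, tris)
  membrane_assemble(mesh$nodes, as.matrix(u), tris, pre, skin, thickness,
                    want_tangent = FALSE)$f
}
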