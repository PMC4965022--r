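# Synthetic breast phantom: hemispherical dome of adipose + fibroglandular
# tissue sitting on a tissue slab whose base represents the chest-wall fascia.
#
# Coordinate convention (used throughout the package): X lateral, Y anterior
# (the breast protrudes in +Y), Z cranial. The chest wall is the plane
# y = -slab_depth; clip planes are the z = +/-a slab sides (superior/inferior)
# and the x = +/-a sides are the lateral boundary.

# elliptical cube-surface-to-sphere map (exact on the cube surface)
ell_map3 <- function(p) {
  x <- p[, 1L]; y <- p[, 2L]; z <- p[, 3L]
  cbind(x * sqrt(pmax(0, 1 - y^2 / 2 - z^2 / 2 + y^2 * z^2 / 3)),
        y * sqrt(pmax(0, 1 - z^2 / 2 - x^2 / 2 + z^2 * x^2 / 3)),
        z * sqrt(pmax(0, 1 - x^2 / 2 - y^2 / 2 + x^2 * y^2 / 3)))
}

# solid cube-to-ball map. Direction comes from the elliptical map; the radius
# blends the L-infinity shell (even radial spacing, but spherical shells that
# flatten diagonal-adjacent tets) with the elliptical radius (non-spherical
# shells, but radial crowding at corners). The 50/50 blend keeps both the
# radial spacing and the shell curvature healthy, and is exact on the surface.
cube_to_ball <- function(p) {
  ninf <- pmax(abs(p[, 1L]), abs(p[, 2L]), abs(p[, 3L]))
  out <- p * 0
  pos <- ninf > 0
  e <- ell_map3(p[pos, , drop = FALSE])
  ne <- sqrt(rowSums(e^2))
  r <- 0.5 * (ninf[pos] + ne)
  out[pos, ] <- e / ne * r
  out
}

# in-plane counterpart on the unit square [-1,1]^2 (the z = 0 restriction of
# cube_to_ball, so the dome base and the slab top coincide node-for-node)
square_to_disc <- function(p2) {
  ninf <- pmax(abs(p2[, 1L]), abs(p2[, 2L]))
  out <- p2 * 0
  pos <- ninf > 0
  u <- p2[pos, 1L]; v <- p2[pos, 2L]
  e <- cbind(u * sqrt(pmax(0, 1 - v^2 / 2)),
             v * sqrt(pmax(0, 1 - u^2 / 2)))
  ne <- sqrt(rowSums(e^2))
  r <- 0.5 * (ninf[pos] + ne)
  out[pos, ] <- e / ne * r
  out
}

#' Generate a synthetic breast phantom mesh
#'
#' Builds a labelled tetrahedral mesh of a hemispherical breast (radius
#' `breast_radius`) resting on a rectangular tissue slab of depth
#' `slab_depth`; the slab base is the chest-wall (fascia) patch, the slab
#' sides provide the clip planes, and the dome plus the exposed slab top form
#' the skin shell. An inner ellipsoidal fibroglandular core occupies
#' approximately `fibro_fraction` of the breast volume; the remainder (and the
#' slab) is adipose. The mesh is a structured hex grid split into conforming
#' tetrahedra, with the dome produced by a radial cube-to-ball map so all dome
#' surface vertices lie exactly on the sphere. A small deterministic jitter
#' (driven by `seed`) is applied to interior nodes so the mesh is not exactly
#' structured.
#'
#' @param breast_radius hemisphere radius in metres.
#' @param slab_depth slab (chest-wall offset) thickness in metres.
#' @param target_edge_length requested element edge length in metres; controls
#'   mesh resolution.
#' @param fibro_fraction target fibroglandular share of breast volume, in
#'   `[0, 1]`.
#' @param seed integer seed for the interior-node jitter (same seed gives a
#'   bitwise-identical mesh).
#' @param slab_half_width half-width of the slab in metres (default
#'   `1.6 * breast_radius`, snapped to the grid).
#' @param jitter relative jitter amplitude (fraction of local spacing).
#' @param skin_thickness skin membrane thickness in metres.
#' @return a [labeled_mesh()].
#' @export
generate_phantom <- function(breast_radius, slab_depth, target_edge_length,
                             fibro_fraction = 0.25, seed = 1L,
                             slab_half_width = 1.6 * breast_radius,
                             jitter = 0.15, skin_thickness = 1.5e-3) {
  stopifnot(breast_radius > 0, slab_depth > 0, target_edge_length > 0,
            fibro_fraction >= 0, fibro_fraction <= 1)
  R <- breast_radius
  m <- max(3L, as.integer(round(R / target_edge_length)))
  if (m < 3L)
    stop("meshing failure: target_edge_length too large relative to the ",
         "breast radius", call. = FALSE)
  h <- R / m                                   # lattice spacing
  if (slab_half_width <= R)
    stop("slab_half_width must exceed breast_radius", call. = FALSE)
  K <- max(1L, as.integer(round((slab_half_width - R) / h)))
  M <- m + K                                   # slab half-cells
  a <- slab_half_width                         # slab extent kept exact
  # 1D lattice coordinate: uniform h inside the breast footprint, the outer
  # ring stretched so the slab edge lands exactly at +/- a
  coord1d <- function(i) {
    s <- sign(i); i <- abs(i)
    ifelse(i <= m, s * i * h, s * (R + (i - m) * (a - R) / K))
  }
  nz <- max(2L, as.integer(round(slab_depth / h)))

  # --- slab: warped structured grid, 2M x 2M x nz cells -------------------
  # per-octant mirrored splits keep cell diagonals running away from the
  # breast axis so no tet ends up with all four vertices on a mapped shell
  ci_s <- rep(0:(2L * M - 1L), times = 2L * M * nz)
  cj_s <- rep(rep(0:(2L * M - 1L), each = 2L * M), times = nz)
  gs <- structured_grid(2L * M, 2L * M, nz,
                        flip_u = ci_s + 0.5 < M, flip_v = cj_s + 0.5 < M)
  # generation frame (u, v, w): u,v in-plane, w vertical (breast axis)
  su <- coord1d(gs$nodes[, 1L] - M)
  sv <- coord1d(gs$nodes[, 2L] - M)
  sw <- (gs$nodes[, 3L] / nz - 1) * slab_depth  # [-slab_depth, 0]
  p2 <- cbind(su, sv)
  tinf <- pmax(abs(su), abs(sv))
  # disc map scaled per point: L-inf square of size max(t, R) -> disc
  s <- pmax(tinf, R)
  inner <- square_to_disc(p2 / s) * s
  wgt <- pmin(1, pmax(0, (tinf - R) / (a - R)))
  wgt[tinf <= R] <- 0
  p2w <- inner * (1 - wgt) + p2 * wgt
  slab_nodes <- cbind(p2w[, 1L], p2w[, 2L], sw)
  slab_key <- paste(gs$nodes[, 1L] - M, gs$nodes[, 2L] - M, gs$nodes[, 3L] - nz,
                    sep = ",")

  # --- dome: half-cube grid 2m x 2m x m mapped onto the hemisphere --------
  ci_d <- rep(0:(2L * m - 1L), times = 2L * m * m)
  cj_d <- rep(rep(0:(2L * m - 1L), each = 2L * m), times = m)
  gd <- structured_grid(2L * m, 2L * m, m,
                        flip_u = ci_d + 0.5 < m, flip_v = cj_d + 0.5 < m)
  du <- (gd$nodes[, 1L] - m) / m
  dv <- (gd$nodes[, 2L] - m) / m
  dw <- gd$nodes[, 3L] / m
  dome_nodes <- cube_to_ball(cbind(du, dv, dw)) * R
  dome_key <- paste(gd$nodes[, 1L] - m, gd$nodes[, 2L] - m, gd$nodes[, 3L],
                    sep = ",")

  # --- merge: dome base (w = 0, |i|,|j| <= m) coincides with slab top -----
  lookup <- new.env(hash = TRUE, parent = emptyenv())
  for (i in seq_along(slab_key)) assign(slab_key[i], i, envir = lookup)
  nslab <- nrow(slab_nodes)
  dome_global <- integer(nrow(dome_nodes))
  extra <- 0L
  for (i in seq_along(dome_key)) {
    hit <- lookup[[dome_key[i]]]
    if (!is.null(hit)) dome_global[i] <- hit
    else { extra <- extra + 1L; dome_global[i] <- nslab + extra }
  }
  new_idx <- which(dome_global > nslab)
  nodes <- rbind(slab_nodes, dome_nodes[new_idx, , drop = FALSE])
  tets <- rbind(gs$tets, matrix(dome_global[gd$tets], ncol = 4L))

  # --- deterministic interior jitter --------------------------------------
  bnd <- unique(as.vector(boundary_faces(tets)))
  interior <- setdiff(seq_len(nrow(nodes)), bnd)
  if (jitter > 0 && length(interior)) {
    set.seed(as.integer(seed) %% .Machine$integer.max)
    amp <- jitter * h
    nodes[interior, ] <- nodes[interior, ] +
      matrix(stats::runif(3L * length(interior), -amp, amp), ncol = 3L)
  }

  # --- map generation frame (u, v, w) to package frame (x, y, z) ----------
  # u -> x (lateral), w -> y (anterior, breast axis), v -> z (cranial)
  nodes <- cbind(nodes[, 1L], nodes[, 3L], nodes[, 2L])

  # --- regions: ellipsoidal fibroglandular core ---------------------------
  region <- rep("adipose", nrow(tets))
  if (fibro_fraction > 0) {
    # core semi-axes (ra, rc, ra) with rc = 0.75 ra, centred on the axis
    # inside the dome; solve (4/3) pi ra^2 rc = f * (2/3) pi R^3
    ra <- R * (fibro_fraction / (2 * 0.75))^(1 / 3)
    rc <- 0.75 * ra
    cy <- 0.45 * R
    cen <- (nodes[tets[, 1L], ] + nodes[tets[, 2L], ] +
            nodes[tets[, 3L], ] + nodes[tets[, 4L], ]) / 4
    inside <- (cen[, 1L] / ra)^2 + ((cen[, 2L] - cy) / rc)^2 +
      (cen[, 3L] / ra)^2 <= 1
    region[inside] <- "fibroglandular"
  }

  # --- boundary patches ----------------------------------------------------
  btris <- boundary_faces(tets)
  fc <- (nodes[btris[, 1L], ] + nodes[btris[, 2L], ] + nodes[btris[, 3L], ]) / 3
  tol <- 1e-9 * R
  patch <- rep("skin", nrow(btris))
  patch[abs(fc[, 2L] + slab_depth) < tol] <- "chest"
  patch[abs(fc[, 3L] - a) < tol] <- "clip_superior"
  patch[abs(fc[, 3L] + a) < tol] <- "clip_inferior"
  patch[abs(fc[, 1L] - a) < tol] <- "lateral"
  patch[abs(fc[, 1L] + a) < tol] <- "lateral"

  labeled_mesh(nodes, tets, region, btris, patch,
               skin_thickness = skin_thickness)
}
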