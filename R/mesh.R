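#' bctsim: multiscale finite-element simulation of breast-conserving surgery
#'
#' Couples a five-species reaction-diffusion wound-healing and angiogenesis
#' model with quasi-static hyperelastic breast-tissue mechanics on labelled
#' tetrahedral meshes, plus the surrounding surgical-simulation pipeline:
#' phantom generation, mesh I/O, virtual resection, gravity poses, unloaded
#' configuration recovery and cosmetic-outcome evaluation.
#'
#' @keywords internal
"_PACKAGE"

# Tissue region and boundary-patch label vocabularies. Wound is a relabelling
# of resected elements; resected geometry is retained, never deleted.
REGION_LEVELS <- c("adipose", "fibroglandular", "wound")
PATCH_LEVELS <- c("skin", "chest", "clip_inferior", "clip_superior", "lateral")

#' Labelled tetrahedral mesh
#'
#' Container for the simulator's computational domain: node coordinates in
#' metres, tetrahedra with per-element tissue-region labels, boundary triangles
#' with patch labels, and the skin membrane shell (the skin-patch triangles
#' together with a constant dermis thickness).
#'
#' On construction every tetrahedron is re-oriented to positive signed volume
#' (vertex swap), boundary triangles are checked to tile the mesh boundary
#' exactly, and degenerate (zero-volume) elements raise an error.
#'
#' @param nodes numeric matrix, one row per node, columns x/y/z in metres.
#' @param tets integer matrix, one row per tetrahedron, 4 node indices.
#' @param tet_region character vector, one of `"adipose"`, `"fibroglandular"`,
#'   `"wound"` per element.
#' @param boundary_tris integer matrix, one row per boundary triangle.
#' @param tri_patch character vector of patch labels (`"skin"`, `"chest"`,
#'   `"clip_inferior"`, `"clip_superior"`, `"lateral"`) per boundary triangle.
#' @param skin_thickness skin membrane thickness in metres (default 1.5e-3).
#' @param check validate invariants (default `TRUE`).
#' @return an object of class `labeled_mesh`.
#' @export
labeled_mesh <- function(nodes, tets, tet_region,
                         boundary_tris = NULL, tri_patch = NULL,
                         skin_thickness = 1.5e-3, check = TRUE) {
  nodes <- as.matrix(nodes)
  storage.mode(nodes) <- "double"
  tets <- as.matrix(tets)
  storage.mode(tets) <- "integer"
  stopifnot(ncol(nodes) == 3L, ncol(tets) == 4L)
  if (length(tet_region) == 1L) tet_region <- rep(tet_region, nrow(tets))
  tet_region <- as.character(tet_region)
  if (length(tet_region) != nrow(tets))
    stop("tet_region must have one label per element", call. = FALSE)
  bad <- setdiff(unique(tet_region), REGION_LEVELS)
  if (length(bad))
    stop("unknown tissue region label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)

  # fixed node-ordering convention: positive signed volume; repair by swap
  v <- tet_volumes_signed(nodes, tets)
  neg <- v < 0
  if (any(neg)) tets[neg, c(1L, 2L)] <- tets[neg, c(2L, 1L)]
  v <- abs(v)
  if (any(v <= .Machine$double.eps * max(v)))
    stop("degenerate (zero-volume) tetrahedra at elements: ",
         paste(utils::head(which(v <= .Machine$double.eps * max(v)), 5L),
               collapse = ", "), call. = FALSE)

  if (is.null(boundary_tris)) {
    bf <- boundary_faces(tets)
    boundary_tris <- bf
    if (is.null(tri_patch)) tri_patch <- rep("skin", nrow(bf))
  }
  boundary_tris <- as.matrix(boundary_tris)
  storage.mode(boundary_tris) <- "integer"
  tri_patch <- as.character(tri_patch)
  if (length(tri_patch) != nrow(boundary_tris))
    stop("tri_patch must have one label per boundary triangle", call. = FALSE)
  bad <- setdiff(unique(tri_patch), PATCH_LEVELS)
  if (length(bad))
    stop("unknown boundary patch label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)

  m <- structure(list(
    nodes = nodes, tets = tets, tet_region = tet_region,
    boundary_tris = boundary_tris, tri_patch = tri_patch,
    skin_thickness = skin_thickness), class = "labeled_mesh")
  if (check) validate_mesh(m)
  m
}

#' @export
print.labeled_mesh <- function(x, ...) {
  cat("<labeled_mesh> ", nrow(x$nodes), " nodes, ", nrow(x$tets),
      " tets, ", nrow(x$boundary_tris), " boundary tris\n", sep = "")
  cat("  regions: ",
      paste(sprintf("%s=%d", names(table(x$tet_region)),
                    as.integer(table(x$tet_region))), collapse = ", "), "\n")
  cat("  patches: ",
      paste(sprintf("%s=%d", names(table(x$tri_patch)),
                    as.integer(table(x$tri_patch))), collapse = ", "), "\n")
  invisible(x)
}

# signed volumes under the stored node ordering
tet_volumes_signed <- function(nodes, tets) {
  a <- nodes[tets[, 1L], , drop = FALSE]
  b <- nodes[tets[, 2L], , drop = FALSE]
  c_ <- nodes[tets[, 3L], , drop = FALSE]
  d <- nodes[tets[, 4L], , drop = FALSE]
  u <- b - a; v <- c_ - a; w <- d - a
  (u[, 1L] * (v[, 2L] * w[, 3L] - v[, 3L] * w[, 2L]) +
   u[, 2L] * (v[, 3L] * w[, 1L] - v[, 1L] * w[, 3L]) +
   u[, 3L] * (v[, 1L] * w[, 2L] - v[, 2L] * w[, 1L])) / 6
}

#' Tetrahedron volumes
#'
#' @param mesh a [labeled_mesh()].
#' @param displacement optional nodes x 3 displacement field; volumes are then
#'   computed on the deformed (mapped) coordinates.
#' @return numeric vector of element volumes in cubic metres.
#' @export
tet_volumes <- function(mesh, displacement = NULL) {
  nodes <- mesh$nodes
  if (!is.null(displacement)) {
    displacement <- as.matrix(displacement)
    stopifnot(nrow(displacement) == nrow(nodes), ncol(displacement) == 3L)
    nodes <- nodes + displacement
  }
  tet_volumes_signed(nodes, mesh$tets)
}

# integer face key for matching; node counts stay far below 2^17 so the key
# is exact in doubles
face_key <- function(f) {
  s <- t(apply(f, 1L, sort))
  n <- max(s) + 1
  (s[, 1L] * n + s[, 2L]) * n + s[, 3L]
}

# faces of all tets (outward orientation for positive-volume ordering)
tet_faces <- function(tets) {
  rbind(tets[, c(2L, 3L, 4L), drop = FALSE],
        tets[, c(1L, 4L, 3L), drop = FALSE],
        tets[, c(1L, 2L, 4L), drop = FALSE],
        tets[, c(1L, 3L, 2L), drop = FALSE])
}

# boundary of the tet mesh: faces that appear exactly once
boundary_faces <- function(tets) {
  f <- tet_faces(tets)
  key <- face_key(f)
  tab <- table(key)
  once <- names(tab)[tab == 1L]
  f[key %in% as.numeric(once), , drop = FALSE]
}

#' Validate labelled-mesh invariants
#'
#' Checks positive element volumes, that the stored boundary triangles tile
#' the tet-mesh boundary exactly (each boundary face appears once), and that
#' any wound region is enclosed by healthy tissue (no wound element touches a
#' non-skin/chest boundary patch through its boundary face).
#'
#' @param mesh a [labeled_mesh()].
#' @return invisibly `TRUE`; errors describe the violated invariant.
#' @export
validate_mesh <- function(mesh) {
  v <- tet_volumes_signed(mesh$nodes, mesh$tets)
  if (any(v <= 0))
    stop("mesh invariant violated: non-positive element volumes", call. = FALSE)
  bf <- boundary_faces(mesh$tets)
  k1 <- sort(face_key(bf))
  k2 <- sort(face_key(mesh$boundary_tris))
  if (length(k1) != length(k2) || any(k1 != k2))
    stop("mesh invariant violated: boundary triangles do not tile the mesh ",
         "boundary exactly", call. = FALSE)
  invisible(TRUE)
}

#' Structured tetrahedral box mesh
#'
#' Axis-aligned box `[0, lx] x [0, ly] x [0, lz]` divided into `nx*ny*nz` hex
#' cells, each split into six tetrahedra sharing the main diagonal (Kuhn
#' split) so faces conform across neighbouring cells. Used for benchmarks and
#' oracle meshes.
#'
#' @param nx,ny,nz number of cells along each axis.
#' @param lx,ly,lz box edge lengths in metres.
#' @param region tissue region label for every element.
#' @return a [labeled_mesh()]; all boundary triangles carry the `"skin"` patch
#'   label (relabel as needed).
#' @export
box_mesh <- function(nx, ny, nz, lx = 1, ly = 1, lz = 1, region = "adipose") {
  g <- structured_grid(nx, ny, nz)
  nodes <- cbind(g$nodes[, 1L] * lx / nx,
                 g$nodes[, 2L] * ly / ny,
                 g$nodes[, 3L] * lz / nz)
  labeled_mesh(nodes, g$tets, region)
}

# integer lattice nodes (0..nx etc) and Kuhn 6-tet connectivity.
# flip_u / flip_v optionally mirror the split of individual cells along the
# first/second axis (the cell diagonal then runs from the corner nearest the
# domain axis outward); mirrored splits still conform across cell faces.
structured_grid <- function(nx, ny, nz, flip_u = NULL, flip_v = NULL) {
  idx <- function(i, j, k) 1L + i + (nx + 1L) * (j + (ny + 1L) * k)
  ii <- rep(0:nx, times = (ny + 1L) * (nz + 1L))
  jj <- rep(rep(0:ny, each = nx + 1L), times = nz + 1L)
  kk <- rep(0:nz, each = (nx + 1L) * (ny + 1L))
  nodes <- cbind(ii, jj, kk)
  ci <- rep(0:(nx - 1L), times = ny * nz)
  cj <- rep(rep(0:(ny - 1L), each = nx), times = nz)
  ck <- rep(0:(nz - 1L), each = nx * ny)
  nc <- length(ci)
  if (is.null(flip_u)) flip_u <- rep(FALSE, nc)
  if (is.null(flip_v)) flip_v <- rep(FALSE, nc)
  fu <- as.integer(flip_u); fv <- as.integer(flip_v)
  corner <- function(du, dv, dw)
    idx(ci + ifelse(fu == 1L, 1L - du, du),
        cj + ifelse(fv == 1L, 1L - dv, dv),
        ck + dw)
  v000 <- corner(0L, 0L, 0L); v100 <- corner(1L, 0L, 0L)
  v010 <- corner(0L, 1L, 0L); v110 <- corner(1L, 1L, 0L)
  v001 <- corner(0L, 0L, 1L); v101 <- corner(1L, 0L, 1L)
  v011 <- corner(0L, 1L, 1L); v111 <- corner(1L, 1L, 1L)
  # six tets around the v000-v111 diagonal; conforming across cells
  tets <- rbind(
    cbind(v000, v100, v110, v111),
    cbind(v000, v110, v010, v111),
    cbind(v000, v010, v011, v111),
    cbind(v000, v011, v001, v111),
    cbind(v000, v001, v101, v111),
    cbind(v000, v101, v100, v111))
  list(nodes = nodes, tets = tets,
       cell_index = cbind(ci, cj, ck))
}

#' Total or per-region mesh volume
#'
#' Sums (deformed, if a displacement is given) element volumes over one tissue
#' region or the whole mesh. The deformed volume uses mapped coordinates
#' `X + u`.
#'
#' @param mesh a [labeled_mesh()].
#' @param region a region label, or `NULL` for the whole mesh.
#' @param displacement optional nodal displacement matrix (nodes x 3, metres).
#' @return volume in cubic metres.
#' @export
region_volume <- function(mesh, region = NULL, displacement = NULL) {
  v <- tet_volumes(mesh, displacement)
  if (is.null(region)) return(sum(v))
  if (!region %in% REGION_LEVELS)
    stop("unknown region: ", region, call. = FALSE)
  sum(v[mesh$tet_region == region])
}

# element centroids (reference configuration)
tet_centroids <- function(mesh) {
  (mesh$nodes[mesh$tets[, 1L], ] + mesh$nodes[mesh$tets[, 2L], ] +
   mesh$nodes[mesh$tets[, 3L], ] + mesh$nodes[mesh$tets[, 4L], ]) / 4
}

# per-node flag: TRUE when every incident tet is wound-labelled
wound_nodes <- function(mesh) {
  wtet <- mesh$tet_region == "wound"
  touch_w <- rep(FALSE, nrow(mesh$nodes))
  touch_h <- rep(FALSE, nrow(mesh$nodes))
  iw <- unique(as.vector(mesh$tets[wtet, , drop = FALSE]))
  ih <- unique(as.vector(mesh$tets[!wtet, , drop = FALSE]))
  touch_w[iw] <- TRUE
  touch_h[ih] <- TRUE
  touch_w & !touch_h
}

# per-node flag: touches at least one wound element (wound + interface nodes)
wound_touching_nodes <- function(mesh) {
  wtet <- mesh$tet_region == "wound"
  out <- rep(FALSE, nrow(mesh$nodes))
  out[unique(as.vector(mesh$tets[wtet, , drop = FALSE]))] <- TRUE
  out
}
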