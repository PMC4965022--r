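# Shared fixtures: small meshes, MSH file builders and the (cached)
# desk-preset healing run used by the acceptance suite.

.fixture_cache <- new.env(parent = emptyenv())

# coarse phantom with a cylindrical wound, small enough for fast tests
tiny_wounded_phantom <- function(edge = 0.015, seed = 7L) {
  key <- paste0("tiny_", edge, "_", seed)
  if (is.null(.fixture_cache[[key]])) {
    ph <- generate_phantom(0.06, 0.02, edge, fibro_fraction = 0.25,
                           seed = seed)
    plan <- resection_plan(c(0.018, 0, 0), c(0, 1, 0), 0.02)
    .fixture_cache[[key]] <- mark_resection(ph, plan)
  }
  .fixture_cache[[key]]
}

# the desk-preset coupled run (shared by the acceptance criteria)
desk_run <- function() {
  if (is.null(.fixture_cache$desk)) {
    cfg <- load_config(system.file("extdata", "desk.yaml",
                                   package = "bctsim"), quiet = TRUE)
    .fixture_cache$desk <- run_scenario(cfg, quiet = TRUE)
  }
  .fixture_cache$desk
}

# a box mesh with the bottom face constrained as chest
supported_box <- function(n = 3L, L = 0.02) {
  m <- box_mesh(n, n, n, L, L, L)
  fc <- (m$nodes[m$boundary_tris[, 1L], ] + m$nodes[m$boundary_tris[, 2L], ] +
         m$nodes[m$boundary_tris[, 3L], ]) / 3
  m$tri_patch[fc[, 2L] < 1e-12] <- "chest"
  m
}

# write a one-tet MSH v2.2 fixture; returns the path
write_single_tet_msh22 <- function(path, tag = 1L) {
  writeLines(c(
    "$MeshFormat", "2.2 0 8", "$EndMeshFormat",
    "$Nodes", "4",
    "1 0 0 0", "2 1 0 0", "3 0 1 0", "4 0 0 1",
    "$EndNodes",
    "$Elements", "1",
    paste("1 4 2", tag, tag, "1 2 3 4"),
    "$EndElements"), path)
  path
}

# structured cube mesh written as MSH v2.2 with one physical volume tag
write_cube_msh22 <- function(path, n = 3L, edge = 1, tag = 5L) {
  m <- box_mesh(n, n, n, edge, edge, edge)
  lines <- c("$MeshFormat", "2.2 0 8", "$EndMeshFormat",
             "$Nodes", as.character(nrow(m$nodes)),
             sprintf("%d %.17g %.17g %.17g", seq_len(nrow(m$nodes)),
                     m$nodes[, 1], m$nodes[, 2], m$nodes[, 3]),
             "$EndNodes",
             "$Elements", as.character(nrow(m$tets)),
             sprintf("%d 4 2 %d %d %d %d %d %d", seq_len(nrow(m$tets)),
                     tag, tag, m$tets[, 1], m$tets[, 2], m$tets[, 3],
                     m$tets[, 4]),
             "$EndElements")
  writeLines(lines, path)
  path
}

# same single tet as MSH v4.1
write_single_tet_msh41 <- function(path, tag = 9L) {
  writeLines(c(
    "$MeshFormat", "4.1 0 8", "$EndMeshFormat",
    "$Entities", "0 0 0 1",
    paste("1 0 0 0 1 1 1 1", tag),
    "$EndEntities",
    "$Nodes", "1 4 1 4",
    "3 1 0 4",
    "1", "2", "3", "4",
    "0 0 0", "1 0 0", "0 1 0", "0 0 1",
    "$EndNodes",
    "$Elements", "1 1 1 1",
    "3 1 4 1",
    "1 1 2 3 4",
    "$EndElements"), path)
  path
}

# random rigid transform with a given rotation angle (radians)
rigid_transform <- function(angle, axis = c(0, 0, 1), shift = c(0, 0, 0)) {
  axis <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, axis[3], -axis[2],
                -axis[3], 0, axis[1],
                axis[2], -axis[1], 0), 3, 3)
  R <- diag(3) + sin(angle) * K + (1 - cos(angle)) * K %*% K
  list(R = R, t = shift)
}
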