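test_that("MSH readers recover geometry and labels", {
  p22 <- write_single_tet_msh22(withr::local_tempfile(fileext = ".msh"),
                                tag = 1L)
  m <- read_mesh(p22, region_map = c(`1` = "adipose"), patch_map = c())
  expect_equal(nrow(m$tets), 1L)
  expect_equal(tet_volumes(m), 1 / 6)        # unit right tet

  # millimetre-scale file with a unit conversion
  m_mm <- read_mesh(p22, region_map = c(`1` = "adipose"), patch_map = c(),
                    scale = 1e-3)
  expect_equal(tet_volumes(m_mm), 1e-9 / 6)

  p41 <- write_single_tet_msh41(withr::local_tempfile(fileext = ".msh"),
                                tag = 9L)
  m41 <- read_mesh(p41, region_map = c(`9` = "fibroglandular"),
                   patch_map = c())
  expect_equal(m41$tet_region, "fibroglandular")
  expect_equal(m41$nodes, m$nodes)
  expect_equal(tet_volumes(m41), 1 / 6)

  # structured cube tessellates exactly
  pc <- write_cube_msh22(withr::local_tempfile(fileext = ".msh"),
                         n = 3L, edge = 2, tag = 5L)
  mc <- read_mesh(pc, region_map = c(`5` = "adipose"), patch_map = c())
  expect_equal(region_volume(mc), 8, tolerance = 1e-12)

  # unmapped physical tag is a labelling error
  expect_error(read_mesh(pc, region_map = c(`4` = "adipose"),
                         patch_map = c()),
               "labelling error")
})

test_that("phantom generator hits target geometry and is deterministic", {
  ph <- generate_phantom(0.06, 0.02, 0.012, fibro_fraction = 0.25, seed = 3L)
  expect_s3_class(ph, "labeled_mesh")
  expect_true(validate_mesh(ph))

  # hemisphere volume within 5% of (2/3) pi r^3
  cen <- tet_centroids(ph)
  vh <- sum(tet_volumes(ph)[cen[, 2L] > 0])
  expect_equal(vh, 2 / 3 * pi * 0.06^3, tolerance = 0.05)

  # fibroglandular share of the breast volume near the requested fraction
  fib <- region_volume(ph, "fibroglandular")
  expect_lt(abs(fib / vh - 0.25), 0.10)

  # bitwise determinism in the seed
  ph2 <- generate_phantom(0.06, 0.02, 0.012, fibro_fraction = 0.25,
                          seed = 3L)
  expect_identical(ph$nodes, ph2$nodes)
  ph3 <- generate_phantom(0.06, 0.02, 0.012, fibro_fraction = 0.25,
                          seed = 4L)
  expect_false(identical(ph$nodes, ph3$nodes))

  # all five patches present; chest is the slab base
  expect_setequal(unique(ph$tri_patch),
                  c("skin", "chest", "clip_inferior", "clip_superior",
                    "lateral"))
})

test_that("phantom boundary-patch areas are stable under refinement", {
  area_of <- function(mesh, patch) {
    tris <- mesh$boundary_tris[mesh$tri_patch == patch, , drop = FALSE]
    sum(vapply(seq_len(nrow(tris)), function(i) {
      a <- mesh$nodes[tris[i, 1L], ]; b <- mesh$nodes[tris[i, 2L], ]
      c_ <- mesh$nodes[tris[i, 3L], ]
      n <- c((b - a)[2] * (c_ - a)[3] - (b - a)[3] * (c_ - a)[2],
             (b - a)[3] * (c_ - a)[1] - (b - a)[1] * (c_ - a)[3],
             (b - a)[1] * (c_ - a)[2] - (b - a)[2] * (c_ - a)[1])
      sqrt(sum(n^2)) / 2
    }, 0))
  }
  coarse <- generate_phantom(0.06, 0.02, 0.015, seed = 1L, jitter = 0)
  fine <- generate_phantom(0.06, 0.02, 0.0075, seed = 1L, jitter = 0)
  for (patch in c("chest", "clip_superior", "lateral")) {
    expect_equal(area_of(coarse, patch), area_of(fine, patch),
                 tolerance = 0.02)
  }
  # the faceted dome underestimates the smooth sphere; refinement converges
  a_skin_c <- area_of(coarse, "skin")
  a_skin_f <- area_of(fine, "skin")
  expect_equal(a_skin_c, a_skin_f, tolerance = 0.02)
})

test_that("cylindrical resection marks exactly the enclosed centroids", {
  m <- box_mesh(4L, 4L, 4L, 1, 1, 1)
  # cylinder through the centre along y
  plan <- resection_plan(c(0.5, 0, 0.5), c(0, 1, 0), 0.25)
  mw <- mark_resection(m, plan)
  # independent brute-force centroid-in-cylinder scan
  cen <- tet_centroids(m)
  d <- cbind(cen[, 1L] - 0.5, cen[, 3L] - 0.5)
  expected <- rowSums(d^2) <= 0.25^2
  expect_identical(mw$tet_region == "wound", unname(expected))
  expect_gt(sum(expected), 0)

  # input mesh untouched; marking is idempotent
  expect_true(all(m$tet_region == "adipose"))
  expect_identical(mark_resection(mw, plan)$tet_region, mw$tet_region)

  # enclosing cylinder takes everything
  all_in <- mark_resection(m, resection_plan(c(0.5, 0, 0.5), c(0, 1, 0), 2))
  expect_true(all(all_in$tet_region == "wound"))

  # a plan that misses the mesh is a resection error, radius 0 is invalid
  expect_error(resection_plan(c(0, 0, 0), c(0, 1, 0), 0), "radius")
  expect_error(mark_resection(m, resection_plan(c(10, 0, 0), c(0, 1, 0),
                                                0.1)),
               "resection error")
})

test_that("region volumes integrate deformed configurations exactly", {
  m <- box_mesh(3L, 3L, 3L, 1, 1, 1)
  expect_equal(region_volume(m), 1, tolerance = 1e-14)
  expect_equal(region_volume(m, "adipose"), 1, tolerance = 1e-14)

  # uniform stretch x2 along y doubles the volume
  u <- cbind(0 * m$nodes[, 1L], m$nodes[, 2L], 0 * m$nodes[, 3L])
  expect_equal(region_volume(m, displacement = u), 2, tolerance = 1e-12)

  # random small displacement vs per-element det(F) Jacobian oracle
  set.seed(11)
  u <- matrix(rnorm(length(m$nodes), 0, 5e-3), ncol = 3L)
  geo <- bctsim:::element_gradients(m$nodes, m$tets)
  F_ <- bctsim:::def_gradients(u, m$tets, geo$grads)
  detF <- bctsim:::kinematics(F_)$J
  expect_equal(region_volume(m, displacement = u),
               sum(geo$vol * detF), tolerance = 1e-10)

  # partition of volume across regions
  ph <- tiny_wounded_phantom()
  tot <- region_volume(ph)
  parts <- sum(vapply(c("adipose", "fibroglandular", "wound"),
                      function(r) region_volume(ph, r), 0))
  expect_equal(parts, tot, tolerance = 1e-12)
})

test_that("mesh invariants are enforced", {
  # degenerate tet rejected
  nodes <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(1, 1, 0))
  expect_error(labeled_mesh(nodes, matrix(1:4, 1), "adipose"),
               "degenerate")
  # inconsistent boundary triangulation rejected
  m <- box_mesh(2L, 2L, 2L, 1, 1, 1)
  bad <- m
  bad$boundary_tris <- bad$boundary_tris[-1, , drop = FALSE]
  bad$tri_patch <- bad$tri_patch[-1]
  expect_error(validate_mesh(bad), "boundary")
  # negative orientation is repaired on construction
  t2 <- m$tets
  t2[, c(1L, 2L)] <- t2[, c(2L, 1L)]
  m2 <- labeled_mesh(m$nodes, t2, m$tet_region, m$boundary_tris,
                     m$tri_patch)
  expect_true(all(tet_volumes(m2) > 0))
})
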