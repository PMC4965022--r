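# Virtual resection: cylindrical excision volumes, the conventional
# lumpectomy geometry (cylinder axis perpendicular to the chest wall,
# extending from the skin to the fascia). Resected elements are relabelled
# as wound, never deleted: the damage formulation treats the wounded and the
# surrounding healthy tissue as two interfacing volumes on one mesh.

#' Cylindrical resection plan
#'
#' @param axis_point a point on the cylinder axis (metres), typically on the
#'   chest wall under the tumour.
#' @param axis_direction axis direction (normalised internally), typically
#'   the anterior chest-wall normal.
#' @param radius cylinder radius in metres.
#' @return object of class `resection_plan`.
#' @export
resection_plan <- function(axis_point, axis_direction, radius) {
  axis_point <- as.numeric(axis_point)
  axis_direction <- as.numeric(axis_direction)
  stopifnot(length(axis_point) == 3L, length(axis_direction) == 3L)
  if (!is.finite(radius) || radius <= 0)
    stop("resection radius must be positive", call. = FALSE)
  nrm <- sqrt(sum(axis_direction^2))
  if (nrm == 0) stop("axis direction must be non-zero", call. = FALSE)
  structure(list(axis_point = axis_point,
                 axis_direction = axis_direction / nrm,
                 radius = radius),
            class = "resection_plan")
}

#' @export
print.resection_plan <- function(x, ...) {
  cat(sprintf("<resection_plan> r = %.1f mm, axis (%.3f, %.3f, %.3f) + t(%.2f, %.2f, %.2f)\n",
              1e3 * x$radius, x$axis_point[1L], x$axis_point[2L],
              x$axis_point[3L], x$axis_direction[1L], x$axis_direction[2L],
              x$axis_direction[3L]))
  invisible(x)
}

#' Mark resected elements as wound
#'
#' Relabels every tetrahedron whose centroid lies inside the (infinite)
#' resection cylinder as `"wound"`. Membership is decided by the element
#' centroid, the skin shell is left untouched (no skin is resected), and the
#' input mesh is not modified. Marking is idempotent.
#'
#' @param mesh a [labeled_mesh()].
#' @param plan a [resection_plan()].
#' @return a new [labeled_mesh()] with wound labels applied.
#' @export
mark_resection <- function(mesh, plan) {
  stopifnot(inherits(plan, "resection_plan"))
  cen <- tet_centroids(mesh)
  d <- sweep(cen, 2L, plan$axis_point)
  along <- d %*% plan$axis_direction
  radial2 <- rowSums(d^2) - as.vector(along)^2
  inside <- radial2 <= plan$radius^2
  if (!any(inside))
    stop("resection error: the planned cylinder does not intersect the mesh",
         call. = FALSE)
  out <- mesh
  out$tet_region[inside] <- "wound"
  out
}
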