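# Cosmetic-outcome evaluation: rigid alignment of two breast surfaces by
# iterative closest point (ICP) and surface-distance statistics between the
# simulated prediction and a follow-up acquisition.

#' Rigid alignment by iterative closest point
#'
#' Point-to-point ICP: each iteration matches every source vertex to its
#' nearest target vertex, then solves the least-squares rigid transform
#' (SVD/Kabsch) for the matched pairs. The mean squared matched distance is
#' non-increasing over iterations on fixed correspondences.
#'
#' @param source,target [tri_surface()] objects (or vertex matrices).
#' @param max_iter iteration cap.
#' @param tol stop when the RMS matched distance improves by less than
#'   `tol` (m) between iterations.
#' @return list with `R` (3x3 rotation), `t` (translation), `errors`
#'   (per-iteration RMS distance, m) and `aligned` (transformed source
#'   vertices).
#' @export
icp_rigid <- function(source, target, max_iter = 50L, tol = 1e-9) {
  src <- if (inherits(source, "tri_surface")) source$vertices
         else as.matrix(source)
  tgt <- if (inherits(target, "tri_surface")) target$vertices
         else as.matrix(target)
  if (!nrow(src) || !nrow(tgt))
    stop("alignment error: empty surface", call. = FALSE)
  R_tot <- diag(3L)
  t_tot <- c(0, 0, 0)
  cur <- src
  errors <- numeric(0)
  for (it in seq_len(max_iter)) {
    nn_idx <- nearest_vertex(cur, tgt)
    q <- tgt[nn_idx, , drop = FALSE]
    e <- sqrt(mean(rowSums((cur - q)^2)))
    # Kabsch: rigid transform minimising ||R p + t - q||^2
    mp <- colMeans(cur); mq <- colMeans(q)
    H <- crossprod(sweep(cur, 2L, mp), sweep(q, 2L, mq))
    sv <- svd(H)
    d <- sign(det(sv$v %*% t(sv$u)))
    Rk <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
    tk <- mq - as.vector(Rk %*% mp)
    cur <- sweep(cur %*% t(Rk), 2L, tk, "+")
    R_tot <- Rk %*% R_tot
    t_tot <- as.vector(Rk %*% t_tot) + tk
    errors <- c(errors, e)
    if (it > 1L && abs(errors[it - 1L] - e) < tol) break
  }
  list(R = R_tot, t = t_tot, errors = errors, aligned = cur)
}

# nearest target vertex for each query point (blocked for memory)
nearest_vertex <- function(p, q, block = 512L) {
  n <- nrow(p)
  out <- integer(n)
  q2 <- rowSums(q^2)
  for (s in seq(1L, n, by = block)) {
    e <- min(n, s + block - 1L)
    pb <- p[s:e, , drop = FALSE]
    d2 <- outer(rowSums(pb^2), q2, "+") - 2 * pb %*% t(q)
    out[s:e] <- max.col(-d2, ties.method = "first")
  }
  out
}

#' Surface distance statistics
#'
#' For every vertex of `a`, the exact point-to-triangle distance to surface
#' `b` (asymmetric, simulation-to-follow-up by convention; set
#' `symmetric = TRUE` to average both directions). Percentiles use linear
#' interpolation between order statistics.
#'
#' @param a,b [tri_surface()] objects.
#' @param symmetric also measure b-to-a and pool the distances.
#' @return list with `distances` (per-vertex, m) and `stats` (named vector:
#'   mean, std, p50, p90, p95, in the same units as the vertices).
#' @export
surface_distance <- function(a, b, symmetric = FALSE) {
  stopifnot(inherits(a, "tri_surface"), inherits(b, "tri_surface"))
  if (!nrow(a$vertices) || !nrow(b$faces))
    stop("empty mesh in surface_distance", call. = FALSE)
  d <- point_surface_distance(a$vertices, b)
  if (symmetric) d <- c(d, point_surface_distance(b$vertices, a))
  stats <- c(mean = mean(d), std = stats::sd(d),
             stats::quantile(d, c(0.5, 0.9, 0.95), names = FALSE))
  names(stats) <- c("mean", "std", "p50", "p90", "p95")
  list(distances = d, stats = stats)
}

# exact point-to-triangle-mesh distances: nearest-vertex upper bound first,
# then exact point-triangle distance on the surviving candidate triangles
point_surface_distance <- function(p, surf) {
  v <- surf$vertices
  f <- surf$faces
  n <- nrow(p)
  A <- v[f[, 1L], , drop = FALSE]
  B <- v[f[, 2L], , drop = FALSE]
  C <- v[f[, 3L], , drop = FALSE]
  cen <- (A + B + C) / 3
  rad <- sqrt(pmax(rowSums((A - cen)^2), rowSums((B - cen)^2),
                   rowSums((C - cen)^2)))
  out <- numeric(n)
  ub_idx <- nearest_vertex(p, v)
  ub <- sqrt(rowSums((p - v[ub_idx, , drop = FALSE])^2))
  for (i in seq_len(n)) {
    # lower bound per triangle: |p - centroid| - circumradius bound
    dcen <- sqrt(rowSums(sweep(cen, 2L, p[i, ])^2))
    cand <- which(dcen - rad <= ub[i] + 1e-15)
    d2 <- point_triangle_dist2(p[i, ], A[cand, , drop = FALSE],
                               B[cand, , drop = FALSE],
                               C[cand, , drop = FALSE])
    out[i] <- sqrt(min(d2))
  }
  out
}

# squared distances from one point to many triangles (vectorised Eberly
# region classification)
point_triangle_dist2 <- function(p, A, B, C) {
  E0 <- B - A
  E1 <- C - A
  D <- sweep(A, 2L, p)
  a <- rowSums(E0 * E0)
  b <- rowSums(E0 * E1)
  c_ <- rowSums(E1 * E1)
  d <- rowSums(E0 * D)
  e <- rowSums(E1 * D)
  det <- pmax(a * c_ - b * b, .Machine$double.xmin)
  s <- b * e - c_ * d
  t <- b * d - a * e
  # clamp barycentric solution to the triangle (all regions at once)
  inside <- s + t <= det & s >= 0 & t >= 0
  s_in <- s / det; t_in <- t / det
  # edge/vertex projections
  clamp01 <- function(x) pmin(1, pmax(0, x))
  # edge AB (t = 0)
  s_ab <- clamp01(-d / pmax(a, .Machine$double.xmin))
  d_ab <- a * s_ab^2 + 2 * d * s_ab + rowSums(D * D)
  # edge AC (s = 0)
  t_ac <- clamp01(-e / pmax(c_, .Machine$double.xmin))
  d_ac <- c_ * t_ac^2 + 2 * e * t_ac + rowSums(D * D)
  # edge BC (s + t = 1): parametrise s = 1 - w, t = w
  num <- c_ + e - b - d
  den <- a - 2 * b + c_
  w <- clamp01(num / pmax(den, .Machine$double.xmin))
  s_bc <- 1 - w; t_bc <- w
  d_bc <- a * s_bc^2 + 2 * b * s_bc * t_bc + c_ * t_bc^2 +
    2 * d * s_bc + 2 * e * t_bc + rowSums(D * D)
  d_edge <- pmin(d_ab, d_ac, d_bc)
  d_in <- a * s_in^2 + 2 * b * s_in * t_in + c_ * t_in^2 +
    2 * d * s_in + 2 * e * t_in + rowSums(D * D)
  pmax(ifelse(inside, d_in, d_edge), 0)
}

#' Distance histogram between two surfaces
#'
#' Normalised frequency of occurrence of the surface distance, for
#' histogram-style reporting of the cosmetic evaluation.
#'
#' @param distances numeric distances (m).
#' @param breaks number of bins or break vector (in mm).
#' @return data.frame with `d_mm` (bin centre) and `n` (normalised
#'   frequency; sums to 1).
#' @export
distance_histogram <- function(distances, breaks = 20L) {
  h <- graphics::hist(distances * 1e3, breaks = breaks, plot = FALSE)
  data.frame(d_mm = h$mids, n = h$counts / sum(h$counts))
}
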