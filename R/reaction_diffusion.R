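# Explicit P1 finite-element solver for the five-species wound-healing and
# angiogenesis system on the fixed Lagrangian mesh:
#
#   eta_t     = D_eta Lap(eta) + K(xi) S(sigma) (2 eta0 eta - eta^2) - k eta
#   sigma_t   = D_sigma Lap(sigma) + ell_eta eta - ell sigma
#   upsilon_t = D_upsilon Lap(upsilon) + beta H(mu) (upsilon0 upsilon - upsilon^2)
#   xi_t      = D_xi Lap(xi) + lambda_upsilon upsilon - lambda xi
#   mu_t      = D_mu Lap(mu) + phi_xi Q(xi) - phi mu
#
# Zero-flux (natural) boundary conditions; forward-Euler time integration
# with nodal source evaluation and row-sum lumped mass.

#' Chemical control of cell mitosis
#'
#' Activator form `S = 2 h1 sigma_bar sigma / (sigma_bar^2 + sigma^2) + h2`.
#' The inhibitor form is reconstructed as
#' `S = ((h0 - 1) sigma + h0 sigma0) / (2 (h0 - 1) sigma + sigma0)`, which
#' satisfies the normalisation S(sigma0) = 1 and S(0) = h0. (The printed
#' inhibitor expression in the source material is typographically garbled;
#' this reconstruction restores the normalisation the activator branch obeys
#' and matches the Sherratt-Murray inhibition mechanism. The activator
#' branch is the one used by all default simulations.)
#'
#' @param sigma_c chemical concentration (vectorised).
#' @param params a [bio_params()].
#' @return dimensionless mitosis factor, `>= 0`.
#' @export
source_S <- function(sigma_c, params) {
  if (params$mitosis_mode == "activator") {
    den <- params$sigma_bar^2 + sigma_c^2
    ifelse(den > 0,
           2 * params$h1 * params$sigma_bar * sigma_c / den, 0) + params$h2
  } else {
    ((params$h0 - 1) * sigma_c + params$h0 * params$sigma0) /
      (2 * (params$h0 - 1) * sigma_c + params$sigma0)
  }
}

#' Angiogenic stimulation of capillary production
#'
#' `H(mu) = 3 mu / (2 mu0 + mu)`; ranges over `[0, 3)` and equals 1 at
#' `mu = mu0`.
#'
#' @param mu MDGF concentration (vectorised), `>= 0`.
#' @param params a [bio_params()].
#' @return dimensionless factor.
#' @export
source_H <- function(mu, params) {
  3 * mu / (2 * params$mu0 + mu)
}

#' Hypoxia-driven MDGF release
#'
#' `Q = 1 - xi / xi_hat` inside the wound while `xi < xi_hat`, zero
#' elsewhere: macrophages release MDGF only at hypoxic wound sites.
#'
#' @param xi normalised oxygen level (vectorised).
#' @param in_wound logical (vectorised): node lies in the wounded region.
#' @param params a [bio_params()].
#' @return dimensionless factor in `[0, 1]`.
#' @export
source_Q <- function(xi, in_wound, params) {
  ifelse(in_wound & xi < params$xi_hat, 1 - xi / params$xi_hat, 0)
}

#' Oxygen-limited cell production rate
#'
#' `K = k_sigma * xi / xi_tilde` for `xi < xi_tilde`, else `k_sigma`:
#' production ramps up linearly with oxygen below the threshold and then
#' saturates at the normal rate.
#'
#' @param xi normalised oxygen level (vectorised).
#' @param params a [bio_params()].
#' @return rate in m^3 cell^-1 s^-1.
#' @export
source_K <- function(xi, params) {
  ifelse(xi < params$xi_tilde, params$k_sigma * xi / params$xi_tilde,
         params$k_sigma)
}

#' Assemble P1 diffusion operators
#'
#' Builds the linear-tetrahedron Galerkin stiffness (Laplacian) matrix and
#' the row-sum lumped mass vector on the mesh. Natural boundary conditions
#' (zero flux) are implied. Also returns per-element shape-function
#' gradients and volumes for reuse by the mechanics assembler.
#'
#' @param mesh a [labeled_mesh()].
#' @return list with `K` (sparse stiffness), `M` (lumped mass vector, sums
#'   to the mesh volume), `grads` (elements x 4 x 3 gradient array), `vol`
#'   (element volumes).
#' @export
assemble_operators <- function(mesh) {
  geo <- element_gradients(mesh$nodes, mesh$tets)
  ne <- nrow(mesh$tets)
  g <- geo$grads
  v <- geo$vol
  if (any(!is.finite(g)) || any(v <= 0))
    stop("geometry error: degenerate element in operator assembly",
         call. = FALSE)
  # K_ab = vol * grad_a . grad_b, vectorised over elements
  ii <- jj <- xx <- vector("list", 16L)
  idx <- 1L
  for (a in 1:4) for (b in 1:4) {
    ii[[idx]] <- mesh$tets[, a]
    jj[[idx]] <- mesh$tets[, b]
    xx[[idx]] <- v * (g[, a, 1L] * g[, b, 1L] + g[, a, 2L] * g[, b, 2L] +
                      g[, a, 3L] * g[, b, 3L])
    idx <- idx + 1L
  }
  K <- Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                            dims = c(nrow(mesh$nodes), nrow(mesh$nodes)))
  M <- rep(0, nrow(mesh$nodes))
  vm <- rowsum(rep(v / 4, 4L), as.vector(mesh$tets))
  M[as.integer(rownames(vm))] <- vm
  list(K = K, M = M, grads = g, vol = v)
}

# constant P1 shape-function gradients and volumes for all elements
element_gradients <- function(nodes, tets) {
  a <- nodes[tets[, 1L], , drop = FALSE]
  b <- nodes[tets[, 2L], , drop = FALSE]
  c_ <- nodes[tets[, 3L], , drop = FALSE]
  d <- nodes[tets[, 4L], , drop = FALSE]
  e1 <- b - a; e2 <- c_ - a; e3 <- d - a
  cr <- function(u, v) cbind(u[, 2L] * v[, 3L] - u[, 3L] * v[, 2L],
                             u[, 3L] * v[, 1L] - u[, 1L] * v[, 3L],
                             u[, 1L] * v[, 2L] - u[, 2L] * v[, 1L])
  n1 <- cr(e2, e3)   # opposite node 2
  n2 <- cr(e3, e1)   # opposite node 3
  n3 <- cr(e1, e2)   # opposite node 4
  det6 <- rowSums(e1 * n1)          # 6 * volume
  vol <- det6 / 6
  ne <- nrow(tets)
  g <- array(0, c(ne, 4L, 3L))
  g[, 2L, ] <- n1 / det6
  g[, 3L, ] <- n2 / det6
  g[, 4L, ] <- n3 / det6
  g[, 1L, ] <- -(g[, 2L, ] + g[, 3L, ] + g[, 4L, ])
  list(grads = g, vol = vol)
}

#' Five-species nodal state
#'
#' @param eta,sigma_c,upsilon,xi,mu nodal fields.
#' @return object of class `species_state`.
#' @export
species_state <- function(eta, sigma_c, upsilon, xi, mu) {
  n <- length(eta)
  stopifnot(length(sigma_c) == n, length(upsilon) == n, length(xi) == n,
            length(mu) == n)
  structure(list(eta = eta, sigma_c = sigma_c, upsilon = upsilon,
                 xi = xi, mu = mu), class = "species_state")
}

#' @export
print.species_state <- function(x, ...) {
  cat("<species_state> ", length(x$eta), " nodes\n", sep = "")
  for (nm in c("eta", "sigma_c", "upsilon", "xi", "mu"))
    cat(sprintf("  %-8s [%.4g, %.4g]\n", nm, min(x[[nm]]), max(x[[nm]])))
  invisible(x)
}

#' Initial conditions of the healing simulation
#'
#' Wound nodes (all incident elements wound-labelled) start with zero cell
#' and capillary density and oxygen `xi_init_wound`; healthy and
#' wound/healthy-interface nodes start at the healthy state `eta0`,
#' `upsilon0`, `xi = 1`. Both growth factors (`sigma_c`, `mu`) start at zero
#' everywhere.
#'
#' @param mesh a [labeled_mesh()] (wound labels applied).
#' @param params a [bio_params()].
#' @return a [species_state()].
#' @export
initialize_state <- function(mesh, params) {
  n <- nrow(mesh$nodes)
  w <- wound_nodes(mesh)
  eta <- rep(params$eta0, n); eta[w] <- 0
  ups <- rep(params$upsilon0, n); ups[w] <- 0
  xi <- rep(1, n); xi[w] <- params$xi_init_wound
  species_state(eta, rep(0, n), ups, xi, rep(0, n))
}

#' Stability limit of the explicit diffusion step
#'
#' Edge-based Courant-Friedrichs-Lewy estimate
#' `dt = safety * min_e h_min(e)^2 / (2 d D_max)` with `d = 3` and `D_max`
#' the largest diffusivity; `h_min(e)` is the element's shortest edge.
#' Infinite when all diffusivities vanish (reaction-only; the caller must
#' cap the step).
#'
#' @param mesh a [labeled_mesh()].
#' @param params a [bio_params()].
#' @param safety safety factor in `(0, 1]`.
#' @return admissible time step in seconds.
#' @export
cfl_max_dt <- function(mesh, params, safety = 0.5) {
  stopifnot(safety > 0, safety <= 1)
  Dmax <- max(params$D_eta, params$D_sigma, params$D_xi, params$D_mu,
              params$D_upsilon)
  if (Dmax == 0) return(Inf)
  t <- mesh$tets
  n <- mesh$nodes
  pairs <- list(c(1L, 2L), c(1L, 3L), c(1L, 4L), c(2L, 3L), c(2L, 4L),
                c(3L, 4L))
  h2 <- Inf
  for (p in pairs) {
    d2 <- rowSums((n[t[, p[1L]], , drop = FALSE] -
                   n[t[, p[2L]], , drop = FALSE])^2)
    h2 <- pmin(h2, d2)
  }
  safety * min(h2) / (2 * 3 * Dmax)
}

# spectral stability bound for the assembled lumped-mass diffusion operator:
# forward Euler is stable for dt < 2 / lambda_max(D_max M^-1 K); Gershgorin
# gives lambda_max <= max_i sum_j |K_ij| / M_i. Sliver elements can make the
# edge-based CFL estimate optimistic, so runs take the minimum of both.
stable_dt_operator <- function(ops, params, safety = 0.5) {
  Dmax <- max(params$D_eta, params$D_sigma, params$D_xi, params$D_mu,
              params$D_upsilon)
  if (Dmax == 0) return(Inf)
  rs <- Matrix::rowSums(abs(ops$K))
  lam <- max(rs / ops$M)
  safety * 2 / (Dmax * lam)
}

# nodal source terms of the five equations (shared by step and oracles)
species_sources <- function(state, params, wound_flag) {
  K_xi <- source_K(state$xi, params)
  S_sg <- source_S(state$sigma_c, params)
  H_mu <- source_H(state$mu, params)
  Q_xi <- source_Q(state$xi, wound_flag, params)
  list(
    eta = K_xi * S_sg * (2 * params$eta0 * state$eta - state$eta^2) -
      params$k * state$eta,
    sigma_c = params$ell_eta * state$eta - params$ell * state$sigma_c,
    upsilon = params$beta * H_mu *
      (params$upsilon0 * state$upsilon - state$upsilon^2),
    xi = params$lambda_upsilon * state$upsilon - params$lambda * state$xi,
    mu = params$phi_xi * Q_xi - params$phi * state$mu)
}

#' One forward-Euler step of the five-species system
#'
#' Updates all species by `dt` with nodal sources and lumped-mass P1
#' diffusion. The capillary equation uses the (small, possibly zero)
#' `D_upsilon`; the cell equation uses the oxygen-limited production rate
#' `K(xi) S(sigma)` in place of the plain `k_sigma S(sigma)`.
#'
#' @param state a [species_state()].
#' @param dt time step (s); must respect [cfl_max_dt()].
#' @param operators output of [assemble_operators()].
#' @param mesh a [labeled_mesh()].
#' @param params a [bio_params()].
#' @param wound_flag optional precomputed logical of wound nodes (all
#'   incident elements wound); computed from the mesh when missing.
#' @return the advanced [species_state()].
#' @export
explicit_step <- function(state, dt, operators, mesh, params,
                          wound_flag = NULL) {
  if (is.null(wound_flag)) wound_flag <- wound_touching_nodes(mesh)
  src <- species_sources(state, params, wound_flag)
  Minv <- 1 / operators$M
  diff_of <- function(field, D) {
    if (D == 0) return(0)
    -D * Minv * as.vector(operators$K %*% field)
  }
  # all species are non-negative quantities; the P1 Galerkin Laplacian on
  # tetrahedra is not an M-matrix, so sharp fronts can undershoot zero and
  # the quadratic logistic terms would then run away. A projection onto the
  # positive cone after the update preserves the physics and the scheme's
  # order (inactive for smooth non-negative fields).
  out <- species_state(
    pmax(0, state$eta + dt * (diff_of(state$eta, params$D_eta) + src$eta)),
    pmax(0, state$sigma_c + dt * (diff_of(state$sigma_c, params$D_sigma) +
                                    src$sigma_c)),
    pmax(0, state$upsilon + dt * (diff_of(state$upsilon, params$D_upsilon) +
                                    src$upsilon)),
    pmax(0, state$xi + dt * (diff_of(state$xi, params$D_xi) + src$xi)),
    pmax(0, state$mu + dt * (diff_of(state$mu, params$D_mu) + src$mu)))
  for (nm in c("eta", "sigma_c", "upsilon", "xi", "mu"))
    if (any(!is.finite(out[[nm]])))
      stop("divergence error: non-finite values in species ", nm,
           " (reduce dt)", call. = FALSE)
  out
}

#' Run the healing simulation to a time horizon
#'
#' Repeated [explicit_step()] to `t_end`. The final partial step is
#' shortened so the horizon is hit exactly. Observers receive
#' `(time, state)` at every requested sample time and their results are
#' collected into the returned time series.
#'
#' @param state initial [species_state()].
#' @param mesh a [labeled_mesh()].
#' @param params a [bio_params()].
#' @param t_end horizon in seconds.
#' @param dt time step in seconds; capped at the operator stability bound.
#' @param sample_every sampling interval for the time series (s); default
#'   records ~50 samples.
#' @param operators optional precomputed [assemble_operators()] output.
#' @param interface_dirichlet hold wound/healthy-interface nodes at their
#'   healthy values throughout the run (hard clamp) instead of only setting
#'   them as initial conditions (default `FALSE`).
#' @return list with `state` (final), `series` (data.frame: time_s,
#'   wound_mean_eta, wound_mean_upsilon, wound_mean_xi, all normalised by
#'   their healthy reference values).
#' @export
run_healing <- function(state, mesh, params, t_end, dt,
                        sample_every = NULL, operators = NULL,
                        interface_dirichlet = FALSE) {
  if (is.null(operators)) operators <- assemble_operators(mesh)
  if (t_end < 0) stop("t_end must be >= 0", call. = FALSE)
  dt_stab <- min(stable_dt_operator(operators, params, 1),
                 1 / max(params$k, params$ell, params$lambda, params$phi))
  if (dt > dt_stab) dt <- dt_stab
  wflag <- wound_touching_nodes(mesh)
  iface <- if (interface_dirichlet) which(wflag & !wound_nodes(mesh))
           else integer(0)
  clamp_iface <- function(s) {
    if (!length(iface)) return(s)
    s$eta[iface] <- params$eta0
    s$upsilon[iface] <- params$upsilon0
    s$xi[iface] <- 1
    s
  }
  welt <- mesh$tet_region == "wound"
  wvol <- operators$vol[welt]
  sample_state <- function(t, s) {
    wm <- function(f) {
      if (!any(welt)) return(NA_real_)
      fe <- (f[mesh$tets[welt, 1L]] + f[mesh$tets[welt, 2L]] +
             f[mesh$tets[welt, 3L]] + f[mesh$tets[welt, 4L]]) / 4
      sum(fe * wvol) / sum(wvol)
    }
    c(time_s = t, wound_mean_eta = wm(s$eta) / params$eta0,
      wound_mean_upsilon = wm(s$upsilon) / params$upsilon0,
      wound_mean_xi = wm(s$xi))
  }
  if (is.null(sample_every)) sample_every <- max(t_end / 50, dt)
  rows <- list(sample_state(0, state))
  t <- 0
  next_sample <- sample_every
  while (t < t_end - 1e-9 * max(t_end, 1)) {
    step <- min(dt, t_end - t)
    state <- clamp_iface(explicit_step(state, step, operators, mesh, params,
                                       wflag))
    t <- t + step
    if (t >= next_sample - 1e-9 * sample_every || t >= t_end) {
      rows[[length(rows) + 1L]] <- sample_state(t, state)
      next_sample <- next_sample + sample_every
    }
  }
  series <- as.data.frame(do.call(rbind, rows))
  list(state = state, series = series)
}
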