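test_that("mitosis, angiogenesis and hypoxia source functions match their closed forms", {
  p <- bio_params(quiet = TRUE)

  # activator S: limits and half-saturation identities
  expect_equal(source_S(0, p), p$h2)
  expect_equal(source_S(p$sigma_bar, p), p$h1 + p$h2)
  expect_equal(source_S(1e12 * p$sigma_bar, p), p$h2, tolerance = 1e-10)
  # homeostasis normalisation: S(sigma0) = 1 with the default h1 + h2 = 1
  expect_equal(source_S(p$sigma0, p), 1)

  # inhibitor branch: normalised at sigma0, h0 at zero, decreasing
  pi_ <- bio_params(mitosis_mode = "inhibitor", quiet = TRUE)
  expect_equal(source_S(pi_$sigma0, pi_), 1)
  expect_equal(source_S(0, pi_), pi_$h0)
  expect_lt(source_S(10 * pi_$sigma0, pi_), source_S(pi_$sigma0, pi_))

  # H(mu) = 3mu/(2mu0 + mu)
  expect_equal(source_H(0, p), 0)
  expect_equal(source_H(p$mu0, p), 1)
  expect_equal(source_H(4 * p$mu0, p), 2)   # 12/6 by direct evaluation

  # Q: hypoxia-gated and wound-gated
  expect_equal(source_Q(0, TRUE, p), 1)
  expect_equal(source_Q(p$xi_hat, TRUE, p), 0)
  expect_equal(source_Q(p$xi_hat / 2, TRUE, p), 0.5)
  expect_equal(source_Q(0.1, FALSE, p), 0)

  # K: linear ramp below xi_tilde, saturated above, continuous at the knee
  expect_equal(source_K(0, p), 0)
  expect_equal(source_K(p$xi_tilde, p), p$k_sigma)
  expect_equal(source_K(p$xi_tilde / 2, p), p$k_sigma / 2)
  expect_equal(source_K(1, p), p$k_sigma)
})

test_that("P1 operators have the discrete Laplacian properties", {
  m <- box_mesh(4L, 4L, 4L, 0.02, 0.02, 0.02)
  ops <- assemble_operators(m)
  n <- nrow(m$nodes)
  # Laplacian of a constant vanishes
  expect_lt(max(abs(ops$K %*% rep(3.7, n))), 1e-12)
  # lumped mass partitions the volume
  expect_equal(sum(ops$M), region_volume(m), tolerance = 1e-12)
  expect_true(all(ops$M > 0))
  # Galerkin Laplacian of a linear field: interior rows vanish
  # (P1 exactness), which is the structured-mesh finite-difference result
  f <- 2 * m$nodes[, 1L] - m$nodes[, 3L]
  lap <- as.vector(ops$K %*% f)
  interior <- setdiff(seq_len(n),
                      unique(as.vector(m$boundary_tris)))
  expect_lt(max(abs(lap[interior])), 1e-12 * max(abs(lap)))
  # quadratic field: lumped-mass Laplacian approaches the constant exact
  # value in the interior of a structured mesh
  f2 <- m$nodes[, 1L]^2
  lap2 <- -as.vector(ops$K %*% f2) / ops$M
  expect_equal(mean(lap2[interior]), 2, tolerance = 0.05)
})

test_that("initial state classifies wound, interface and healthy nodes", {
  p <- bio_params(quiet = TRUE)
  mw <- tiny_wounded_phantom()
  st <- initialize_state(mw, p)

  # brute-force per-node incident-region scan
  n <- nrow(mw$nodes)
  wound_only <- healthy_any <- rep(FALSE, n)
  for (e in seq_len(nrow(mw$tets))) {
    nodes_e <- mw$tets[e, ]
    if (mw$tet_region[e] == "wound") wound_only[nodes_e] <- TRUE
    else healthy_any[nodes_e] <- TRUE
  }
  w <- wound_only & !healthy_any
  expect_identical(st$eta == 0, w)
  expect_identical(st$upsilon == 0, w)
  expect_true(all(st$xi[w] == p$xi_init_wound))
  expect_true(all(st$eta[!w] == p$eta0))
  expect_true(all(st$xi[!w] == 1))
  # both growth factors start at zero everywhere
  expect_true(all(st$sigma_c == 0) && all(st$mu == 0))

  # no wound labels: uniform healthy state
  ph <- box_mesh(2L, 2L, 2L, 1, 1, 1)
  st0 <- initialize_state(ph, p)
  expect_true(all(st0$eta == p$eta0) && all(st0$xi == 1))
})

test_that("explicit step respects the CFL bound and its scalings", {
  m <- box_mesh(3L, 3L, 3L, 3e-3, 3e-3, 3e-3)   # h = 1 mm
  p0 <- bio_params(D_eta = 0, D_sigma = 0, D_xi = 0, D_mu = 0,
                   D_upsilon = 0, quiet = TRUE)
  expect_identical(cfl_max_dt(m, p0), Inf)

  p1 <- bio_params(D_eta = 1e-9, D_sigma = 0, D_xi = 0, D_mu = 0,
                   D_upsilon = 0, quiet = TRUE)
  # dt = h^2 / (6 D) with h = 1e-3, D = 1e-9 -> 166.7 s
  expect_equal(cfl_max_dt(m, p1, safety = 1), 1e-6 / 6e-9,
               tolerance = 1e-12)
  p2 <- bio_params(D_eta = 2e-9, D_sigma = 0, D_xi = 0, D_mu = 0,
                   D_upsilon = 0, quiet = TRUE)
  expect_equal(cfl_max_dt(m, p2, safety = 1),
               cfl_max_dt(m, p1, safety = 1) / 2)
})

test_that("healthy equilibrium is a numerical fixed point", {
  p <- bio_params(quiet = TRUE)
  m <- box_mesh(3L, 3L, 3L, 0.02, 0.02, 0.02)
  ops <- assemble_operators(m)
  n <- nrow(m$nodes)
  eq <- species_state(rep(p$eta0, n), rep(p$sigma0, n), rep(p$upsilon0, n),
                      rep(1, n), rep(0, n))
  st <- explicit_step(eq, 500, ops, m, p, wound_flag = rep(FALSE, n))
  expect_equal(st$eta / p$eta0, eq$eta / p$eta0, tolerance = 1e-12)
  expect_equal(st$sigma_c, eq$sigma_c, tolerance = 1e-12)
  expect_equal(st$upsilon / p$upsilon0, eq$upsilon / p$upsilon0,
               tolerance = 1e-12)
  expect_equal(st$xi, eq$xi, tolerance = 1e-12)
  expect_equal(st$mu, eq$mu, tolerance = 1e-12)
})

test_that("spatially uniform stepping matches a scalar five-ODE oracle", {
  p <- bio_params(D_eta = 0, D_sigma = 0, D_xi = 0, D_mu = 0,
                  D_upsilon = 0, quiet = TRUE)
  m <- box_mesh(2L, 2L, 2L, 0.01, 0.01, 0.01)
  ops <- assemble_operators(m)
  n <- nrow(m$nodes)
  q <- c(eta = 0.3 * p$eta0, sigma = 0.4 * p$sigma0,
         upsilon = 0.2 * p$upsilon0, xi = 0.3, mu = 0.7 * p$mu0)
  st <- species_state(rep(q[1], n), rep(q[2], n), rep(q[3], n),
                      rep(q[4], n), rep(q[5], n))
  # independent scalar forward-Euler implementation
  scalar_rhs <- function(q) {
    S <- 2 * p$h1 * p$sigma_bar * q[2] / (p$sigma_bar^2 + q[2]^2) + p$h2
    K <- if (q[4] < p$xi_tilde) p$k_sigma * q[4] / p$xi_tilde else p$k_sigma
    H <- 3 * q[5] / (2 * p$mu0 + q[5])
    Q <- if (q[4] < p$xi_hat) 1 - q[4] / p$xi_hat else 0
    c(K * S * (2 * p$eta0 * q[1] - q[1]^2) - p$k * q[1],
      p$ell_eta * q[1] - p$ell * q[2],
      p$beta * H * (p$upsilon0 * q[3] - q[3]^2),
      p$lambda_upsilon * q[3] - p$lambda * q[4],
      p$phi_xi * Q - p$phi * q[5])
  }
  dt <- 400
  wf <- rep(TRUE, n)
  for (i in 1:5) {
    st <- explicit_step(st, dt, ops, m, p, wf)
    q <- q + dt * scalar_rhs(q)
  }
  got <- c(st$eta[1], st$sigma_c[1], st$upsilon[1], st$xi[1], st$mu[1])
  expect_equal(unname(got), unname(q), tolerance = 1e-14)

  # and the high-accuracy ODE oracle (deSolve) at reduced dt
  skip_if_not_installed("deSolve")
  q0 <- c(0.3 * p$eta0, 0.4 * p$sigma0, 0.2 * p$upsilon0, 0.3, 0.7 * p$mu0)
  t_end <- 1e4
  sol <- deSolve::lsoda(q0, c(0, t_end),
                        function(t, y, parms) list(scalar_rhs(y)),
                        rtol = 1e-12, atol = 1e-12)
  st2 <- species_state(rep(q0[1], n), rep(q0[2], n), rep(q0[3], n),
                       rep(q0[4], n), rep(q0[5], n))
  nsteps <- 20000                               # dt = 0.5 s
  for (i in seq_len(nsteps))
    st2 <- explicit_step(st2, t_end / nsteps, ops, m, p, wf)
  got2 <- c(st2$eta[1], st2$sigma_c[1], st2$upsilon[1], st2$xi[1],
            st2$mu[1])
  ref <- unname(sol[2, -1])
  scale <- c(p$eta0, p$sigma0, p$upsilon0, 1, p$mu0)
  expect_lt(max(abs(got2 - ref) / scale), 1e-6)
})

test_that("zero-flux diffusion conserves each species' mass", {
  p <- bio_params(k_sigma = 0, ell_eta = 0, ell = 0, beta = 0,
                  lambda_upsilon = 0, phi_xi = 0, phi = 0, quiet = TRUE)
  m <- box_mesh(4L, 4L, 4L, 0.02, 0.02, 0.02)
  ops <- assemble_operators(m)
  n <- nrow(m$nodes)
  set.seed(5)
  st <- species_state(runif(n), runif(n), runif(n), runif(n), runif(n))
  mass <- function(s) vapply(s[c("eta", "sigma_c", "upsilon", "xi", "mu")],
                             function(f) sum(ops$M * f), 0)
  m0 <- mass(st)
  dt <- cfl_max_dt(m, p, 0.5)
  for (i in 1:20) st <- explicit_step(st, dt, ops, m, p, rep(FALSE, n))
  expect_equal(mass(st), m0, tolerance = 1e-10)
})

test_that("capillary growth follows the logistic closed form under frozen stimulation", {
  # uniform field, H(mu) frozen at 1 by clamping mu = mu0 each step
  p <- bio_params(D_eta = 0, D_sigma = 0, D_xi = 0, D_mu = 0,
                  D_upsilon = 0, phi = 0, phi_xi = 0, quiet = TRUE)
  m <- box_mesh(2L, 2L, 2L, 0.01, 0.01, 0.01)
  ops <- assemble_operators(m)
  n <- nrow(m$nodes)
  ui <- 0.05 * p$upsilon0
  st <- species_state(rep(p$eta0, n), rep(p$sigma0, n), rep(ui, n),
                      rep(1, n), rep(p$mu0, n))
  t_end <- 1.5 / (p$beta * p$upsilon0)
  nsteps <- 12000
  for (i in seq_len(nsteps)) {
    st <- explicit_step(st, t_end / nsteps, ops, m, p, rep(TRUE, n))
    st$mu <- rep(p$mu0, n)                     # hold H = 1
  }
  r <- p$beta * p$upsilon0
  ups_exact <- p$upsilon0 * ui * exp(r * t_end) /
    (p$upsilon0 + ui * (exp(r * t_end) - 1))
  expect_equal(st$upsilon[1] / p$upsilon0, ups_exact / p$upsilon0,
               tolerance = 1e-4)
})

test_that("the cell front propagates at the Fisher-KPP speed", {
  # 1D-like bar, sigma frozen at sigma0 (S = 1), oxygen saturated (K = k_sigma)
  p <- bio_params(D_eta = 1e-11, D_sigma = 0, D_xi = 0, D_mu = 0,
                  D_upsilon = 0, beta = 0, phi_xi = 0, quiet = TRUE)
  nxc <- 200L
  m <- box_mesh(nxc, 1L, 1L, 0.1, 5e-4, 5e-4)
  ops <- assemble_operators(m)
  n <- nrow(m$nodes)
  x <- m$nodes[, 1L]
  st <- species_state(ifelse(x < 0.01, p$eta0, 0), rep(p$sigma0, n),
                      rep(p$upsilon0, n), rep(1, n), rep(0, n))
  # linearised front speed 2 sqrt(D_eta (2 k_sigma S eta0 - k)), k = k_sigma eta0
  speed_exact <- 2 * sqrt(p$D_eta * p$k)
  front_pos <- function(s) max(x[s$eta > 0.5 * p$eta0])
  dt <- 0.8 * min(cfl_max_dt(m, p, 1), 0.25 / p$k)
  advance <- function(s, t) {
    for (i in seq_len(ceiling(t / dt))) {
      s <- explicit_step(s, dt, ops, m, p, rep(FALSE, n))
      s$sigma_c <- rep(p$sigma0, n)   # freeze S at its healthy value
      s$xi <- rep(1, n)               # keep K saturated
    }
    s
  }
  t_settle <- 0.03 / speed_exact
  st <- advance(st, t_settle)
  x1 <- front_pos(st)
  t_meas <- 0.04 / speed_exact
  st <- advance(st, t_meas)
  x2 <- front_pos(st)
  speed <- (x2 - x1) / (ceiling(t_meas / dt) * dt)
  expect_lt(abs(speed / speed_exact - 1), 0.10)
})

test_that("run_healing handles trivial horizons and diverging states", {
  p <- bio_params(quiet = TRUE)
  mw <- tiny_wounded_phantom()
  st <- initialize_state(mw, p)
  out <- run_healing(st, mw, p, t_end = 0, dt = 1000)
  expect_identical(out$state$eta, st$eta)
  expect_equal(nrow(out$series), 1L)
})

test_that("the interface clamp holds wound-margin nodes at healthy values", {
  p <- bio_params(quiet = TRUE)
  mw <- tiny_wounded_phantom()
  st <- initialize_state(mw, p)
  iface <- bctsim:::wound_touching_nodes(mw) & !bctsim:::wound_nodes(mw)
  out <- run_healing(st, mw, p, t_end = 3 * 86400, dt = 5000,
                     interface_dirichlet = TRUE)
  expect_true(all(out$state$eta[iface] == p$eta0))
  expect_true(all(out$state$xi[iface] == 1))
  # without the clamp the margin responds to the neighbouring wound
  out2 <- run_healing(st, mw, p, t_end = 3 * 86400, dt = 5000)
  expect_gt(max(abs(out2$state$eta[iface] - p$eta0)) / p$eta0, 1e-4)
})
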