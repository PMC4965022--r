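# Biochemical and biomechanical parameter bundles, with validation and the
# homeostasis normalisation that makes healthy tissue a steady state of the
# five-species model. All numeric defaults live in the versioned file
# inst/extdata/default_params.yaml, not in code.

.param_cache <- new.env(parent = emptyenv())

#' Packaged default parameters
#'
#' Reads (and caches) the versioned default parameter file shipped in
#' `extdata/default_params.yaml`.
#'
#' @return nested list with `biology`, `materials` and `schedule` defaults.
#' @export
default_params <- function() {
  if (is.null(.param_cache$defaults)) {
    path <- system.file("extdata", "default_params.yaml", package = "bctsim")
    if (path == "")
      stop("packaged default_params.yaml not found", call. = FALSE)
    .param_cache$defaults <- yaml::read_yaml(path)
  }
  .param_cache$defaults
}

# fill NULL entries of `given` from `defs` (one level)
fill_defaults <- function(given, defs) {
  for (nm in names(defs))
    if (is.null(given[[nm]])) given[[nm]] <- defs[[nm]]
  given
}

#' Biochemical parameters of the wound-healing and angiogenesis model
#'
#' Holds every coefficient of the five-species reaction-diffusion system:
#' cell density eta, mitosis-regulating chemical sigma_c, capillary density
#' upsilon, normalised oxygen level xi and macrophage-derived growth factor
#' (MDGF) mu.
#'
#' Homeostasis normalisation: for the healthy state
#' `(eta0, sigma0, upsilon0, 1, 0)` to be a steady state, three parameters
#' are forced by the others and are always (re)derived here:
#' `sigma0 = ell_eta * eta0 / ell` (chemical balance),
#' `k = k_sigma * S(sigma0) * eta0` (cell balance) and
#' `lambda = lambda_upsilon * upsilon0` (oxygen balance, which pins the
#' normalised healthy oxygen level at 1). Values supplied for `k` or
#' `lambda` that disagree are overridden with a message.
#'
#' The capillary equation is a Fisher-type logistic without an intrinsic
#' diffusion term; a small capillary diffusivity `D_upsilon` (default
#' non-zero) spreads neovascularisation from the wound interface into the
#' wound, which is how the model's capillary ingrowth is realised (set it to
#' 0 to recover the strictly local logistic form, in which case an interior
#' wound with exactly zero initial capillary density never revascularises).
#'
#' @param D_eta,D_sigma,D_xi,D_mu,D_upsilon diffusivities (m^2/s).
#' @param k_sigma cell production rate (m^3 cell^-1 s^-1).
#' @param eta0 reference cell density in healthy tissue (cell m^-3).
#' @param h1,h2 activator mitosis-control parameters (S(sigma) =
#'   `2 h1 sigma_bar sigma / (sigma_bar^2 + sigma^2) + h2`).
#' @param h0 inhibitor mitosis-control parameter.
#' @param sigma_bar activator half-saturation concentration; `NULL` means
#'   "use sigma0" (so S(sigma0) = h1 + h2).
#' @param ell_eta chemical production rate per cell (conc m^3 cell^-1 s^-1).
#' @param ell chemical decay rate (s^-1).
#' @param beta capillary growth rate (m/s).
#' @param upsilon0 reference capillary density (m^-1).
#' @param mu0 MDGF reference concentration.
#' @param lambda_upsilon oxygen production rate per capillary density (m/s).
#' @param phi_xi MDGF production rate under hypoxia (conc/s).
#' @param phi MDGF decay rate (s^-1).
#' @param xi_hat oxygen threshold below which macrophages release MDGF.
#' @param xi_tilde oxygen threshold limiting cell production.
#' @param mitosis_mode `"activator"` (default, the mode used for the breast
#'   simulations) or `"inhibitor"`.
#' @param xi_init_wound initial oxygen level inside the wound (default 0: no
#'   vasculature, no supply).
#' @param k,lambda optionally supplied; rederived from the homeostasis
#'   constraint (a mismatch is reported, the derived value wins).
#' @param quiet suppress override messages.
#'
#' Any argument left `NULL` takes its value from the versioned default file
#' `extdata/default_params.yaml` (see [default_params()]).
#' @return object of class `bio_params`.
#' @export
bio_params <- function(D_eta = NULL, D_sigma = NULL, D_xi = NULL,
                       D_mu = NULL, D_upsilon = NULL,
                       k_sigma = NULL, eta0 = NULL,
                       h1 = NULL, h2 = NULL, h0 = NULL, sigma_bar = NULL,
                       ell_eta = NULL, ell = NULL,
                       beta = NULL, upsilon0 = NULL, mu0 = NULL,
                       lambda_upsilon = NULL,
                       phi_xi = NULL, phi = NULL,
                       xi_hat = NULL, xi_tilde = NULL,
                       mitosis_mode = NULL,
                       xi_init_wound = NULL,
                       k = NULL, lambda = NULL, quiet = FALSE) {
  fields <- c("D_eta", "D_sigma", "D_xi", "D_mu", "D_upsilon", "k_sigma",
              "eta0", "h1", "h2", "h0", "ell_eta", "ell", "beta",
              "upsilon0", "mu0", "lambda_upsilon", "phi_xi", "phi",
              "xi_hat", "xi_tilde", "mitosis_mode", "xi_init_wound")
  p <- mget(fields)
  p <- fill_defaults(p, default_params()$biology[fields])
  if (!p$mitosis_mode %in% c("activator", "inhibitor"))
    stop("mitosis_mode must be 'activator' or 'inhibitor'", call. = FALSE)
  sigma_bar <- sigma_bar %||% default_params()$biology$sigma_bar

  errs <- character()
  nonneg <- c("D_eta", "D_sigma", "D_xi", "D_mu", "D_upsilon", "k_sigma",
              "ell_eta", "ell", "beta", "mu0", "lambda_upsilon", "phi_xi",
              "phi", "h1", "h2", "xi_init_wound")
  for (nm in nonneg)
    if (!is.finite(p[[nm]]) || p[[nm]] < 0)
      errs <- c(errs, paste0(nm, " must be finite and >= 0"))
  for (nm in c("eta0", "upsilon0"))
    if (!is.finite(p[[nm]]) || p[[nm]] <= 0)
      errs <- c(errs, paste0(nm, " must be positive"))
  for (nm in c("xi_hat", "xi_tilde"))
    if (!is.finite(p[[nm]]) || p[[nm]] <= 0 || p[[nm]] >= 1)
      errs <- c(errs, paste0(nm, " must lie in (0, 1)"))
  if (length(errs))
    stop("invalid biochemical parameters:\n  ",
         paste(errs, collapse = "\n  "), call. = FALSE)

  # homeostasis normalisation (derived quantities); with no chemical
  # production the healthy chemical level is zero whatever the decay rate
  if (p$ell_eta > 0 && p$ell == 0)
    stop("ell must be positive when ell_eta > 0 (healthy chemical level ",
         "sigma0 = ell_eta * eta0 / ell would be unbounded)", call. = FALSE)
  p$sigma0 <- if (p$ell_eta == 0) 0 else p$ell_eta * p$eta0 / p$ell
  p$sigma_bar <- if (is.null(sigma_bar)) p$sigma0 else sigma_bar
  class(p) <- "bio_params"   # needed by source_S below
  k_derived <- p$k_sigma * source_S(p$sigma0, p) * p$eta0
  lam_derived <- p$lambda_upsilon * p$upsilon0
  if (!is.null(k) && !isTRUE(all.equal(k, k_derived)) && !quiet)
    message(sprintf(
      "homeostasis constraint overrides k: supplied %.6g, derived %.6g",
      k, k_derived))
  if (!is.null(lambda) && !isTRUE(all.equal(lambda, lam_derived)) && !quiet)
    message(sprintf(
      "homeostasis constraint overrides lambda: supplied %.6g, derived %.6g",
      lambda, lam_derived))
  p$k <- k_derived
  p$lambda <- lam_derived
  p
}

#' @export
print.bio_params <- function(x, ...) {
  cat("<bio_params> mitosis:", x$mitosis_mode, "\n")
  cat(sprintf("  eta0 %.3g  k %.3g/s  sigma0 %.3g  upsilon0 %.3g  lambda %.3g/s\n",
              x$eta0, x$k, x$sigma0, x$upsilon0, x$lambda))
  cat(sprintf("  D: eta %.2g sigma %.2g xi %.2g mu %.2g upsilon %.2g m^2/s\n",
              x$D_eta, x$D_sigma, x$D_xi, x$D_mu, x$D_upsilon))
  invisible(x)
}

#' Per-region material parameters for the biomechanical model
#'
#' Mooney-Rivlin bulk tissue (`W = c1 (I1bar - 3) + c2 (I2bar - 3) +
#' kappa/2 (J - 1)^2`), Veronda-Westmann skin membrane and the fibroblast
#' active-traction parameters. Any argument (or missing list entry) left
#' `NULL` takes its value from the versioned default file (see
#' [default_params()]).
#'
#' @param adipose,fibroglandular,wound lists with `c1`, `c2` (Pa), `kappa`
#'   (Pa) and `rho0` (kg/m^3).
#' @param skin list with `alpha` (Pa), `beta` (dimensionless), `c2` (Pa) and
#'   `rho0`.
#' @param active list with `tau_f` (Pa m^3/cell: specific fibroblast
#'   traction), `alpha_f` (dimensionless) and `eta0_f` (cell/m^3: reference
#'   fibroblast density); the fully-healed isotropic active stress is
#'   `tau_f * alpha_f * eta0_f`.
#' @param zeta_eps floor on tissue integrity: damage is clamped to
#'   `1 - zeta_eps` so wound elements keep a small deviatoric stiffness.
#' @param damage_volumetric if `TRUE` the damage factor also scales the
#'   volumetric (kappa) term; default `FALSE` keeps the fluid-filled wound
#'   quasi-incompressible.
#' @param active_global if `TRUE` the active stress acts in all regions, not
#'   only wound-labelled elements (sensitivity studies only).
#' @return object of class `material_set`.
#' @export
material_set <- function(adipose = NULL, fibroglandular = NULL,
                         wound = NULL, skin = NULL, active = NULL,
                         zeta_eps = NULL, damage_volumetric = NULL,
                         active_global = NULL) {
  defs <- default_params()$materials
  for (rn in c("adipose", "fibroglandular", "wound", "skin", "active"))
    assign(rn, fill_defaults(get(rn) %||% list(), defs[[rn]]))
  zeta_eps <- zeta_eps %||% defs$zeta_eps
  damage_volumetric <- damage_volumetric %||% defs$damage_volumetric
  active_global <- active_global %||% defs$active_global
  errs <- character()
  for (rn in c("adipose", "fibroglandular", "wound")) {
    r <- get(rn)
    for (nm in c("c1", "c2", "kappa", "rho0"))
      if (is.null(r[[nm]]) || !is.finite(r[[nm]]) || r[[nm]] <= 0)
        errs <- c(errs, paste0(rn, "$", nm, " must be positive"))
  }
  for (nm in c("alpha", "beta", "c2", "rho0"))
    if (is.null(skin[[nm]]) || !is.finite(skin[[nm]]) || skin[[nm]] <= 0)
      errs <- c(errs, paste0("skin$", nm, " must be positive"))
  for (nm in c("tau_f", "alpha_f", "eta0_f"))
    if (is.null(active[[nm]]) || !is.finite(active[[nm]]) || active[[nm]] < 0)
      errs <- c(errs, paste0("active$", nm, " must be >= 0"))
  if (zeta_eps <= 0 || zeta_eps >= 1)
    errs <- c(errs, "zeta_eps must lie in (0, 1)")
  if (length(errs))
    stop("invalid material parameters:\n  ",
         paste(errs, collapse = "\n  "), call. = FALSE)
  structure(list(adipose = adipose, fibroglandular = fibroglandular,
                 wound = wound, skin = skin, active = active,
                 zeta_eps = zeta_eps,
                 damage_volumetric = isTRUE(damage_volumetric),
                 active_global = isTRUE(active_global)),
            class = "material_set")
}

#' @export
print.material_set <- function(x, ...) {
  for (rn in c("adipose", "fibroglandular", "wound")) {
    r <- x[[rn]]
    cat(sprintf("  %-14s c1 %.4g Pa  c2 %.4g Pa  kappa %.4g Pa  rho0 %.4g\n",
                rn, r$c1, r$c2, r$kappa, r$rho0))
  }
  cat(sprintf("  skin: alpha %.4g Pa, beta %.3g, c2 %.4g Pa\n",
              x$skin$alpha, x$skin$beta, x$skin$c2))
  cat(sprintf("  active stress (healed): %.4g Pa\n",
              x$active$tau_f * x$active$alpha_f * x$active$eta0_f))
  invisible(x)
}

#' Two-timescale coupling schedule
#'
#' The biochemical solver advances with explicit steps `dt_bio` (reference
#' value 17.28 s on fine clinical meshes); the quasi-static mechanics is
#' re-solved every `dt_mech` (reference 6 days) up to `t_end` (reference 90
#' days). `dt_mech` must be an integer multiple of `dt_bio`; `dt_bio` is
#' adjusted downward (if needed) at run time to divide `dt_mech` exactly and
#' to respect the stability limit of the explicit scheme.
#'
#' @param dt_bio biochemical time step in seconds.
#' @param dt_mech_days mechanics step in days.
#' @param t_end_days healing horizon in days.
#' @param cfl_safety safety factor applied to the stability limit.
#' @return object of class `schedule`.
#' @export
schedule <- function(dt_bio = NULL, dt_mech_days = NULL, t_end_days = NULL,
                     cfl_safety = NULL) {
  defs <- default_params()$schedule
  dt_bio <- dt_bio %||% defs$dt_bio
  dt_mech_days <- dt_mech_days %||% defs$dt_mech_days
  t_end_days <- t_end_days %||% defs$t_end_days
  cfl_safety <- cfl_safety %||% defs$cfl_safety
  stopifnot(dt_bio > 0, dt_mech_days > 0, t_end_days > 0,
            cfl_safety > 0, cfl_safety <= 1)
  if (abs(t_end_days / dt_mech_days - round(t_end_days / dt_mech_days)) > 1e-9)
    stop("t_end_days must be a multiple of dt_mech_days", call. = FALSE)
  structure(list(dt_bio = dt_bio,
                 dt_mech = dt_mech_days * 86400,
                 t_end = t_end_days * 86400,
                 cfl_safety = cfl_safety),
            class = "schedule")
}

#' Load a validated simulation configuration from YAML
#'
#' Reads a single YAML file with optional sections `phantom`, `resection`,
#' `biology`, `materials`, `schedule`, `gravity` and `mesh` (MSH input with
#' `region_map`/`patch_map`/`scale`); missing keys fall back to package
#' defaults. All parameter invariants are validated on load and the
#' homeostasis-derived constants are recomputed (and reported when they
#' override supplied values).
#'
#' @param path YAML config path.
#' @param quiet suppress derivation messages.
#' @return a list with components `phantom`, `resection` (a
#'   [resection_plan()] or `NULL`), `bio` ([bio_params()]), `materials`
#'   ([material_set()]), `schedule` ([schedule()]), `gravity` (list with
#'   `pose`, `magnitude`) and `mesh` (input spec or `NULL`).
#' @export
load_config <- function(path, quiet = FALSE) {
  if (!file.exists(path)) stop("no such config file: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  known <- c("phantom", "resection", "biology", "materials", "schedule",
             "gravity", "mesh")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown))
    stop("unknown config section(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)

  bio <- do.call(bio_params, c(cfg$biology %||% list(), list(quiet = quiet)))
  mat <- do.call(material_set, cfg$materials %||% list())
  sch <- do.call(schedule, cfg$schedule %||% list())

  phantom <- cfg$phantom
  resect <- NULL
  if (!is.null(cfg$resection))
    resect <- resection_plan(cfg$resection$axis_point,
                             cfg$resection$axis_direction,
                             cfg$resection$radius)
  grav <- cfg$gravity %||% list(pose = "none", magnitude = 9.81)
  if (is.null(grav$pose)) grav$pose <- "none"
  if (is.null(grav$magnitude)) grav$magnitude <- 9.81
  if (!grav$pose %in% c("none", "prone", "supine", "upright"))
    stop("gravity$pose must be none/prone/supine/upright", call. = FALSE)

  mesh_in <- cfg$mesh
  if (!is.null(mesh_in)) {
    for (nm in c("path", "region_map", "patch_map"))
      if (is.null(mesh_in[[nm]]))
        stop("config mesh section is missing key: ", nm, call. = FALSE)
    mesh_in$region_map <- unlist(mesh_in$region_map)
    mesh_in$patch_map <- unlist(mesh_in$patch_map)
    if (is.null(mesh_in$scale)) mesh_in$scale <- 1
  }

  list(phantom = phantom, resection = resect, bio = bio, materials = mat,
       schedule = sch, gravity = grav, mesh = mesh_in)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Gravity vector for a named pose
#'
#' Coordinate convention: X lateral, Y anterior, Z cranial. In the prone
#' pose the breast hangs anteriorly, so gravity is `(0, +g, 0)`; supine is
#' `(0, -g, 0)` (tissue pulled towards the chest wall) and upright is
#' `(0, 0, -g)` (caudal).
#'
#' @param pose `"prone"`, `"supine"`, `"upright"` or `"none"`.
#' @param magnitude gravitational acceleration (m/s^2).
#' @return length-3 gravity vector (m/s^2).
#' @export
gravity_vector <- function(pose, magnitude = 9.81) {
  switch(pose,
         none = c(0, 0, 0),
         prone = c(0, magnitude, 0),
         supine = c(0, -magnitude, 0),
         upright = c(0, 0, -magnitude),
         stop("unknown pose: ", pose, call. = FALSE))
}
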