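# Default parameter set of the simulator (SI units throughout).
#
# Biochemical values follow the Sherratt-Murray epidermal-healing kinetics
# and continuum angiogenesis modelling literature in order of magnitude, and
# are tuned as a set so that the bundled desk-scale phantom reproduces the
# expected healing behaviour (proliferative contraction between roughly day
# 8 and 16, shape plateau around day 30, ~8% wound volume loss). The
# contraction magnitude and timing are strongly parameter-dependent; treat
# these as a calibrated reference set, not as patient-specific values.
#
# Derived at load time (homeostasis normalisation; do not set here):
#   sigma0 = ell_eta * eta0 / ell
#   k      = k_sigma * S(sigma0) * eta0
#   lambda = lambda_upsilon * upsilon0

biology:
  D_eta: 4.0e-11        # cell diffusivity, m^2/s
  D_sigma: 1.0e-10      # mitosis-chemical diffusivity, m^2/s
  D_xi: 2.0e-10         # oxygen diffusivity, m^2/s
  D_mu: 1.0e-10         # MDGF diffusivity, m^2/s
  D_upsilon: 1.0e-11    # capillary ingrowth diffusivity, m^2/s (see docs)
  k_sigma: 2.5e-20      # cell production rate, m^3 cell^-1 s^-1
  eta0: 1.0e+14         # reference cell density, cell/m^3
  h1: 0.9               # activator mitosis gain (S(sigma0) = h1 + h2 = 1)
  h2: 0.1               # basal mitosis level
  h0: 10.0              # inhibitor-branch parameter (S(0) = h0)
  sigma_bar: ~          # activator half-saturation; null = use sigma0
  ell_eta: 5.0e-19      # chemical production per cell, conc m^3/(cell s)
  ell: 5.0e-5           # chemical decay rate, 1/s
  beta: 1.2e-9          # capillary growth rate, m/s
  upsilon0: 5.0e+3      # reference capillary density, 1/m
  mu0: 1.0              # MDGF reference concentration (arbitrary units)
  lambda_upsilon: 1.0e-8  # oxygen supply per capillary density, m/s
  phi_xi: 2.0e-5        # MDGF release rate under hypoxia, conc/s
  phi: 1.0e-6           # MDGF decay rate, 1/s (slow: spans remodelling)
  xi_hat: 0.5           # hypoxia threshold for MDGF release
  xi_tilde: 0.9         # oxygen threshold limiting mitosis
  mitosis_mode: activator
  xi_init_wound: 0.0    # initial wound oxygen level

materials:
  adipose:         {c1: 120.0, c2: 30.0, kappa: 1.5e+4, rho0: 945.0}
  fibroglandular:  {c1: 240.0, c2: 60.0, kappa: 3.0e+4, rho0: 1041.0}
  wound:           {c1: 120.0, c2: 30.0, kappa: 1.5e+4, rho0: 1000.0}
  skin:            {alpha: 3.0e+3, beta: 5.0, c2: 1.0e+3, rho0: 1100.0}
  # fully-healed active stress tau_f * alpha_f * eta0_f = 1.4 kPa
  active:          {tau_f: 1.4e-10, alpha_f: 1.0, eta0_f: 1.0e+13}
  zeta_eps: 1.0e-3
  damage_volumetric: false
  active_global: false

schedule:
  dt_bio: 17.28         # s; fine-mesh reference biochemical step
  dt_mech_days: 6       # mechanics re-solve interval
  t_end_days: 90        # healing horizon
  cfl_safety: 0.5
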