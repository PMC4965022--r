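---
title: "Methods: coupled wound-healing and breast-mechanics simulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: coupled wound-healing and breast-mechanics simulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the modelling assumptions, parameter choices and
numerical decisions behind `bctsim`. It is the package's reference for
*why* the code does what it does; the README shows *how* to run it.

## The biological model and its assumptions

Healing of the resected region is described by five continuum fields on a
fixed (Lagrangian) tetrahedral mesh: cell density $\eta$ (cells m$^{-3}$),
a homogenised mitosis-regulating chemical $\varsigma$, capillary density
$\upsilon$ (m$^{-1}$, capillary wall area per tissue volume), normalised
oxygen level $\xi$ (healthy level 1) and a homogenised macrophage-derived
growth factor (MDGF) $\mu$. The causal chain the equations encode is:
resection leaves an avascular, hypoxic region; hypoxia makes macrophages
release MDGF ($Q$ term); MDGF drives capillary regrowth (logistic in
$\upsilon$, gated by $H(\mu) = 3\mu/(2\mu_0+\mu)$); capillaries restore
oxygen; oxygen permits cell proliferation (production gate $K(\xi)$,
chemical control $S(\varsigma)$), and the cell front closes the wound.

Key structural assumptions:

* **No mechano-sensing.** Strain does not feed back into the transport
  equations, so biology→mechanics coupling is strictly one-way. This keeps
  the biology solvable on the reference mesh with no remeshing or state
  mapping, and it is tested as an invariant (the biology trajectory is
  bitwise-independent of whether mechanics runs).
* **Homeostasis normalisation.** The healthy state
  $(\eta_0, \varsigma_0, \upsilon_0, 1, 0)$ must be a steady state, which
  forces three constants: $\varsigma_0 = \ell_\eta \eta_0/\ell$,
  $k = k_\varsigma S(\varsigma_0)\eta_0$ and
  $\lambda = \lambda_\upsilon \upsilon_0$. The first two follow from the
  chemical and cell balances. The third is the same argument applied to
  the oxygen balance: the oxygen level is *defined* as normalised to 1 in
  healthy tissue, and that is only a steady state if supply at
  $\upsilon_0$ balances consumption at $\xi = 1$. `bio_params()` therefore
  always derives all three and reports any user-supplied value it
  overrides.
* **Capillary ingrowth as diffusion.** The capillary equation is a local
  logistic: with an exactly zero initial value inside the wound and no
  transport term, the interior could never revascularise (zero is a fixed
  point of the logistic). Neovascularisation physically proceeds by
  sprouting from the wound margin inward, which the model represents with
  a small capillary diffusivity `D_upsilon` (default
  $10^{-11}\,$m$^2$/s). Setting it to zero recovers the strictly local
  form. This is the one term added beyond the minimal five-equation
  system, and the packaged tests that compare against the local closed
  forms (well-mixed ODE oracle, logistic solution) run with uniform fields
  where the term vanishes identically.
* **Mitosis control.** The activator form
  $S = 2h_1\bar\varsigma\varsigma/(\bar\varsigma^2+\varsigma^2) + h_2$ is
  the default and the form used in all bundled simulations. The inhibitor
  branch is implemented as
  $S = ((h_0-1)\varsigma + h_0\varsigma_0)/(2(h_0-1)\varsigma +
  \varsigma_0)$, the reconstruction that restores the Sherratt–Murray
  normalisation $S(\varsigma_0) = 1$ (the same normalisation the activator
  obeys with the default $h_1 + h_2 = 1$); the printed source for the
  inhibitor expression is typographically ambiguous, and the code comments
  flag this.

### Initial and boundary conditions

Wound nodes — nodes all of whose incident elements are wound-labelled —
start at $\eta = \upsilon = 0$ and $\xi = $ `xi_init_wound` (default 0: no
vasculature means no supply; the stated initial conditions only pin
$\eta$ and $\upsilon$, so the initial oxygen level is exposed as a config
key). Interface nodes (touching both wound and healthy elements) take
healthy values, implementing the wound/healthy-interface condition as an
initial condition rather than a permanent Dirichlet clamp; both growth
factors start at zero everywhere, so even healthy tissue undergoes a brief
transient while $\varsigma$ rises to $\varsigma_0$. All species carry
zero-flux (natural) boundary conditions: the wound is assumed well
interior to the domain, so boundary effects are negligible — an assumption
the phantom geometry respects by construction.

## The biomechanical model

Quasi-static Total-Lagrangian finite elasticity, linear tetrahedra.
Near-incompressibility is handled with the mixed $u/p$ formulation with
element-wise constant pressure. For constant-gradient tetrahedra the
pressure can be condensed out exactly — the element pressure is
$p_e = \kappa(J_e - 1)$ — so the assembled system involves displacements
only and the pressure is recovered afterwards (`mech_state$pressure`).
This is the minimal stable-in-practice pairing; it retains the mild
volumetric locking known for P1/P0 in bending-dominated problems, which
is acceptable here because the loadings (gravity, isotropic wound
traction) are volumetric/bulk-dominated. The penalty-consistency test
(volume change monotonically vanishing as $\kappa$ grows) quantifies the
incompressibility behaviour that matters for the contraction metric.

* **Damage.** $\zeta = 1 - \eta/\eta_0$ per element (element mean of nodal
  $\eta$), clamped to $[0, 1-\varepsilon]$ with $\varepsilon = 10^{-3}$ so
  wound elements never lose all deviatoric stiffness; healthy elements are
  pinned at $\zeta = 0$. The integrity factor $(1-\zeta)$ scales the
  *isochoric* Mooney-Rivlin terms and leaves the $\kappa$ penalty intact,
  so the freshly wounded, fluid-filled region is soft in shear but still
  quasi-incompressible. (The source description of which part is scaled is
  self-contradictory — "dilational" scaled versus "volumetric left intact"
  — and the second reading wins on the stated physical grounds; a
  `damage_volumetric` switch implements the other reading for sensitivity
  studies.)
* **Active stress.** $S_\text{active} = \tau_f \eta_f I$ with
  $\eta_f = \alpha_f (\eta/\eta_0) \eta_{0,f}$, applied in wound-labelled
  elements only: $\eta_f$ is defined as the fibroblast density *in the
  wounded region*, and applying the same stress in healthy tissue (where
  $\eta = \eta_0$ always) would contract the whole breast rather than the
  wound. An `active_global` switch exists for sensitivity studies. The
  active stress is zero at surgery time ($\eta \approx 0$) and grows with
  healing, which is what produces the sigmoidal contraction curve.
* **Skin.** Veronda-Westmann membrane
  ($W = \alpha[e^{\beta(\tilde I_1 - 3)} - 1] + c_2(\tilde I_2 - 3)$) on
  the skin boundary patch, 1.5 mm constant thickness, with exact
  through-thickness incompressibility via the plane-stress substitution
  $\lambda_3^2 = 1/\det C_s$. No skin is resected.
* **Boundary conditions.** Chest wall (pectoral fascia interface) fully
  fixed; superior/inferior clip planes $u_Z = 0$; skin and lateral
  boundary traction-free.

## Two-timescale coupling

Biochemistry advances with explicit steps of `dt_bio` (reference 17.28 s
on fine clinical meshes); every `dt_mech` = 6 days the element damage and
active stress are rebuilt from the current $\eta$ and the mechanics is
re-solved from the reference configuration (Total-Lagrangian, so no mesh
update is ever needed), warm-started from the previous solution. Damage
and active stress are updated once per mechanics step, not sub-stepped:
the mechanics is quasi-static, so only the state at the solve time
matters. The deformed wound volume (sum of element volumes under the
mapped coordinates) is recorded each cycle, normalised by the reference
wound volume.

## Numerical choices

* **Stability.** `cfl_max_dt()` implements the edge-based estimate
  $\Delta t = s\,\min_e h_{\min,e}^2 / (6 D_{\max})$. On tetrahedral
  meshes with less-than-perfect elements the true spectral bound can be
  tighter, so runs additionally compute a Gershgorin bound on
  $\lambda_{\max}(M^{-1}K)$ and take the minimum; the step is also capped
  at a fraction of the fastest reaction time constant and then rounded
  down so that it divides `dt_mech` exactly.
* **Positivity.** The P1 Galerkin Laplacian is not an M-matrix, so sharp
  initial fronts can undershoot zero, and a negative $\eta$ feeds the
  quadratic logistic unstably. The update is therefore projected onto the
  non-negative cone each step. The projection is inactive for smooth
  non-negative fields (all oracle comparisons are unaffected) and
  preserves the lumped-mass conservation property whenever it is inactive.
* **Newton solver.** Exact consistent tangents (verified against central
  finite differences of the assembled residual to $10^{-5}$ relative),
  load stepping with automatic increment halving, residual-based
  backtracking, and convergence at $10^{-8}$ relative residual. A
  stagnation acceptance triggers when the residual has dropped at least
  $10^5$-fold but floors out at solver rounding — which happens for very
  stiff material limits — rather than forcing futile iterations.
* **Unloaded configuration.** Fixed-point (Sellier-style) iteration:
  forward-solve gravity from the current reference guess, move the
  reference nodes by the prediction mismatch, repeat; tolerance
  $10^{-4}$ m, at most 20 iterations, with an inversion guard on the
  reference update. The scheme's round-trip accuracy is tested directly
  (forward solve, then unload, recovers the original reference).
* **Resection.** Element membership in the resection cylinder is decided
  by the element centroid — deterministic, mesh-independent in the limit,
  and consistent with labelling whole elements as wound. Resected elements
  are retained and relabelled, never deleted: the damage formulation needs
  the wound and the surrounding healthy tissue as two interfacing volumes
  of one mesh.
* **ICP and surface distance.** Rigid alignment uses point-to-point ICP
  (nearest-vertex correspondences, Kabsch/SVD update); the evaluation
  metric is the exact point-to-triangle distance from each source vertex
  to the target surface (asymmetric by convention, simulation →
  follow-up; a `symmetric` flag pools both directions). Percentiles use
  linear interpolation between order statistics (the conventional
  definition; the choice is documented because percentile conventions
  differ).

## The phantom and what passing tests mean

`generate_phantom()` builds a hemispherical "breast" (adipose shell around
an ellipsoidal fibroglandular core at a requested volume fraction) on a
rectangular tissue slab whose base is the chest-wall fascia; slab sides
provide the clip planes, and the dome plus the exposed slab top carry the
skin membrane. The mesh is a structured hex lattice split into conforming
tetrahedra, with the dome produced by a smooth cube-to-ball map (surface
nodes exactly on the sphere) and per-octant mirrored element splits chosen
so that no tetrahedron degenerates on the mapped shells; a small
deterministic jitter (seeded) de-structures the interior.

The phantom emulates the *geometry class* of the clinical problem —
two-tissue breast volume, skin shell, chest-wall support, clipped domain,
cylindrical lumpectomy from skin to fascia — at desk scale (~2300 nodes
for the bundled preset, element edges ~10 mm). It does not emulate real
breast anatomy: no Cooper's ligaments, no ductal structure, idealised
symmetric shape, population-typical rather than patient-specific material
constants. Passing the acceptance suite therefore demonstrates that the
implementation reproduces the *model's* predicted physiology and
contraction behaviour under controlled conditions, not that it predicts
any specific patient's cosmetic outcome.

## Parameters

All defaults live in `inst/extdata/default_params.yaml` (SI units,
commented per key) and are loaded — never hard-coded — by `bio_params()`,
`material_set()` and `schedule()`. The biochemical set follows the
epidermal-healing and continuum-angiogenesis literature in structure and
order of magnitude, with rates tuned as a set so the desk phantom
reproduces the expected healing behaviour: hypoxic lag of a few days,
proliferative contraction peaking around days 8–16, plateau by about day
30, and ~8% final wound-volume loss. Both the magnitude and the timing of
contraction are strongly parameter-dependent (notably on
$\tau_f \alpha_f \eta_{0,f}$ against $\kappa$, and on
$D_\eta, k$ through the front speed $2\sqrt{D_\eta k}$); the defaults are
a calibrated reference set, not patient values. Mechanical moduli are
breast-tissue scale (adipose $c_1 = 120$ Pa, fibroglandular twice as
stiff, $\kappa$ set for a small-strain Poisson ratio near 0.49, skin
$\alpha = 3$ kPa with exponent 5).

The desk preset (`inst/extdata/desk.yaml`) runs a 6 cm-radius phantom at
10 mm edge length with a 2 cm-radius lumpectomy and `dt_bio` = 5000 s
(the coarse mesh admits a far larger stable step than the fine-mesh
17.28 s reference; the stability guards above still apply). Heavier
problem sizes — finer meshes, the 17.28 s reference step — run with the
same code paths by editing the config.

Desk-preset healing runs set gravity to zero: the contraction metric is
the *normalised* wound-volume ratio, and a constant-in-time gravity
preload contributes only a fixed offset to both numerator and denominator
configurations; the gravity solves themselves are exercised by the pose
and unloading pipeline with stiffer test materials.

## Known limitations

* One-way coupling by design: no mechano-sensitive chemotaxis or
  stress-modulated healing.
* P1/P0 condensed elements lock mildly in bending-dominated scenarios;
  they are adequate for the bulk-dominated loadings here.
* Explicit biochemical stepping makes very fine meshes expensive
  ($\Delta t \propto h^2$); an implicit or operator-split integrator
  would lift this.
* No contact: an imaging coil or supine support surface touching the
  skin is not modelled, so the unloaded-state estimate inherits any
  contact distortion present in the input geometry.
* Adjuvant-therapy effects (radiotherapy fibrosis, chemotherapy) are out
  of scope; the damage law heals monotonically to full integrity.
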