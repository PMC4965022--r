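# bctsim — multiscale finite-element simulation of breast-conserving surgery

`bctsim` is an R package that simulates the mechano-biological aftermath of
breast-conserving therapy (lumpectomy): it couples a continuum
wound-healing and angiogenesis model to a nonlinear soft-tissue mechanics
model on a labelled tetrahedral mesh of the breast, and predicts how the
resected region heals, contracts and reshapes the breast over the weeks
after surgery. It is aimed at computational biomechanics researchers who
want a self-contained, scriptable implementation of the full pipeline —
mesh in, virtual surgery, healing simulation, cosmetic evaluation out —
without patient data: a synthetic breast phantom generator stands in for
image-derived geometry.

## The model

**Wound healing and angiogenesis.** Five fields live on the nodes of the
(fixed, Lagrangian) mesh: cell density η, a mitosis-regulating chemical ς,
capillary density υ, normalised oxygen level ξ and macrophage-derived
growth factor (MDGF) μ. They obey a reaction–diffusion system

    η̇ = D_η ∇²η + K(ξ) S(ς) (2 η₀ η − η²) − k η
    ς̇ = D_ς ∇²ς + ℓ_η η − ℓ ς
    υ̇ = D_υ ∇²υ + β H(μ) (υ₀ υ − υ²)
    ξ̇ = D_ξ ∇²ξ + λ_υ υ − λ ξ
    μ̇ = D_μ ∇²μ + φ_ξ Q(ξ) − φ μ

with S the (activator or inhibitor) chemical control of mitosis,
H(μ) = 3μ/(2μ₀+μ) the angiogenic stimulus, Q the hypoxia-gated MDGF
release and K the oxygen-limited cell production rate. Hypoxia in the
freshly resected wound releases MDGF, capillaries regrow logistically,
oxygen returns, and the cell front closes the wound. The system is
discretised with linear (P1) tetrahedra, lumped mass and forward-Euler
stepping under a CFL-type stability bound, with zero-flux boundaries.

**Tissue mechanics.** Quasi-static Total-Lagrangian finite elasticity with
a mixed u/p treatment of near-incompressibility (element-constant pressure,
statically condensed). Adipose and fibroglandular tissue are Mooney-Rivlin,

    W = (1 − ζ) [c₁(Ī₁ − 3) + c₂(Ī₂ − 3)] + κ/2 (J − 1)²,

where the damage variable ζ = 1 − η/η₀ scales the isochoric stiffness of
the wounded tissue (the volumetric part stays intact: the fluid-filled
wound remains quasi-incompressible). The skin is a Veronda-Westmann
membrane shell of 1.5 mm thickness; fibroblast traction adds an isotropic
active stress S_active = τ_f η_f I in the wound, with η_f ∝ η/η₀. The
chest wall is fixed, clip planes carry zero axial displacement, skin is
traction-free.

**Coupling.** Biology advances with seconds-scale explicit steps; every 6
days the cell density is mapped to element damage and active stress and
the mechanics is re-solved (Newton with load increments and exact
consistent tangents). Coupling is one-way (non-mechano-sensing): the
biology never sees the deformation, so the healing trajectory is identical
with or without the mechanics.

The pipeline also provides the surgical-planning steps around the core
solver: gravity-pose prediction (prone/supine/upright), recovery of the
unloaded (gravity-free) reference configuration by fixed-point inverse
analysis, cylindrical resection labelling, and cosmetic-outcome evaluation
(rigid ICP alignment plus exact point-to-triangle surface-distance
statistics).

## Worked example

```r
library(bctsim)

# synthetic breast: 6 cm hemisphere on a tissue slab, ~2300 nodes
mesh <- generate_phantom(breast_radius = 0.06, slab_depth = 0.02,
                         target_edge_length = 0.01, fibro_fraction = 0.25,
                         seed = 1)

# virtual lumpectomy: 2 cm-radius cylinder perpendicular to the chest wall
plan <- resection_plan(axis_point = c(0.018, 0, 0),
                       axis_direction = c(0, 1, 0), radius = 0.02)
mesh <- mark_resection(mesh, plan)
region_volume(mesh, "wound")           # 9.28e-05  (m^3)

# 90 days of coupled healing with the packaged default parameters
res <- run_coupled(mesh, bio_params(), material_set(),
                   schedule(dt_bio = 5000))
contraction_metrics(res$trajectory)
#> $final_fraction
#> [1] 92.01296
#> $day_max_rate
#> [1] 12
#> $plateau_day
#> [1] 24
```

The wound-volume trajectory is the classic three-phase curve: slow early
contraction while the wound is hypoxic and inert (inflammation), a
pronounced contraction as the cell front sweeps the wound and pulls on the
surrounding tissue (proliferation, steepest around day 12), and a smooth
plateau once η ≈ η₀ everywhere (remodelling; the shape is effectively
final from about day 24–30). The healed wound retains ~92% of its original
volume with the default parameter set; the magnitude is strongly dependent
on the biochemical and active-traction parameters (see
`inst/extdata/default_params.yaml`).

A thin command-line interface wraps the same pipeline:

```sh
Rscript $(Rscript -e 'cat(system.file("cli/bctsim.R", package="bctsim"))') \
    demo --config inst/extdata/desk.yaml --out out/
```

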