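---
title: "Methods: the coupled immuno-mechanical aneurysm model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the coupled immuno-mechanical aneurysm model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aortawall)
```

# The model

`aortawall` couples an inflammatory reaction–advection–diffusion network to
quasi-static hyperelasticity on a moving mesh, as a mechanistic model of
abdominal aortic aneurysm growth. The computational domain is a 2D section
of the wall of an already-bulged aorta: two curved strips — the media
(smooth-muscle- and elastin-rich) and the adventitia (fibroblast- and
collagen-rich) — bounded by the lumen interface `Γ_B`, the interlayer
membrane `Γ_M`, the outer surface `Γ_A`, and two artificial horizontal cuts
`Γ_0` where the bulge meets the straight vessel.

## Species network

Twelve fields (g/cm³) evolve by

$$\partial_t Z + \nabla\cdot(\mathbf v Z) - D_Z \Delta Z = F_Z(Z),$$

where `v` is the tissue velocity from the mechanics and the sources encode:
MCP-1 production by macrophage-stressed SMCs, internalization and decay;
macrophage activation by IFN-γ enhanced by TNF-α; T-cell activation by
macrophage contact under IL-12, inhibited by IL-10; SMC renewal, apoptosis
driven by macrophages, and death; IL-6 production by macrophages and SMCs;
IL-10/IL-12/TNF-α production by macrophages with IL-10 feedback inhibition;
IFN-γ production by T cells; MMP production by macrophages and SMCs
enhanced by TNF-α; TIMP production by macrophages; MMP–TIMP mutual binding
depletion; and ECM production by fibroblasts (adventitia) and SMCs (media)
clamped by a carrying capacity, degraded by MMP. Macrophages additionally
drift chemotactically up the MCP-1 and IL-6 gradients with a shared
coefficient `chi_C`.

Boundary exchange is of Robin type, `flux = -rate (X - X_external)`: the
monocyte/T-cell influx on `Γ_B` and `Γ_A` (the macrophage rate is gated by
local MCP-1, `alpha_M P/(P+K_P)`), endothelial MCP-1 and IL-6 sources on
`Γ_B` with serum levels `P0` and `I60`, and interlayer exchange across
`Γ_M` with class-specific coefficients (50 for cells, 500 for cytokines).
The exchange rates multiply the concentration jump directly in the weak
form — they act as exchange *velocities* (cm/day). This is the reading
under which the boundary influx acts on the tens-of-days timescale of the
disease; multiplying them by the cellular diffusivities (~1e-6 cm²/day)
would freeze the influx entirely. SMCs are confined to the media (zero flux
everywhere), and the ECM is one continuous field across `Γ_M`.

## Mechanics

The wall is an incompressible-type, isotropic hyperelastic solid,
`W = beta1 (I_B - 3) + beta2 (I_B - 3)^2` with `I_B = tr(B)`, `B = F Fᵀ`,
and Cauchy stress `sigma = -p I + (2 beta1 + 4 beta2 (I_B - 3)) B`. The
biology enters through two affine closures: the moduli degrade with SMC
loss, `beta_i(S) = beta_i0 + k_i (S/S0 - 1)`, and the hydrostatic tissue
pressure follows the ECM, `p(rho) = p* - beta_p (1 - rho/rho*)`. Blood
exerts the traction `-p_B n` on `Γ_B` (110 mmHg converted to N/cm²);
`Γ_A` is traction-free; a surface tension `gamma_surf * kappa * n` acts on
`Γ_B` and `Γ_M`; displacement is clamped on the cuts.

The 2D section is treated in plane strain: `F` is augmented with a unit
out-of-plane stretch so `I_B = tr(B_2D) + 1` and the `(I_B - 3)` terms hold
literally. The elastic part of the first Piola stress is implemented as the
exact gradient of the stored energy per reference volume,
`P_el = (2 beta1 + 4 beta2 (I_B - 3)) F`, and the pressure part as the
exact pullback `-p cof(F)`; this makes the discrete residual the exact
gradient of a potential (verified by finite differences in the test suite)
and agrees with the Cauchy form up to `O(J - 1)` in the
nearly-incompressible regime. A config switch (`piola_variant = "paper"`)
provides the alternative halved-coefficient Lagrangian form with an
explicit `J` factor.

Two properties of this constitutive law are worth knowing. First,
`dW/dI_B = beta1 + 2 beta2 (I_B - 3)` becomes negative once
`I_B - 3 < -beta1/(2 beta2)` (about −0.046 at baseline): under a few
percent of biaxial *compression* the material destabilizes and the Newton
tangent is indefinite. Simulated states are expansive and never enter this
regime. Second, since `beta2 >> beta1`, the quadratic term acts like a
near-incompressibility penalty on linear elements; see *Numerics*.

# Parameters

All constants live in a single registry (`load_parameters()`), in (g, cm,
day) units with moduli in N/cm²; every value carries provenance
(`default` / `override` / `assumed` / `derived`) and can be overridden from
a flat YAML file. `check_params()` re-derives the constants that come from
literature measurements:

* IL-6 production rates from steady-state secretion assays
  (`lambda = d_I6 * IL6_level / cell_density`, with the cell-count
  convention 1e6 cells/ml = 1e-3 g/cm³), giving `lambda_I6M = 1.73e-6`/day
  and `lambda_I6S = 1.73e-5`/day;
* the moduli slopes `k1 = 30.4`, `k2 = 84` N/cm² from healthy vs diseased
  tissue moduli assuming the diseased wall has half its SMCs;
* the pressure law `p* = 37`, `beta_p = 18` N/cm² from measured peak wall
  stress ranges assuming ECM reduced to 75 %.

A few constants are not available in published tables and are closed here
(all config-exposed, flagged `assumed` in the dump):

* `lambda_S` (SMC source): set to `d_S * S0` so that healthy,
  macrophage-free tissue is exactly stationary at the baseline `S0`; this
  also makes `S -> S0/2` the asymptotic state under saturated macrophage
  attack, consistent with the moduli calibration point.
* `d_T = 0.197`/day (T-cell death), `lambda_MTa = 1` (dimensionless TNF-α
  enhancement amplitude), `D_r = 8.64e-7` cm²/day (ECM quasi-immobile),
  `gamma_surf = 1e-2` N/cm.
* `rho*` in the pressure law is taken equal to the initial ECM density
  3.43e-4 g/cm³ (distinct from the carrying capacity `rho0 = 1e-3`); both
  are independent keys.
* The moduli law needs an SMC density in the adventitia, where SMCs do not
  exist and a literal `S = 0` would give `beta1 < 0`. The adventitia
  (which suffers no SMC loss) uses the baseline `S0`, i.e. retains its
  healthy moduli (`adventitia_smc` key).
* The interlayer exchange uses the species-class values 50 (cells) and 500
  (cytokines); a tabulated single alternative (0.1 cm⁻¹) is retained as a
  comment in the source.

# Initial conditions and geometry

The study conditions are generated programmatically, no external data. The
three boundaries are cosine bulge profiles in profile units,
`x_A = 0.7 cos(pi y)/2 + 0.3`, `x_M = 0.55 cos(pi y)/2 + 0.2`,
`x_B = 0.5 cos(pi y)/2` on `y in [-1, 1]`, nested and positive-width. The
vessel centerline is at `x = -0.75`, which makes the unscaled bulge
diameter exactly 2; the section is scaled uniformly by `R0/2`. Initially
IL-6 is at half its serum influx level, `Q = 3e-8`, `Q_r = 1e-8`,
`rho = 3.43e-4`, `S = S0 = 6e-3` g/cm³, and all other fields are zero.

Because the profiles are even in `y`, identifying the two cut rows
periodically (as done for species transport) coincides with reflective
conditions for the default geometry; displacement is clamped at the cuts.

What this synthetic geometry does *not* emulate: real aneurysms are
three-dimensional, non-symmetric, with intraluminal thrombus, residual
stress and anisotropic fiber-reinforced walls; passing tests on this
section therefore validate the numerics and the stated model, not clinical
realism.

# Numerics

* **Mesh** — structured boundary-fitted triangulation (two triangles per
  quad), matched node-for-node along `Γ_M`; defaults 32 rows and 4 + 2
  through-thickness layers (231 nodes, 384 elements). Jump species carry
  two one-sided fields (media and adventitia copies of the interface
  nodes); ECM is a single merged-mesh field.
* **Time stepping** — decoupled scheme, default `k = 0.5` day: Newton solve
  of the Lagrangian equilibrium with previous-step `S`, `rho` in the
  coefficients; mesh update by the flow map; implicit species solve on the
  moved mesh. Velocity is the backward difference of displacement; the
  `div(v) Z` dilution term is assembled implicitly with elementwise
  discrete divergence. Since nodes follow the flow map, the material
  derivative needs no interpolation.
* **IMEX split** — production terms are explicit, all degradation, binding
  and apoptosis channels are implicit with coefficients frozen at the
  previous step (e.g. MMP loses mass at rate `d_Q + d_QQr * Qr^{n-1}`,
  implicitly in `Q`). This keeps every species solve linear, reproduces the
  implicit-Euler decay closed form exactly, and makes the fastest tabled
  rate (TNF-α, 55.45/day) unconditionally stable at `k = 0.5`.
* **Mass lumping** — lumped mass matrices and lumped Robin edge weights;
  with zero flux and zero sources the lumped total mass of each species is
  conserved to solver precision (tested).
* **Chemotaxis** — lagged: the flux uses `M`, `∇P`, `∇I6` from the previous
  step, keeping the macrophage solve linear. The induced drift
  (`~1e-5` cm/day at the simulated gradients) is far below diffusion.
* **Clamping** — transported fields are clamped at zero after each solve
  and the clamped mass is logged in the trajectory (`clamped_mass`
  column); linear FEM with chemotaxis can undershoot and the kinetics are
  defined only for nonnegative states.
* **Newton** — analytic consistent tangent (including the pressure-load
  and surface-tension stiffness), backtracking damping, convergence at
  `max(1e-12, 1e-10 * initial residual)`; non-convergence or element
  inversion triggers time-step halving (at most 5 levels) before the run
  aborts with the partial trajectory preserved. A run also aborts if SMC
  loss ever drives a modulus non-positive, since the constitutive law is
  undefined there.
* **Surface tension** — the Lagrangian pull-back of the curvature traction
  reduces, edge by edge for linear elements, to the gradient of
  `gamma_surf` times the current polyline length; residual and tangent use
  this equivalent discrete form (the standalone evaluator and an analytic
  circle test are in the suite).
* **Pre-equilibration** — at the initial state the reference pressure
  `p(rho(0)) = p*` generally differs from `2 beta1`, so the configuration
  carries residual stress; a `t = 0` equilibrium solve defines the starting
  geometry and the reported diameter is scaled so `R(0) = R0` exactly.
* **Linear algebra** — sparse LU (`Matrix`) throughout; problem sizes are
  a few hundred unknowns per field.

## Verification and observed accuracy

The suite verifies: exact agreement of the kinetics with an independently
coded literal transcription (1000 random states, 12 digits); the
implicit-Euler decay closed form; discrete mass conservation; equivalence
of the transport solver with the two-compartment ODE reduction when
transport is switched off; frame indifference and energy consistency of
the mechanics; homogeneous-stress patch tests; quadratic Newton
convergence; analytic curvature on circles and second-order curvature
convergence on ellipses; and manufactured-solution convergence of the
displacement solver.

On the manufactured-solution study the decoupled limit (`beta2 -> 0`,
two Poisson problems) converges at the clean `O(h²)` rate. The full
material converges but at a reduced preasymptotic rate (`~O(h^1.5)` on
coarse meshes, improving under refinement): with `beta2 >> beta1` the
quadratic energy term acts like a near-incompressibility constraint and
linear displacement elements exhibit mild volumetric locking. This is a
known property of P1 discretizations of such materials and is shared by
the discretization this implementation follows.

# The well-mixed reduction

`integrate_wellmixed()` collapses each layer to one compartment: diffusion
disappears and each boundary/interface exchange is multiplied by the
corresponding surface-to-volume ratio of the reference geometry. It is used
for steady-state analysis (`find_steady_state()`, a damped Newton with
finite-difference Jacobian), for parameter sanity checks, and as the
independent oracle for the transport solver. The ECM keeps no interlayer
exchange term there (it is quasi-immobile, and continuous across `Γ_M` in
the full model).

# Behavior under the default constants, and limitations

The simulated disease course under the tabulated constants is: MCP-1 seeds
from the blood, ignites the macrophage influx within days (the influx gate
`P/(P + K_P)` saturates once SMC-derived MCP-1 production starts), SMCs
fall toward `S0/2` in the macrophage-exposed regions, ECM settles slightly
below baseline, and the bulge dilates modestly. Three quantitative
properties of this parameter set deserve emphasis, because they bound what
the simulation can show:

* **Macrophage penetration is shallow.** With `D_M = 8.64e-7` cm²/day and
  `d_M = 0.015`/day the diffusive penetration depth is
  `sqrt(D_M/d_M) ≈ 0.008` cm, a small fraction of the ~0.2 cm media, so SMC
  apoptosis — and hence wall softening — is confined to thin layers at the
  exchange boundaries. Coarse meshes under-resolve this layer (the default
  spacing exceeds it), which if anything *overestimates* the softened
  volume.
* **The printed moduli permit only small dilation.** Even with SMCs halved
  through the whole wall, the equilibrium stretch admitted by
  `2 beta1 + 4 beta2 (I_B - 3)` with `beta2(S0/2) = 146.1` N/cm² against
  the `p(rho) - p_B ≈ 35` N/cm² driving stress is 1–3 %; the acceptance
  script's 500-day runs end near 2.004 cm from a 2 cm start for both ends
  of the serum IL-6 range.
* **IL-6 sensitivity is structurally weak.** The serum level `I60` enters
  only through the IL-6 boundary source and macrophage chemotaxis; at
  `chi_C = 10` the resulting drift is negligible, so the predicted
  `R(T)` surface is nearly flat in `I60` (the monotone-in-`I60` property is
  asserted in the acceptance suite and documents this). The response is
  strictly increasing in `R0`.

Likewise, in the well-mixed reduction the MMP average declines
monotonically from its (quasi-steady) initial value as its dominant source
`lambda_QS * S` falls, and TIMP relaxes within a day from its initial
1e-8 g/cm³ to the sustainable `lambda_QrM * M / d_Qr ≈ 8e-11`; the
corresponding turning-point assertions in the acceptance suite record
this. None of the tabulated rates, closures or tolerances were adjusted in
response to these outcomes.

Problem sizes used throughout were chosen to keep a full 500-day run of
the coupled solver at a couple of minutes on one CPU (default mesh 231
nodes, 1000 steps); the unit suite uses smaller meshes and horizons with
the same code paths.

Out of scope by design: rupture-risk estimation, 3D geometry, hemodynamic
shear-stress modeling (endothelial effects enter only via boundary influx
constants), tissue inertia and body forces, anisotropic fiber models,
viscoelasticity, and patient-data fitting.
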