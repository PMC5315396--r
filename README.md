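# aortawall

Coupled immuno-mechanical simulation of abdominal aortic aneurysm (AAA)
growth.

AAA is a localized dilation of the infrarenal aorta whose main clinical
question is how fast the diameter will grow. `aortawall` implements a
mechanistic answer: an inflammatory network in the arterial wall degrades
the smooth muscle cells (SMCs) and the extracellular matrix (ECM), which
weakens the wall's elastic moduli and lets the bulge dilate under blood
pressure. Given the diameter at screening, `R0`, and the serum IL-6 level,
`I60` (a proposed prognostic biomarker), the model predicts the bulge
diameter `R(t)` at later times.

## The model

**Biology.** Twelve species live in a 2D section of the two-layer wall
(media `Ω_M`, adventitia `Ω_A`): MCP-1 (`P`), macrophages (`M`), T cells
(`T`), SMCs (`S`, media only), IL-6, IL-10, IL-12, TNF-α, IFN-γ, MMP (`Q`),
TIMP (`Q_r`) and ECM (`ρ`). Each satisfies a reaction–advection–diffusion
equation

```
∂Z/∂t + ∇·(v Z) − D_Z ΔZ = F_Z(Z),
```

with mass-action/Michaelis–Menten sources: macrophage-induced SMC
apoptosis, T-cell activation by macrophage contact under IL-12 (inhibited
by IL-10), cytokine production by macrophages and SMCs, MMP–TIMP mutual
binding, and ECM production with a carrying-capacity clamp `(1 − ρ/ρ0)⁺`
and degradation by MMP. Macrophages are chemotactic toward MCP-1 and IL-6
(`−∇·(M χ_C ∇P) − ∇·(M χ_C ∇I6)`). Robin exchange conditions couple the
wall to the blood (monocyte/T-cell influx gated by MCP-1; endothelial
MCP-1 and IL-6 sources with serum levels `P0` and `I60`) and couple the two
layers across the media/adventitia membrane.

**Mechanics.** The wall is an incompressible-type hyperelastic solid with
stored energy `W = β1 (I_B − 3) + β2 (I_B − 3)²`, `I_B = tr(B)`,
`B = F Fᵀ`, and Cauchy stress

```
σ = −p(ρ) I + (2β1(S) + 4β2(S)(I_B − 3)) B,
β_i(S) = β_i0 + k_i (S/S0 − 1),        p(ρ) = p* − β_p (1 − ρ/ρ*),
```

so SMC loss softens the wall and ECM loss lowers the confined tissue
pressure. Quasi-static equilibrium `∇·σ = 0` is solved with blood traction
`σn = −p_B n` on the lumen boundary, a traction-free outer boundary,
surface tension `γ κ n` on the free boundaries, and clamped artificial
cuts. The equilibrium is pulled back to the reference mesh (total
Lagrangian), solved by Newton iteration with an analytic consistent
tangent, and the mesh moves with the flow map `x = x̂ + û`, so species are
advanced on the deformed mesh with no interpolation in the material
derivative.

Each time step (default 0.5 day) solves mechanics with the previous-step
biology in the coefficients, moves the mesh, then advances all species
implicitly (implicit diffusion and degradation, explicit production,
lagged chemotaxis).

## Worked example

```r
library(aortawall)

traj <- run_simulation(R0 = 2, I60 = 6e-9, T_end = 50, k = 0.5,
                       ny = 16, n_med = 3, n_adv = 2)
print(traj)
#> <aaa_trajectory> 101 records, t = 0 .. 50 day; diameter 2 -> 2.005 cm

as.data.frame(traj)[c(1, 21, 51, 101),
                    c("time", "diameter", "mac_media", "smc_media")]
#>  time diameter mac_media smc_media
#>     0 2.000000     0e+00  0.006000
#>    10 2.004267     8e-06  0.005489
#>    25 2.004452     8e-06  0.005472
#>    50 2.004718     9e-06  0.005449
```

Macrophages enter from the blood and the adventitial side (column
`mac_media`, g/cm³), SMC density falls from its healthy baseline
`S0 = 6e-3 g/cm³` in a boundary layer next to the lumen, and the bulge
diameter creeps up from its 2 cm starting value. Trajectory columns report
the layer-averaged concentration of every species plus solver diagnostics;
`write_trajectory_csv()` and `write_vtk_snapshot()` export the time series
and mesh fields.

The parameter registry with every constant, unit and provenance is
available via `load_parameters()` / `dump_parameters()`, and
`check_params()` re-derives the constants that come from literature
measurements (IL-6 secretion assays, tissue moduli, peak wall stress):

```r
check_params()
#>   parameter  derived registry
#>  lambda_I6M 1.73e-06 1.73e-06
#>  lambda_I6S 1.73e-05 1.73e-05
#>          k1 3.04e+01 3.04e+01
#>          k2 8.40e+01 8.40e+01
#>      beta_p 1.80e+01 1.80e+01
#>      p_star 3.70e+01 3.70e+01
#>    lambda_S 5.16e-03 5.16e-03
```

A command-line driver wraps the same functions:

```sh
Rscript $(Rscript -e 'cat(system.file("cli/aortawall.R", package="aortawall"))') \
    run --r0 2 --i60 6e-9 --t-end 500 --out out/
```

with subcommands `run`, `sweep` (the `(I60, R0)` prediction map),
`wellmixed` (the two-compartment ODE reduction) and `check-params`.

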