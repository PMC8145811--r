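# sfsaxs

Time-resolved small-angle X-ray scattering (SAXS) analysis of
surfactant-driven protein unfolding and refolding.

When a globular protein such as β-lactoglobulin is mixed with the anionic
surfactant SDS in a stopped-flow apparatus, core–shell protein–micelle
complexes form within milliseconds and then rearrange over seconds; adding
the non-ionic surfactant C12E8 extracts the SDS into mixed micelles and
lets the protein refold over minutes. Synchrotron stopped-flow SAXS follows
these events as a series of absolute-scale scattering curves I(q) (cm⁻¹ vs
Å⁻¹). This package implements the complete analysis chain for such series,
for scattering practitioners who want a scripted, testable version of it:

- **Form factors** — core–shell ellipsoid of revolution with a *displaced
  core*: the scattering amplitude at polar angle θ is
  `A(q,θ) = k₁Φ(qr₁(θ)) + k₂Φ(qr₂(θ))·J₀(qs·sinθ)` with
  `Φ(x) = 3(sin x − x cos x)/x³`, `rᵢ²(θ) = Rᵢ²(sin²θ + εᵢ²cos²θ)` and the
  core offset `s ≤ R₁ − R₂` perpendicular to the symmetry axis, modelling
  protein bound asymmetrically on one side of a micelle. Shell uniformity
  is maintained via `ε₁ = (ε₂R₂ + D)/(R₂ + D)`. A random-flight structure
  factor `S(q) = 1 + (2/N)Σ(N−k)xᵏ`, `x = sin(qD_mic)/(qD_mic)`, with
  linear weighting for non-integer N describes transient clustering, and a
  Gaussian chain (Debye function) describes unfolded protein.
- **Absolute scale** — contrast prefactors `k₁ = v₁Δρ₁`,
  `k₂ = v₂(Δρ₂ − Δρ₁)` and number densities are derived from molecular
  volumes, scattering lengths and surfactant concentrations, so model
  curves come out in cm⁻¹ with no free scale factor.
- **Frame-series fitting** — weighted Levenberg–Marquardt with box bounds,
  parameter locking, Latin-hypercube multi-start and warm starts along the
  time series; per-frame reduced χ² and linearized uncertainties.
- **Species decomposition** — refolding frames are decomposed as
  `I = a₁I_complex + a₂I_micelle + a₃I_native + a₄I_chain + a₅` with
  protein-mass conservation `a₁ = 1 − a₃ − a₄` imposed exactly and a
  two-step χ² that propagates the basis curves' own counting noise.
- **Kinetics** — 1–3-component exponential fits with F-test order
  selection and half-times `t₁/₂ = ln2/k`.
- **Model-free tools** — Guinier fits (Rg, I(0)) and direct-transform
  pair-distance distributions p(r)/Dmax for model curves.
- **Structure scattering** — Debye-equation curves from Cα bead models
  (PDB input via bio3d) with a simple hydration layer, and monomer/dimer
  fraction fitting.
- **Synthetic data** — generators for complete unfolding/refolding frame
  series and kinetic traces with truth tables, so the entire pipeline is
  testable without any experimental download.

## Worked example

Generate a noisy absolute-scale curve of the saturated (10.5 mM SDS)
end-state complex and refit it with core radius, core offset, shell
thickness and proteins-per-complex free:

```r
library(sfsaxs)

q     <- default_q_grid(300)                       # 0.005-0.4 1/A
truth <- complex_preset("sds10.5")                 # end-state parameters
I     <- complex_intensity(q, truth)               # cm^-1
curve <- add_noise(saxs_curve(q, I, sigma = 0.01 * I), f_rel = 0.01, seed = 7)

params <- saxs_params(
  Rcore = c(10, 4, 25), eps = lock(1.8), Dhead = c(12, 4, 30),
  s_frac = c(0.5, 0, 1), Npro = c(1.5, 0.05, 10),
  Nmic = lock(1), Dmic = lock(50), C_total = lock(10.5), C_free = lock(3.7))

fit <- fit_curve(curve, complex_model(), params, starts = 8, seed = 1)
fit
#> <saxs_fit> N = 300, free = 4, chi2_red = 0.9872, converged
#> # A tibble: 9 x 6
#>   name     value   lower upper locked       sd
#> 1 Rcore   13.7      4       25 FALSE   0.0144
#> 2 eps      1.8   -Inf      Inf TRUE   NA
#> 3 Dhead   10.1      4       30 FALSE   0.0243
#> 4 s_frac   0.183    0        1 FALSE   0.00445
#> 5 Npro     0.981    0.05    10 FALSE   0.00111
#> ...
```

The fit recovers the generating geometry: a 13.7 Å micellar core
(`Rcore`), a ~10 Å protein/head-group shell (`Dhead`), about one protein
per complex (`Npro`) and a small core offset `s = s_frac * Dhead ≈ 1.8 Å`
(the protein sits almost symmetrically around the micelle in the end
state), at reduced χ² ≈ 0.99 for correctly specified noise.

A stopped-flow fluorescence trace with three kinetic phases:

```r
sim <- simulate_kinetic_trace(c(1, -0.4, 0.6), c(0.23, 0.75, 3.84),
                              y_inf = 1, noise = 0.01, seed = 5)
tidy(fit_exponentials(sim$trace, n = 3))
#> # A tibble: 3 x 4   (columns abridged)
#>   component amplitude  rate halftime
#> 1         1     1.01  3.01     0.230
#> 2         2    -0.387 0.992    0.699
#> 3         3     0.580 0.174    3.98
```

The fastest phase (t₁/₂ ≈ 0.23 s) corresponds to initial surfactant
binding, the slower phases to protein rearrangement on the micelle.

Higher-level drivers `run_unfold_analysis()` / `run_refold_analysis()`
run the two full workflows (per-frame fits or decompositions, then
exponential fits of the resulting trajectories) and write CSV/JSON
reports; `simulate_unfolding_series()` / `simulate_refolding_series()`
produce complete synthetic inputs with truth tables. `autoplot()`,
`plot_series()`, `plot_parameter_trajectories()` and `plot_fractions()`
give ggplot2 graphics for every result type.

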