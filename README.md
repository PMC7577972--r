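# turbflux

Turbulence-driven nutrient fluxes and bloom budgets from microstructure and
hydrographic profiles.

## The problem

Over rough topography, breaking internal tides drive strong turbulent mixing
that can pump nitrate and phosphate upward from the nutricline into the
euphotic zone, sustaining phytoplankton blooms in otherwise oligotrophic
water. Quantifying that pathway from ship observations takes a chain of
inferences:

1. **Dissipation.** Free-fall profilers sample velocity shear at 512 Hz while
   descending at ~0.6 m s⁻¹. The turbulent kinetic energy dissipation rate is
   ε = 7.5 ν ⟨(∂u′/∂z)²⟩ (W kg⁻¹), with the shear variance obtained by
   integrating each segment's wavenumber spectrum against the empirical
   Nasmyth form: the integration band's upper cutoff depends on the
   Kolmogorov wavenumber k_s = (ε/ν³)^¼, which depends on ε itself, so the
   integration is iterated to convergence and the unresolved model-variance
   fraction added back. A deterministic spectral-consistency statistic
   (mean |log₁₀(Φ_obs/Φ_N)| over the fit band) flags bad segments.
2. **Stratification.** Potential density is Thorpe-resorted into its stable
   order; the buoyancy frequency N² = (g/ρ₀) ∂ρ_s/∂(depth) comes from the
   resorted profile, and the mixed layer is the shallowest depth where σ_θ
   deviates 0.03 kg m⁻³ from the uppermost observation.
3. **Diffusivity.** The Osborn relation K_ρ = Γ ε N⁻² with Γ = 0.2, masked
   inside the mixed layer.
4. **Nutrients.** Bottle nutrients correlate linearly with potential
   temperature in the warm (θ > 15 °C) upper layer, so nutrient profiles are
   reconstructed from θ with least-squares regressions (95 % Student-t
   limits); one station with anomalous temperature structure carries its own
   regression. Profiler fluorescence becomes chlorophyll *a* through a
   two-step affine calibration fitted on ≥ 100 m pairs (avoiding
   non-photochemical quenching).
5. **Fluxes and budgets.** The vertical turbulent flux is F = −K ∂C/∂z
   (mmol m⁻² d⁻¹, positive upward), evaluated at the 100 m euphotic-zone
   base. Redfield stoichiometry (C:N:P = 106:16:1, M_c = 12 g mol⁻¹)
   converts the flux to new production; the steady-state balance
   M_c r_C-N r_C-Chl⁻¹ F = γ h_e C̄ gives the chlorophyll depletion (≡
   growth) rate γ over the carbon-to-chlorophyll range 25–52; the tidal
   excursion L_e = U_K1/ω_K1 against the topographic half-width W gauges
   whether horizontal advection can compete.

The package implements every stage plus a seeded synthetic-data generator —
shear records whose spectra *are* the Nasmyth form at prescribed ε(z),
density profiles with a mixed layer, prescribed N²(z) and injected
overturns, and bottle chemistry obeying the linear θ relations — so the
whole chain is testable against known ground truth without cruise data.

It is written for observational oceanographers and biogeochemists who want
a desk-scale, reproducible version of this inference chain.

## Worked example

Run the full pipeline on a small synthetic cross-ridge section (three
stations, the central one over the "ridge" with 100× background
dissipation):

```r
library(turbflux)
cfg <- pipeline_config(42, n_stations = 3, depth_max = 250)
b <- run_pipeline(cfg, quiet = TRUE)
print(b)
#> <pipeline_bundle> 3 stations, seed 42
#>   station      mld    max_k_rho   flux_no3    flux_po4
#> 1      L1 53.67243 0.0001800862 0.06741990 0.003995253
#> 2      L2 53.83802 0.0011277401 0.51369879 0.030441410
#> 3      L3 53.33402 0.0001832992 0.07778104 0.004609247
#> ...
```

The ridge station L2 carries an order of magnitude more eddy diffusivity
(1.1 × 10⁻³ m² s⁻¹) and nitrate flux (0.51 mmol N m⁻² d⁻¹ at 100 m) than
its neighbours — the generator's prescribed dissipation peak propagated
through every stage. The detected mixed layer (~54 m) is where the density
threshold criterion is met on the generator's gradual pycnocline.

Feeding the budget the section-maximum fluxes observed on the real cruise
(4.7 mmol N and 0.33 mmol P m⁻² d⁻¹ at 100 m):

```r
m <- select_nutrient_model("L8", "nitrate")   # pooled: -0.540 ± 0.085
u <- propagate_uncertainty(4.7, m)
budget_report(4.7, 0.33, flux_no3_hw = u$hw,
  flux_po4_hw = propagate_uncertainty(0.33, select_nutrient_model("L8", "phosphate"))$hw)
#> <budget_result>
#>   nitrate flux at h_e: 4.7 +/- 0.74 mmol N m-2 d-1
#>   new production (N): 0.374 +/- 0.0588 g C m-2 d-1
#>   new production (P): 0.42 +/- 0.0787 g C m-2 d-1
#>   depletion rate gamma: 0.18-0.374 d-1 (modified: 0.359-0.747 d-1)
#>   tidal excursion L_e = 6.85 km, L_e/W = 0.34-0.68
```

So the nitrate flux supports ~0.37 g C m⁻² d⁻¹ of new production within the
surface 100 m; balancing that production against loss at a mean chlorophyll
of 0.4 mg m⁻³ implies that 18–37 % of the standing chlorophyll turns over
per day (36–75 % once regenerated production is included via an f-ratio of
0.5); and a ~7 km diurnal tidal excursion against a 10–20 km ridge
half-width (ratio 0.34–0.68) means advection matters but does not dominate.

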