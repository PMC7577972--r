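---
title: "From microstructure shear to nutrient fluxes and bloom budgets: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From microstructure shear to nutrient fluxes and bloom budgets: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(turbflux)
```

This vignette documents the models, assumptions, parameter choices and
numerical decisions behind the package, stage by stage.

## Dissipation from shear spectra

Free-fall profilers measure vertical shear of horizontal velocity at 512 Hz
while sinking at roughly 0.6 m s⁻¹. Under isotropy the dissipation rate is

$$\varepsilon = 7.5\,\nu\,\overline{(\partial u'/\partial z)^2},$$

with ν the kinematic viscosity of seawater, computed from temperature by the
standard fit ν(T) = 1.792·10⁻⁶ / (1 + 0.0337 T + 0.000221 T²) m² s⁻¹
(salinity changes ν by ~2 %, negligible against the factor-level accuracy of
ε itself; a constant ν can be passed everywhere for controlled tests).

The shear variance is estimated spectrally. Each record is cut into
half-overlapping segments (default 4 s ≈ 2.4 m of water at 0.6 m s⁻¹ —
short enough that ε is locally stationary, long enough to resolve
wavenumbers down to ~0.4 cpm), linearly detrended, Hann-tapered (taper
power corrected, and the taper-induced DC offset removed so the spectrum
integrates to the taper-corrected variance exactly), and transformed.
Frequency maps to wavenumber through the frozen-field hypothesis,
k = f / W_fall, Φ(k) = Φ(f) · W_fall.

The reference shape is the empirical Nasmyth spectrum in its closed
rational form,

$$\Phi_N(k) = (\varepsilon^3/\nu)^{1/4}\, G_2(k/k_s), \qquad
G_2(x) = \frac{8.05\,x^{1/3}}{1 + (20.6\,x)^{3.715}}, \qquad
k_s = (\varepsilon/\nu^3)^{1/4},$$

whose defining property — enforced by test rather than by trusting the
constants — is that 7.5 ν ∫Φ_N dk = ε (the fit integrates to 1/7.5 within
0.1 %; the package asserts 3 % across ε = 10⁻¹⁰–10⁻⁶ W kg⁻¹).

Because the usable integration band depends on ε through k_s, the estimate
is iterative: integrate the observed spectrum from k_min = 1 cpm to a
provisional cutoff, convert to ε, recompute the cutoff as the wavenumber
resolving 90 % of model variance (x₉₀ ≈ 0.09 k_s), divide by the resolved
model-variance fraction of the actual band, and repeat until ε changes by
< 1 %. The cutoff never exceeds 80 % of the spectral band (anti-aliasing
guard). The field practice of visually vetting each spectrum against the
model is replaced by a deterministic surrogate: a segment is rejected when
the mean |log₁₀(Φ_obs/Φ_N)| over the fit band reaches log₁₀ 3. Note the
refit absorbs any uniform scale factor, so this statistic tests *shape*
consistency — which is exactly what a trained eye checks.

Per-segment estimates are averaged into 5 m depth bins per probe; accepted
per-probe values are averaged unless they disagree by more than a factor 10,
in which case the smaller is kept (collisions with plankton or debris bias a
probe high, not low). Casts are then bin-averaged; a bin in which everything
was rejected stays missing — never zero, which would bias fluxes.

None of segment length, bin width, or the rejection threshold is dictated by
the measurement principle; all are exposed as arguments with the defaults
above, chosen to resolve the 10⁻¹⁰–10⁻⁶ W kg⁻¹ range at this sampling rate.

## Stratification

Observed potential density is Thorpe-resorted (stable sort into
non-decreasing order; displacements are observed minus resorted depth and
sum to zero on a uniform grid). The buoyancy frequency

$$N^2 = \frac{g}{\rho_0}\,\frac{\partial \rho_s}{\partial(\mathrm{depth})},
\qquad g = 9.81\ \mathrm{m\,s^{-2}},\ \rho_0 = 1027.0\ \mathrm{kg\,m^{-3}},$$

uses centred differences of the *resorted* density over a 10 m stencil;
resorting guarantees non-negativity, and values below a floor of 10⁻⁷ s⁻²
(homogeneous layers) are floored and flagged so the Osborn relation cannot
blow up. The mixed-layer depth is the shallowest depth where σ_θ exceeds
the uppermost observation by 0.03 kg m⁻³, linearly interpolated between the
bracketing samples; on a density step the interpolated crossing converges
to the step depth as the grid refines. The Osborn diffusivity
K_ρ = 0.2 ε N⁻² is masked inside the mixed layer (its production–dissipation
balance fails there) and wherever ε was rejected or N² floored.

## Nutrients, fluorescence, and fluxes

Nutrient concentrations are reconstructed from potential temperature with
linear regressions valid for θ > 15 °C (roughly the upper 400 m in this
regime); predictions at colder θ are masked, and negative predictions —
possible at warm surface θ — are clipped to zero and flagged. The package
registry carries a pooled model per species and a station-specific override
for the station whose temperature structure differs (L4); registry lookup
falls back to the pooled model for unknown stations. Confidence limits are
95 % Student-t half-widths; a coverage test (500 synthetic fits at n = 50)
checks the machinery stays at 93–97 %.

Profiler fluorescence becomes chlorophyll *a* through two affine stages
(profiler → reference fluorometer → bottle chlorophyll), fitted only on
pairs at 100 m and deeper because daytime near-surface fluorescence is
depressed by non-photochemical quenching. The chain composes to a single
affine map (asserted to 10⁻¹²); bottle–profile pairing takes the nearest
sample within 2 m.

Fluxes use the depth-down convention throughout (depth in metres, positive
downward, profiles surface → bottom). The z-up flux law F = −K ∂C/∂z becomes
F = +K ∂C/∂(depth): nutrient concentrations increase downward, so upward
fluxes are positive. Gradients are centred differences after a 10 m boxcar
smoothing (smoothing a quadratic leaves its derivative unchanged, so this
costs no accuracy at second order); the per-second flux converts to
mmol m⁻² d⁻¹ by exactly one factor of 86 400, applied at flux assembly. The
headline flux is the value at the 100 m euphotic-zone base; a ± window
maximum is available as an option but is not the default, since a maximum
search over a noisy profile is biased high.

The reported flux uncertainty contains the regression-slope term only
(relative flux half-width = relative slope half-width): the reconstructed
gradient is linear in the slope, and sampling variability of ε is
deliberately not folded in, keeping the error budget interpretable.

## Budgets

With M_c = 12 g mol⁻¹ and Redfield ratios r_C-N = 106/16, r_C-P = 106/1,
new production is M_c · r · F / 1000 (g C m⁻² d⁻¹). The steady-state
chlorophyll depletion rate solves M_c r_C-N r_C-Chl⁻¹ F = γ h_e C̄ with
h_e = 100 m, C̄ = 0.4 mg m⁻³ and r_C-Chl spanning 25–52 g C (g Chl)⁻¹
(pico-phytoplankton-dominated water); γ is reported at both endpoints, the
larger at r_C-Chl = 25. Dividing by the f-ratio (default 0.5) converts the
new-production-only rate into a total-production-equivalent growth rate.
Evaluating the formula at the rounded inputs F = 4.7, C̄ = 0.4 gives
0.180–0.374 d⁻¹; reported cruise values of 0.16–0.33 d⁻¹ are consistent
with unrounded intermediates, and the package reproduces the formula rather
than the rounded digits — the acceptance check asserts agreement within the
stated half-widths (±0.06, ±0.13), not digit equality. The tidal excursion
is L_e = U_K1/ω_K1 (≈ 6.85 km at U = 0.5 m s⁻¹, ω = 7.3·10⁻⁵ rad s⁻¹),
compared against a topographic half-width W = 10–20 km supplied by the
user — W has no formal definition and is a judgement call.

## What the synthetic generator does and does not emulate

The generator exists so that every stage has a parameter-recovery test with
exact ground truth. Per station it draws, from independent seeded
substreams:

* **Shear records** built block-by-block (4 s blocks) in the spectral
  domain: independent zero-mean Gaussian amplitudes with variance
  proportional to the Nasmyth spectrum at the locally prescribed ε and ν,
  inverse-transformed. The time-domain variance therefore equals
  ε/(7.5 ν) in expectation (asserted within 10 % over 50 seeds), and the
  recovery suite demands median recovered ε within a factor 2 of truth at
  every decade from 10⁻¹⁰ to 10⁻⁶ W kg⁻¹ (observed: within ~3 %).
* **Density profiles**: uniform σ_θ above the configured mixed layer, slope
  N² ρ₀/g below, plus white Gaussian noise (default 0.002 kg m⁻³);
  overturns are injected as seeded local permutations of the stable
  profile, so resorting must recover the stable original exactly.
* **Bottles and fluorescence**: nutrients from the configured linear θ
  relations plus noise (clipped at zero); fluorescence is true chlorophyll
  pushed backwards through the calibration chain, with an optional
  near-surface quenching suppression.

Default study conditions: five stations with the dissipation amplitude
peaking at the central "ridge" station (10⁻⁷ against a ~10⁻⁹–10⁻¹⁰
background, spanning the observed four-decade range), a 40 m mixed layer,
N² = 2·10⁻⁵ s⁻² below it, surface θ = 24 °C cooling at 0.025 °C m⁻¹ (so
the θ > 15 °C validity range ends near 400 m), and the cruise's own
regression and calibration coefficients as generating truth.

Deliberate non-goals: no internal-wave dynamics or tidal-cycle time
dependence (blocks are statistically independent); white noise only — no
instrument spike spectra, so the despiking problem is not emulated and
de-spiking is a QC option rather than a tested stage; temperature and
density are generated independently (salinity is implicit), so θ–S water
mass structure is not meaningful in the synthetic section. Passing tests
therefore demonstrate correctness of the *inference chain*, not robustness
to every pathology of real probes.

## Numerical choices and degenerate inputs

* The cumulative Nasmyth variance fraction is a monotone spline lookup
  built once per session (quadrature per call would dominate the iteration).
* The iterative ε estimate starts from the full usable band, floors at
  10⁻¹³ W kg⁻¹, caps at 25 iterations (non-convergence ⇒ rejected), and
  keeps a ≥ 3-bin band even when the nominal cutoff falls below k_min.
* Ties in Thorpe resorting keep observed depth order (stable sort), making
  resorting of an already-stable profile the identity.
* Missing densities are excluded from resorting with a warning and
  reinserted as gaps; profiles with < 3 valid points are errors, not NaNs.
* A record shorter than one segment, a zero fall speed, an empty model
  registry, non-positive budget constants, and overturns exceeding the
  depth range all raise immediate errors with diagnostics.

## Problem sizes used by the test and acceptance suites

Recovery studies run at desk scale by design: 30 s single-probe records (50
seeds per dissipation level), three-station sections to 250 m for the
end-to-end flux checks (flux recovery observed within ~5 % of the analytic
truth Γ ε N⁻² · slope · dθ/d(depth), against a 25 % acceptance bound), 500
regression fits at n = 50 for coverage, and 1 000 random profiles for the
resorting oracle. These sizes give stable medians while keeping the whole
suite under a minute of compute; nothing in the method depends on them.

## Known limitations

* The spectral-consistency threshold (log₁₀ 3) is a pragmatic surrogate for
  expert judgement; it is insensitive to uniform calibration errors by
  construction.
* The Osborn Γ = 0.2 is a constant-efficiency assumption; real mixing
  efficiency varies with turbulence intensity and stratification.
* The θ–nutrient reconstruction inherits all the caveats of water-mass
  regression: it cannot represent biologically driven departures from the
  θ relation, and it is undefined below the 15 °C isotherm.
* The budget assumes steady state between turbulent supply and consumption
  and between growth and loss; the excursion diagnostic L_e/W bounds, but
  does not model, horizontal advection.
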