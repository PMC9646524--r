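# viscomigration

Elevated extracellular fluid viscosity — counterintuitively — makes many
cell types migrate *faster*, both on 2D substrates and inside confining
microchannels. `viscomigration` implements the computational core of that
phenomenon for cell biophysicists: the two models that explain it at the
filament and whole-cell scales, and the quantification statistics used to
measure it in microscopy data, together with seeded synthetic-data
generators so the whole pipeline is testable without any imaging data.

## What the package computes

**1. Stochastic actin network under viscous load** (`simulate_actin()`,
`ensemble_density()`). A filament-resolved 2D model of the lamellipodium:
barbed ends elongate, branch (ARP2/3-like, at ±70° off the mother) and cap
as Poisson processes, and the leading edge advances by a shared-load
Brownian ratchet

```
v = k_on exp( − F w δ / (n kB T) ),     F = F₀ + F_η,    F_η = k · η · v_{i−1}
```

where `F₀` is membrane tension per unit edge width, and the viscous load
`F_η` is a linear dashpot scaling with medium viscosity `η` and the edge
velocity of the previous iteration (`k = 100,000`, dimensionless). A
filament keeps up with the edge only while `k_on cos θ ≥ v`, so when the
viscous load slows the edge, steeper-angled daughter branches survive at
the membrane: the network densifies and pointed-end creation transiently
outruns capping — the signature of a denser, more branched network at
elevated viscosity.

**2. Two-phase osmotic-engine model of confined migration**
(`solve_steady_state()`, `speed_vs_viscosity()`). A 1D steady-state
continuum model of a cell of length `L` in a microchannel, treating the
F-actin network (`θₙ, vₙ`) and cytosol (`θ_c, v_c, p`) as interpenetrating
phases with interfacial drag `η θₙ (v_c − vₙ)`, network swelling pressure
`σₙ = k_σₙ θₙ`, focal-adhesion resistance `η_st(x) θₙ vₙ`, saturating
polymerization at the front, distributed depolymerization `γ θₙ`,
transmembrane water fluxes `J_water = −α[(p − p*) − RT(c − c₀)]`, channel
hydraulic resistance `d_g = 12 μ l₀ / w²`, polarized active ion fluxes
(`|J_f / J_b| = γ_polar`, the NHE1 polarization ratio) and a whole-cell
force balance including wall friction `ξ v₀`. Low- (0.77 cP) and
high-viscosity (8 cP) regimes differ by their measured constants:
adhesion profile (quadratic, `b = 0.3` vs quartic, `b = 0.25`; scale 8×),
friction (`ξ` = 180 vs 900 Pa s/µm), polarization (1.67 vs 2.84) and cell
length (85 vs 125 µm). `knockdown_nhe1()` zeroes both active fluxes.

**3. Quantification statistics** (`quantify` layer): track speed and
persistence (≥ 4, ≤ 71 frames), z-stack cell volume (trapezoidal),
projected lamella area fraction (2 µm critical height), per-frame lamella
growth `(Aᵢ − Aᵢ₋₁)/Pᵢ₋₁`, calcium spike counting (strictly > 2× baseline,
per event), front-to-rear intensity ratios, ON-pixel density within
1.5 µm of the cell edge, pH-recovery rate `−dR/dt`, kymograph retrograde
flow, and %-w/v → molarity/osmolarity conversions.

**4. Synthetic data with ground truth** (`make_prw_track()`,
`make_sphere_stack()`, `make_spike_trace()`, …): every estimator has a
paired seeded generator whose `truth` record enables recovery tests.

## Worked example

```r
library(viscomigration)

sol <- solve_steady_state(two_phase_params(), regime_config("HV"), n_grid = 200)
print(sol)
#> Two-phase steady state (HV regime, 8.00 cP, L = 125 um, 200 nodes)
#>   v0 = 0.0092283 um/s (0.5537 um/min), v_c = -0.0056284 um/s
#>   J_water front/back = 0.01486 / -0.01486 um/s
#>   residuals: mass 1.14e-16, force balance 9.38e-15, newton 1.93e-11 (18 it)

kd <- solve_steady_state(knockdown_nhe1(two_phase_params()),
                         regime_config("HV"), n_grid = 200)
1 - kd$v0 / sol$v0
#> [1] 0.38  # 38% speed loss without the osmotic engine (31% in the LV regime)

ens <- ensemble_density(actin_sim_params(eta_cP = 8), n_rep = 20, base_seed = 1)
mean(ens$mean_density[ens$time_s >= 6.5])
#> [1] 756   # post-load filaments per um of edge (vs ~570 at 0.8 cP)
```

Reading the output: the confined cell at 8 cP translocates at
0.55 µm/min, with water entering the front face at 0.015 µm/s and leaving
the rear — the cytosol streams *backwards* through the moving cell
(`v_c < 0`), the signature of water-dominated propulsion. Removing the
polarized ion flux (NHE1 knockdown) costs 38% of the speed at 8 cP but
only ~31% at 0.77 cP, the model's headline asymmetry. In the actin
simulator, switching on the 8 cP viscous load at t = 6 s densifies the
simulated network by ~30% relative to 0.8 cP.

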