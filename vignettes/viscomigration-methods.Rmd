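---
title: "Models and methods behind viscomigration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind viscomigration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(viscomigration)
```

This vignette is the package's own account of its science: the two models
it implements, the assumptions and unit conventions behind them, which
parameters are measured constants and which are documented stand-ins, the
numerical choices, and what the synthetic-data layer does and does not
show about real data.

## 1. The phenomenon

Extracellular fluid viscosity in tissues ranges from near-water
(0.7–0.8 cP at 37 °C) to several cP in interstitial fluid and can exceed
8 cP pathologically. Elevated viscosity mechanically loads the protruding
cell edge and, rather than slowing cells down, triggers a cascade —
denser branched actin, polarized NHE1-driven water uptake, swelling,
calcium influx, contractility — that speeds migration up. The package
models the two quantitative limbs of this cascade: the filament-scale
response of the lamellipodial network to viscous load, and the cell-scale
two-phase osmotic-engine mechanics of confined migration.

## 2. Stochastic actin simulator

### Model

Filaments are explicit objects with a barbed-end position (distance
behind the leading edge), an orientation $\theta$ relative to the edge
normal, and a growing/capped state. Per time step $\mathrm{d}t$:

* every growing filament caps with probability
  $1 - e^{-k_{cap}\mathrm{d}t}$ (Bernoulli thinning of a Poisson
  process);
* every *working* filament (growing, within the working band of the
  edge) branches with probability $1 - e^{-k_{br}\mathrm{d}t}$; the
  daughter starts at the mother's barbed position with orientation
  $\theta \pm 70^\circ$ and its pointed end anchored to the mother.
  Branching is membrane-proximal because ARP2/3 activation is;
* the edge advances at the shared-load Brownian-ratchet velocity
  $v = k_{on} \exp\!\left(-F w \delta / (n_w k_BT)\right)$ with
  $F = F_0 + F_\eta$, where $n_w$ is the working-filament count,
  $w$ the edge width and $\delta$ the monomer half-size;
* the viscous load is a linear dashpot,
  $F_\eta = k\,\eta\,v_{i-1}$ with $k = 100{,}000$ (dimensionless) and
  $v_{i-1}$ the previous iteration's velocity, active from
  $t_{load}$ (default 6 s) onward and clamped at zero for a retracting
  edge — drag opposes protrusion, it does not push;
* a growing filament elongates toward the edge at
  $k_{on}\cos\theta$ and can only stay in the working band while
  $k_{on}\cos\theta \ge v$.

The last rule is what makes the model respond to load the way dense
branched networks do: at low viscosity the edge is fast and only
near-normal filaments keep up, so most $\pm70^\circ$ daughters are lost;
when the viscous load slows the edge, steep daughters survive at the
membrane, the working population grows, branching (proportional to the
working count) transiently outruns capping (proportional to all growing
filaments), and the network densifies. Densification, slower edge
velocity at higher viscosity, and the post-load spike of pointed-end over
capped-end creation are all emergent — none is scripted.

### Parameters

`k = 100,000`, the load switch-on time (6 s) and the branch angle
(70°) are fixed by the modelled experiment. The kinetic constants are
not printed anywhere and are shipped as defaults of literature
magnitude: $k_{on} = 0.3$ µm/s, $k_{br} = 1.0$ /s, $k_{cap} = 0.4$ /s,
$F_0 = 50$ pN/µm, $\delta = 2.7$ nm, $k_BT = 4.1\times10^{-3}$ pN µm,
50 seed filaments/µm with orientations uniform in $\pm35^\circ$. With
these, branching and capping balance at a working fraction of ~0.8, and
the free-load critical angle $\cos^{-1}(v/k_{on})$ straddles the
$\pm70^\circ$ daughter orientation between 0.8 and 8 cP — the regime the
model is meant to probe. Every shipped test of the simulator is
direction- or invariant-based (density ratio, velocity ordering,
creation-rate spike, conservation counts), never tied to these numeric
defaults.

The density readout is the number of barbed ends (growing or capped)
within 1 µm behind the edge per µm of edge; the physical units of
ensemble density plots are model-defined, so only ratios and directions
are meaningful.

### Numerics

Per-`dt` Bernoulli thinning is used instead of an exact event queue
because the viscous load couples to the per-iteration velocity $v_{i-1}$;
the constructor rejects any `dt` for which a per-step event probability
reaches 0.1. Runs are bit-reproducible given `seed`; ensembles seed
replicate $i$ with `base_seed + i - 1`.

## 3. Two-phase osmotic-engine model

### Model

On the co-moving domain $x \in [0, L]$ (rear to front) the unknown
fields are the network and G-actin concentrations $\theta_n, \theta_c$,
the ion concentration $c$, the cytosol pressure $p$, the network velocity
$v_n$, plus the scalars $v_0$ (cell speed) and $v_c$ (cytosol velocity,
spatially uniform by incompressibility). The equations, all in their
standard two-phase form: pressure gradient balancing interfacial drag
$-p' = \eta\theta_n(v_c - v_n)$; network force balance
$-(k_{\sigma_n}\theta_n)' + \eta\theta_n(v_c - v_n) - \eta_{st}(x)\theta_n v_n = 0$
with $\eta_{st}(x)$ the adhesion coefficient times the regime's
normalized profile; F/G-actin conservation with distributed
depolymerization $\gamma\theta_n$ and saturating front polymerization
$J_{actin} = J^f_{actin}\theta_c/(\theta_{c,c} + \theta_c)$; ion
convection–diffusion; osmotic/hydraulic water fluxes at both faces with
channel hydraulic resistance $d_g = 12\mu l_0/w^2$ shifting the face
pressures; passive ion leaks plus prescribed active fluxes with
$J^f = -\gamma_{polar} J^b$; total-actin conservation
$\int(\theta_n + \theta_c)\,\mathrm{d}x = L\theta_*$; and the whole-cell
force balance including wall friction $\xi v_0$.

Because the steady state lives on a domain attached to the moving cell,
all convective fluxes are taken relative to the cell,
$\theta(v - v_0)$; the boundary flux conditions then take exactly their
stated forms (e.g. $\theta_n(v_0 - v_n) = J_{actin}$ at the front). Of
the four actin flux boundary conditions, only three are independent
given the conservation laws; the solver imposes those three plus the
total-actin constraint, and reports the rear G-actin flux mismatch as a
diagnostic (it converges to zero with the mesh).

### How the osmotic engine propels the cell here

Water enters the front face and leaves the rear, so in the cell frame the
cytosol streams rearward ($v_c < v_0$, and $v_c < 0$ in the shipped
default regime). This propels the cell through two routes: directly,
through the hydraulic-resistance term of the global force balance (small
at the printed channel geometry), and indirectly, because the streaming
cytosol drags the network rearward, reshaping $\theta_n$ and hence the
adhesion traction integral $-\int\eta_{st}\theta_n v_n$. Zeroing the
active fluxes (`knockdown_nhe1()`) removes the streaming and costs the
high-viscosity regime proportionally more speed than the low-viscosity
one — the model's headline asymmetry — because the HV regime combines a
stronger polarization ratio (2.84 vs 1.67) with front-concentrated
adhesion.

### Parameters

Measured regime constants (fixed by the modelled experiments): adhesion
profiles and minima ($b_{LV} = 0.3$ quadratic, $b_{HV} = 0.25$ quartic),
the 8× adhesion-scale ratio, $\xi_{LV} = 180$ / $\xi_{HV} = 900$ Pa s/µm,
$\gamma_{LV} = 1.67$ / $\gamma_{HV} = 2.84$, $L = 85$/125 µm,
$L_0 = 200$ µm, $w = 3.5$ µm, medium viscosities 0.77 and 8 cP.

The remaining core constants are **documented stand-ins** of literature
magnitude for a confined mesenchymal cell (their source table is not
publicly printed): interfacial drag $\eta = 3000$ Pa s µm⁻² mM⁻¹,
$k_{\sigma_n} = 100$ Pa/mM, $\gamma = 0.005$ /s, $D_{\theta_c} = 50$ and
$D_c = 300$ µm²/s, $\alpha = 3\times10^{-3}$ µm/(Pa s),
$k_{sol} = 0.05$ µm/s, $J^b_{active} = -3$ mM µm/s (rear efflux),
$J^f_{actin} = 0.05$ mM µm/s, $\theta_{c,c} = 0.3$ mM,
$\theta_* = 0.5$ mM, $c_0 = 340$ mM, $RT = 2577$ Pa/mM,
$\eta_{st,LV}^0 = 15$ Pa s µm⁻² mM⁻¹. They were chosen once, from
physical reasoning, to place the model in the regime the phenomenon
lives in — osmotic engine a substantial contributor, front water influx
exceeding $v_0$, speeds of order 0.5 µm/min — and then frozen. All
shipped claims about the model are directions and invariants that should
survive reasonable variations of these stand-ins; absolute speeds should
not be quoted as predictions.

Unit system: Pa, µm, s, mM, with $RT = 8.314 \times 310$ J/mol/K
expressed per mM so $RT\,\Delta c$ is in Pa. Channel-end pressures
default to zero (open channel); the effective channel length
$l_0 = L_0 - L$ is split symmetrically between the two sides
(configurable via `dg_split`), since the split is not defined by the
geometry alone.

### Numerics

Conservative finite differences on a uniform grid (default 200 nodes):
second-order midpoint fluxes in the interior, second-order one-sided
stencils at the faces; the pressure is recovered by cumulative
trapezoidal integration of the drag force; the water fluxes at the faces
are eliminated in closed form (they appear linearly in their own
definitions through the face pressures). The full discrete system —
3 fields plus $v_0$, $v_c$ and the rear pressure — is solved by a damped
Newton iteration with a finite-difference Jacobian and a backtracking
line search that rejects steps leaving the positive cone. Convergence is
declared below a scaled residual RMS of $10^{-9}$; converged solutions
carry mass-conservation and force-balance residuals at rounding level,
and halving the mesh spacing moves $v_0$ by under 0.3%.

One deliberate choice: $\theta_n$ is *not* floored away from zero inside
the solver. In the HV regime the network concentration decays
exponentially toward the rear (to ~$10^{-12}$ mM at 125 µm), and a hard
floor makes the true solution infeasible, which stalls the line search.
The swelling term only ever uses the log-derivative
$\theta_n'/\theta_n$, which remains finite along the decay, so iterates
need only strict positivity. The standalone `network_velocity()` helper,
which users may call on arbitrary inputs, retains an explicit
degenerate-point fallback with a warning.

The mirror-symmetric configuration (equal face properties,
$\gamma_{polar} = 1$ with equal active fluxes, symmetric quadratic
adhesion, polymerization applied at both ends via
`symmetric_polymerization = TRUE`) is the solver's strongest self-check:
it must and does return $|v_0|$ at solver-tolerance level rather than
machine zero, since nothing in the discretization enforces the symmetry
explicitly.

## 4. Quantification layer

Each estimator implements one published formula-bearing procedure and
nothing upstream of it (no segmentation, registration or localization).
Choices the procedures leave open, and how they are resolved:

* **Calcium spikes** — "baseline" is undefined in the source procedure;
  the default is the median of the trace's lowest quartile (robust to
  the spikes themselves), overridable by a fixed value or pre-stimulus
  window. "Greater than 2×" is read strictly; contiguous
  supra-threshold runs count once and events must be separated by at
  least 2 sub-threshold samples. Counting is per event, not per frame.
* **Track statistics** — tracks shorter than 4 samples are rejected
  with a typed condition; tracks longer than 71 samples use the first
  71 (the cap's alignment is unstated; first-window is the
  deterministic choice).
* **Volume** — the slice-pair averaging described for z-stacks *is* the
  trapezoidal rule; out-of-focus slice removal is the caller's job, as
  it was manual in the source procedure.
* **Lamella fraction** — slice $k$ sits at height $(k-1)\,\mathrm{d}z$
  with slice 1 on the substrate; "above" the 2 µm critical height is
  strict.
* **Edge density** — the 1.5 µm band is taken on the cell-interior side
  of the edge polygon only (measurements are inside the cell); pixel
  centres decide membership.
* **pH recovery** — the fitted window is operator-chosen in practice and
  is therefore an explicit argument.

## 5. Synthetic data: what it does and does not show

Each generator emulates the *record* an imaging pipeline would hand the
corresponding estimator, with the generating parameter embedded as
ground truth: persistent random-walk tracks (heading angle performing a
Gaussian rotational walk of variance $2\,\mathrm{d}t/\tau$ — any
stationary persistent walk suffices for a summary-statistic recovery
test), rasterized spheres (pixel-centre rule), baseline-plus-plateau
spike traces, exact circle contour series, linear kymograph and pH
traces, and Bernoulli edge-band point patterns. Recovery tests at these
conditions demonstrate that the estimators are correct implementations
of their formulas and are unbiased under idealized noise. They do not
demonstrate robustness to segmentation error, drift, photobleaching,
non-Gaussian noise or tracking mistakes — none of which the generators
simulate (no PSF or photophysics is modelled by design).

## 6. Problem sizes and determinism

The shipped tests run the models at their intended sizes: 200-node grids
(with one 400-node solve for the convergence check) and 20-replicate
ensembles of 12 s simulations at 5 ms steps, a few minutes in total on
one CPU. Every stochastic path is seeded explicitly; `run_pipeline()`
threads one run-level seed into any stage that accepts one, records it
in the run manifest, and draws no global entropy itself.

## 7. Known limitations

* The actin model is 2D with a straight, laterally periodic edge: no
  filament bending or severing, no monomer depletion, no membrane shape.
* The two-phase model is 1D and steady-state: volume changes,
  transients, and the signalling loop (membrane tension, TRPV4, calcium,
  RHOA) enter only through the measured regime constants, exactly as in
  the source formulation.
* The two-phase core constants are stand-ins; absolute speeds are
  order-of-magnitude, not calibrated predictions.
* The Newton solver starts from a fixed uniform state; warm-starting
  from a nearby converged state is deliberately not offered, because
  finite-difference Jacobians are unreliable on the exponentially small
  rear network tail.
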