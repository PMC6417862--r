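---
title: "Models and methods: global treadmilling of branched actin networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: global treadmilling of branched actin networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(actintread)
```

## The system

Branched (Arp2/3-nucleated) actin networks grown in vitro from micropatterned
nucleation-promoting factors polymerize at a leading edge of width `W` at
speed `V`. With ADF/Cofilin in solution, aged network material accumulates
bound cofactor, the trailing edge fragments, and the network settles into a
*global treadmilling* state: length roughly constant, material flowing
through. This package implements the four models that together explain how
the equilibrium length `L*` depends on actin density `A0`, ADF/Cofilin
concentration `C0`, and — via local depletion of the free cofactor — the
network width `W`, plus the generators and estimators needed to exercise
every stage on synthetic data.

All quantities are in µM, µm and s. Rates quoted per minute in the
experimental literature are converted at the boundary with `per_min()`.

## Transport: cofilin binding with local depletion

Free cofilin `CF(x, y, t)` diffuses in the chamber; bound cofilin
`CB(x, y, t)` lives on the network and drifts with the material at speed `V`
away from the (stationary) leading edge:

$$\partial_t C_B = -V\,\partial_y C_B + r_B A C_F - r_U C_B,\qquad
  \partial_t C_F = D\,\Delta C_F - r_B A C_F + r_U C_B.$$

Assumptions: the chamber is quasi-2D (depth much smaller than lateral
dimensions); actin disassembly is *not* modelled here (the density `A(y)` is
constant or tabulated); fresh actin is cofilin-free, so the advection inflow
at the leading edge is exactly zero. Defaults are the reference kinetics
`C0 = 0.125` µM, `D = 10` µm²/s, `rB = 0.5/min/µM`, `rU = 0.31/min`,
`A = 50` µM, `V = 1.16` µm/min.

**Numerics** (`simulate_chamber()`): Lie operator splitting per step —

1. backward-Euler diffusion with a sparse Cholesky factorization computed
   once (unconditionally stable; on a closed domain it conserves mass to
   solver precision, which the tests check at 1e-6 relative);
2. first-order upwind advection of `CB` (CFL `V·dt/h ≤ 0.5` enforced);
3. the linear binding/unbinding exchange solved *exactly* per cell
   (two-state relaxation), which preserves positivity and detailed balance
   `CB/CF → rB·A/rU` regardless of step size.

Boundary modes: `"far-field"` holds `CF = C0` on the chamber edge (the
physical chamber is millimetres across, effectively infinite); `"closed"`
is no-flux, used for conservation tests. The network mask is a `W × L(t)`
rectangle, `L(t) = V·t`, advanced by whole grid rows. An optional
saturation factor `max(0, 1 − CB/(s_max·A))` on the binding term is
available but off by default — the plain mass-action law is the model as
stated. `diffusion_correction` (steric slow-down of diffusion inside the
network) defaults to 1, since the effect is a few percent at most.

Problem sizes: the reference depletion run uses a 300 × 300 µm domain at
`h = 2` µm (15 cells across the width) and `dt = 0.5` s, which takes a few
seconds; halving `h` or `dt` moves the headline depletion figure by a few
percentage points (first-order splitting), which is small against the
geometric uncertainty discussed below. Tests use 120–160 µm domains.

**A note on the depletion magnitude.** At the reference parameters the
binding time `1/(rB·A) ≈ 2.4` s is far shorter than the diffusive supply
time `W²/D = 90` s, and the treadmill keeps consuming cofilin at the rate
fresh actin is made, so the free pool near the network drops by ~80% after
40 min in this geometry. The magnitude depends on the chamber size and
boundary treatment (larger domains deplete deeper); the domain above is the
smallest that keeps the far-field boundary several network dimensions away.

## Fragmentation: stochastic lattice and its mean field

The network is idealized as a square lattice with spacing `a = 0.5` µm:
nodes are effective crosslinking/branching points, edges are filament
arrays (not single filaments). Each intact node breaks in a step of length
`dt` with probability `1 − exp(−P·dt)` (per-node Bernoulli, tau-leap
style), where

$$P = k_{\mathrm{break}}\, C_B^{\beta} / A_{\mathrm{local}}^{\alpha},
\qquad \alpha = 2,\ \beta = 1 \text{ by default}.$$

`A_local` is the intact-edge count in a uniform disc of radius `2a`,
normalized (with boundary correction) so a fully intact lattice maps to
`A0`. Pieces disconnected from the leading-edge row are pruned and logged —
this is what produces *macroscopic fragmentation* rather than grain-by-grain
erosion: node removal primes the network, and the positive feedback between
local density loss and breakage rate produces trailing-edge avalanches.
`CB` is spatially constant by default (its measured variation along the
network is small compared to actin's); a `CB(y)` profile can be supplied.
`k_break = 2.5` µM/s by default, chosen so equilibrium lengths fall in the
observed tens-of-µm range at `A0 = 50` µM, `CB = 0.5` µM, `V ≈ 1` µm/min.

The continuum approximation integrates the broken-node fraction along the
material flow, `V\,dq/dy = P(A_0, C_B)(1 − q)`, and places the network end
where `q` reaches a percolation-like threshold `q_c` (default 0.4):

$$L = c\,\ln\!\frac{1}{1-q_c}\; \frac{V A_0^{\alpha}}{k_{\mathrm{break}} C_B^{\beta}},$$

the advertised scaling `L ∝ V·A0^α/CB^β` with a prefactor `c` calibrated
against one stochastic run (`calibrate_continuum()`).

**Known limitation — discreteness of the lattice.** The stochastic model's
*measured* log–log exponents are below the microscopic ones at the default
spacing: regressing equilibrium length on `A0` over {35, 50, 70} µM gives a
slope near 1.66 (not 2.0), and on `CB` near −0.84 (not −1.0). The bias is a
property of the avalanche trigger on a finite lattice: it shrinks as `a`
decreases (slope ≈ 1.77 at `a = 0.25` µm) and is insensitive to width and
to the absolute length scale. Consequently the one-point-calibrated
continuum prediction tracks stochastic means to within ~10% near the
calibration point but can miss by ~25% at the corners of a 4× parameter
span. Analyses that need the exact exponents should use the continuum or
feedback models; the lattice model is the mechanism demonstrator.

Sweep sizes: equilibrium runs use `T = 8000–10000` s of simulated time
(transients are `L*/V ≈ 1000–4000` s, diagnosed from the series, not
assumed) at a step bounded by `dt·P(A0, CB) ≤ 0.2` and half the
row-crossing time; one run takes a few seconds.

## Equilibrium: two feedbacks in the (L, CB) plane

Disassembly shortens the network as bound cofilin accumulates
(`L = k1·A0^α·V/CB^β`); binding loads the network in proportion to its
residence time `L/V`, damped by the depletion factor:

$$C_B = k_2\, r_B A_0 C_0 \frac{L}{V}\cdot
        \frac{D}{r_B A_0 W L + D}.$$

The first curve falls with `L`, the second rises and saturates, so they
cross exactly once: every parameter combination has an equilibrium. For
α = 2, β = 1 the intersection is the positive root of a quadratic, which
`solve_equilibrium()` returns in closed form (the tests cross-check it
against an independent bracketing root search to 1e-10 relative). Defaults
`k1 = 1` s/µM, `k2 = 0.5`, `rB = 0.01/(s·µM)`, `D = 10` µm²/s.

The dimensionless depletion number `rB·A0·W·L/D` classifies regimes:
≲1 negligible depletion, ≫1 strong. In the strong limit
`CB ≈ k2·D·C0/(V·W)` and `L ≈ (k1/k2)·A0²·V²·W/(D·C0)` — linear in width,
quadratic in density. (The strong-depletion length is derived from the two
base equations; `depletion_limit_length()` warns outside its regime.)
`length_phase_map()` sweeps `(C0, A0)` or `(W, A0)`, and
`compensate_length()` inverts the closed form for the `C0` or `W` that
restores a target length after a density change.

## Steering: two elastic beams growing side-by-side

Two lanes of width `W` with speeds `V1, V2` and modulus ratio
`σ = E2/E1 = (A2/A1)^τ` (modulus–density exponent `τ = 2.5` by default,
0.5 available; predictions are insensitive) bend, in mechanical
equilibrium, into an arc of constant radius

$$R = W\left(\frac{V_1+V_2}{V_1-V_2} +
      \frac{(\sigma-1)(V_1\sigma-V_2)}{4\sigma(V_1-V_2)}\right),$$

growing at `Vh = (V1+V2)/2 − (V1−V2)(V1²σ²−V2²)/(2(V1²σ²+6V1V2σ+V2²))`,
always turning toward the slower lane. At `σ = 1` the radius reduces to
`W(V1+V2)/(V1−V2)`; a very sparse (elastically weak) lane straightens the
pair, and curvature is maximal at an intermediate `σ`.

Lanes sharing one cofilin pool couple through a joint depletion factor
`D/(rB(A1W1L1 + A2W2L2) + D)`; `coupled_equilibrium_lengths()` solves the
joint system by damped fixed-point iteration. Both lanes grow longer than
in isolation and the sparser lane gains more (it benefits from the dense
lane's consumption).

`heterogeneous_shape()` integrates the centerline with the local curvature
`1/R(σ(y))` evaluated *pointwise* from the density profiles (the simplest
defensible blending; an integrated-stiffness alternative would smooth the
transition), and sets curvature exactly to 0 beyond the shorter lane's
trailing edge — the survivor grows straight, with a sharp transition.
Because "average curvature radius" of a shape mixing an arc and a straight
tail is ambiguous, the object reports both conventions:
`avg_curvature_radius` (inverse mean curvature over the curved portion —
stable, but blind to tail growth) and `avg_curvature_radius_full` (over the
whole shape — this is the one that registers straightening as the sparse
lane shortens, and the one the straightening analysis uses).

## Synthetic data and inference

The generators emulate the *statistical structure* of the measurements, not
the microscopy: no point-spread function, no intensity calibration
(synthetic units are true concentrations), no segmentation artifacts.
Noise models: additive Gaussian for kymographs (clipped at zero),
multiplicative lognormal for lengths and slopes (positive, scale-free).
Every generator is seed-deterministic and attaches provenance metadata
(generator, parameters, seed, package version) writable as a JSON sidecar.

- `gen_kymograph()` samples `CB(y, t)`; in no-depletion mode it is the
  closed form (every material path linear with slope `rB·C0·A`), in
  depletion mode the PDE (later-starting paths bind slower). The path along
  the moving front itself (`t0 = 0`) is pixel-limited; estimators should
  use interior start times.
- `gen_density_profiles()` builds the plateau-plus-collapse shape with a
  logistic drop over 10% of the length by default, within 1% of `A0` over
  the first 80%.
- `gen_length_table()` draws `(V, A0, CB)` over the experimental spans
  (density classes ~30/50/80 µM, speeds ~1 µm/min rising weakly with
  density, `CB` log-uniform on [0.1, 2] µM, condition labels
  `C0 ∈ {125, 250, 400, 500}` nM, `W ∈ {15, 30, 90}` µm) and applies the
  power law with lognormal noise.
- `gen_binding_table()` produces initial slopes `rB·C0·A` with a noise
  level calibrated by `calibrate_binding_noise()` so the slope-vs-`C0·A`
  Pearson correlation sits in the moderate (~0.5) regime; the calibrated
  default is `sdlog = 0.82`.

`fit_exponents()` works in log space — the power law is linear there and
lognormal noise becomes homoscedastic: `log(L/V) ~ log A0 + log CB`, with a
fixed-exponent mode that fits only the prefactor and reports the R² of
predicted vs observed lengths over any exponent grid. Near-collinear
designs are flagged via a condition-number diagnostic rather than silently
fitted. No multiple-testing correction is applied anywhere: each analysis
runs a single planned test. The binding correlation is computed pooled
across conditions.

## Workbench

`run_scenario()` executes named scenarios (transport depletion map,
kymograph, fragmentation sweep, feedback curves, phase maps, steering
shapes, synthetic tables) from a validated config (unknown keys rejected,
YAML/JSON round-trip), writing CSVs plus a provenance sidecar; reruns are
byte-identical, and `compare_runs()` diffs two bundles numerically. The
numbered scripts under `analysis/` are thin narrative drivers over these
functions; there is deliberately no shell CLI — the package functions and
scripts are the interface.

## What the tests do and do not show

The suite verifies closed forms against independent oracles (root finders,
brute-force edge counts, bracketing searches), conservation and positivity
of the PDE scheme against analytic limits (Gaussian spread, detailed
balance), connectivity invariants of the lattice, seed determinism, and
estimator recovery on calibrated synthetic data. Passing tests show the
models are implemented as specified and the inference recovers what the
generators encode; they cannot show that real networks follow these laws —
the generators inherit the models' assumptions (constant `CB`, no
disassembly feedback on transport, no cofilin cofactors, no
hydrolysis-state kinetics), which is exactly the regime where the models
claim validity.
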