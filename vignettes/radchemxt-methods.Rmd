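---
title: "Methods: radial reaction-diffusion kinetics of radiolysis tracks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: radial reaction-diffusion kinetics of radiolysis tracks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(radchemxt)
```

## The problem

Ionising radiation deposits energy along narrow particle tracks in water,
producing a heterogeneous cloud of radiolysis products (OH•, e⁻aq, H•,
H₃O⁺, ...) clustered around the track axis. During the heterogeneous
chemical stage (ps–µs) the species diffuse apart and recombine; by ~1 µs
to ~1 ms the concentrations become effectively uniform and classical
well-mixed kinetics take over. Monte Carlo step-by-step track chemistry
is accurate in the early stage but prohibitively slow beyond a few µs;
well-mixed codes are cheap but wrong whenever radial structure persists,
which it does for intermediate and high LET beams.

`radchemxt` bridges the two regimes. It takes a snapshot of a track at a
hand-over time `t_in` (~500 ns), converts it into per-species radial
concentration histograms `[A](t, r)` around the track axis, and evolves
the coupled reaction–diffusion system

$$\partial_t [A] = D_A \left(\partial_r^2 + \tfrac1r \partial_r\right)[A]
  \;+\; \sum_\text{reactions} \nu_A\, \kappa\, [R_1][R_2]$$

to the homogeneous stage (≥ 1 ms), reporting G-values (molecules per
100 eV) and radial distributions along the way.

## Numerical scheme

**Operator splitting.** Each step advances diffusion first, then
reactions, with the same `dt` (Lie splitting). The reaction part is
non-linear and strongly coupled (same-species channels such as
OH• + OH•), so it cannot be folded into the linear implicit diffusion
solve; conversely, accuracy requires both parts to act within the same
step. First-order splitting error is monitored by a Richardson
(dt-halving) test in the suite.

**Diffusion.** Crank–Nicolson on the uniform partition of bin centres
(`bw` = 20 nm by default), giving a tridiagonal system
`M a(n+1) = N a(n)` solved by the Thomas algorithm (validated against a
dense linear-algebra oracle to 1e-10 up to the production size J = 250).
Boundary conditions use two virtual points eliminated by mirror
conditions: `a(-1) = a(0)` enforces smoothness at the axis, and
`a(J) = a(J-1)` the zero-flux Neumann condition at `r_max` — in a
uniform parallel radiation field, whatever leaves one track cell enters
from its neighbours. Two structural consequences are tested exactly:
flat fields are fixed points of the update, and total mass
`∑_j c_j V_j` is conserved (the annulus volumes `V_j ∝ r_j` make the
cylindrical stencil telescope; drift is at rounding level, and the
suite bounds it at 1e-3 per 1000 steps). Free diffusion of a Gaussian
matches the analytic 2-D heat kernel at second order in `bw`.

**Reactions.** Bin-wise forward Euler: increments
`ΔA(r) = ν κ [R₁](r)[R₂](r) dt` are accumulated from the pre-step state
for all channels, then applied simultaneously. Bins never exchange
matter through reactions. Same-species channels use the convention
`d[A]/dt = −2κ[A]²` (each event consumes two molecules); the suite
checks the `1/[A]` slope equals `2κ`. Dissolved O₂ is a continuum: one
fixed concentration from Henry's law (`[O₂] = pO₂ · K_H`,
`K_H = 1.3e-3` M/atm at 25 °C), entering the rate products but never
evolving. A negative concentration produced by the explicit update is
clamped to zero and counted; the clamp counter must be zero in every
shipped run, and is, because the staged `dt` schedule keeps per-step
relative changes small.

**Time steps.** The staged schedule grows `dt` from 0.5 ns just after
hand-over to 10 ns beyond 1 ms (0.5 / 1 / 2.5 / 5 / 10 ns over the
intervals t_in–1 µs / 1–10 µs / 10–100 µs / 100 µs–1 ms / ≥1 ms).
The automatic step-increase "flags" of the original description are not
specified anywhere; we implement the static interval map, which is what
the published table documents. Steps are clipped so interval boundaries
and recording times are hit exactly.

**Flattening ("phase III").** At every recording time, any field whose
unweighted relative standard deviation over bins falls below the
threshold (default 5%) is collapsed to the single mass-conserving value
`N_tot / (N_A π r_max² h)` and thereafter skipped by the diffusion
step. The unweighted deviation versus volume-weighted collapse choice
is deliberate: the flatness test treats all radii alike (matching how
the distributions are inspected), while the collapse must conserve
mass exactly (verified to 1e-12). Once all fields are flat the
integrator is exactly bin-independent homogeneous forward-Euler
kinetics.

## The reaction network

The bundled, editable table (`inst/extdata/default_network.json`)
defines the ten tracked species — category (i) primary radicals OH•,
H₃O⁺, H•, e⁻aq; (ii) intra-track molecules H₂, H₂O₂, OH⁻; (iii) oxygen
products HO₂•, O₂•⁻, HO₂⁻ — with standard diffusion-controlled rate
constants and diffusion coefficients for water at 25 °C, pH 7 (the
Buxton/Frongillo lineage used across track-chemistry codes). The engine
treats all constants purely as configuration; no value is hard-coded.

Choices worth recording:

* **OH• + H₂O₂ → HO₂• is excluded.** Its rate (~2.7e7 /M/s) is 3–4
  orders below the diffusion-controlled channels and negligible at
  track concentrations, and including it would make category-(iii)
  species reachable in anoxia, contrary to the structural property the
  engine guarantees (and to pre-oxygen track-chemistry networks, which
  track no HO₂• at all).
* **Superoxide acid–base pair.** HO₂• → O₂•⁻ + H₃O⁺ (8e5 /s) and its
  diffusion-controlled reverse are included so the HO₂•/O₂•⁻ split is
  sensible at pH 7; the package reports their sum wherever the
  oxygen-product yield matters.
* **pH 7 is nominal only**: no background H₃O⁺/OH⁻ equilibrium
  concentration is injected; only radiolytic ions evolve. Acid–base
  equilibria other than the superoxide pair, temperature dependence and
  ionic-strength corrections are out of scope.
* **Rate constants are time-independent** (no Noyes transient term):
  by ~1 ns the transient correction is negligible, and the
  concentration-based reaction algorithm uses plain mass action.
* Element bookkeeping treats water as implicit: a reaction balances if
  its H and O excesses correspond to an integer number of implied H₂O
  on either side (H₃O⁺ + OH⁻ → 2 H₂O). Whether that neutralisation
  counts one or two waters affects nothing dynamical.

## Geometry and observables

The cylindrical cell has radius `r_max` and height `h` (the track
segment length). `r_max = 5 µm` by default, large enough that the
zero-flux boundary is inert for single-track studies; when inter-track
spacing matters, `surface_from_fluence()` sizes the cell from the
dose–LET–fluence relation `D[Gy] = 1.6e-9 · LET · Φ / ρ`, whose
inversion `S = 1/Φ` gives the mean surface per track and
`r_max = sqrt(S/π)`. `h` is 10 µm for electron/proton-like beams, 1–2
µm for high-LET ions (track-segment condition).

Discrete positions are binned as half-open annuli `[e_j, e_{j+1})`;
a position at or beyond `r_max` (or outside `[0, h]` axially) is
discarded and counted. Concentrations are per-track averages over the
`n_tracks` superimposed input tracks; averaging happens once at
binning, before evolution (the alternative evolve-each-then-average
mode is out of scope). `total_amount()` inverts the binning exactly;
`gvalues()` divides by the deposited energy `LET · h · 1000` eV, making
G intensive in `h` and inversely proportional to LET at fixed fields.

## Synthetic tracks

The generator replaces the Monte Carlo front-end for testing. Per
species, counts are Poisson around the expected per-track yield; radii
follow a 2-D Gaussian whose scale is the free-diffusion spread at the
hand-over time, `σ_s = sqrt(σ₀² + 2 D_s t_in)` with a 10 nm initial
spur width; z is uniform (axial homogeneity is χ²-tested). Two presets
anchor the dilution range:

* `low_let_preset()` — electron-like, LET 0.2 keV/µm, h 10 µm, single
  Gaussian, scavenger-free escape yields at ~500 ns
  (G ≈ 2.70/3.30/0.58/2.62 for OH•/H₃O⁺/H•/e⁻aq and 0.45/0.68/0.50 for
  H₂/H₂O₂/OH⁻, chosen from the standard low-LET literature values so
  that G(H•)+G(e⁻aq) ≈ 3.2).
* `high_let_preset()` — carbon-like, LET 160 keV/µm (tunable), h 2 µm,
  lower radical and higher molecular yields, plus a δ-ray penumbra: 35%
  of each species in a 1 µm Gaussian halo. Real ion tracks put a large
  fraction of their dose in the electron penumbra; without it a
  synthetic carbon track is unrealistically compact. The penumbra
  remains a flag (`penumbra_fraction`) and the low-LET default is a
  single Gaussian.

**Oxygenated snapshots.** A Monte Carlo track simulated *with* oxygen
shows O₂•⁻/HO₂• already at 500 ns, because the scavenging reactions
e⁻aq + O₂ and H• + O₂ have time constants of ~200 ns at air
saturation. The presets therefore accept `po2` and pre-partition the
e⁻aq/H• yields by the survival factor `exp(−κ[O₂]t_in)`. Without this,
no initial condition seeded only with categories (i)/(ii) at 500 ns
could reproduce the ~1% agreement between anoxic reactant and oxic
product yields at 1 µs — ~7.5% of the electrons would still be
unconverted after only 500 ns of oxygen exposure.

What the generator does *not* emulate: discrete δ-ray clusters that
break radial symmetry, species–species spatial correlations inside
spurs, LET-dependent yield evolution before `t_in`, and any particular
Monte Carlo code's radial profile. A green test on synthetic tracks
establishes that the *solver* is correct for the stated initial
condition, not that the fixture reproduces any published track.

## Independent oracles

Two well-mixed engines validate the homogeneous limit without sharing
code with the solver: an adaptive Cash–Karp Runge–Kutta 5(4)
integrator for the mass-action rate equations (no stiff solver is
needed — at nM–µM track concentrations the fastest network rate is
~1e-3 /ns), and an exact Gillespie direct-method stochastic simulation
whose propensities mirror the network conventions
(`κ n_A (n_A − 1)/(N_A V)` for same-species channels). The comparison
volume for fluence-based scenarios is `V = h/Φ`. The suite checks the
integrator against closed forms (exponential, second-order), the SSA
replicate means against the integrator at several count scales, and the
radial solver against the integrator from uniform random initial
concentrations (agreement within 1% at 10 µs; the package's acceptance
script reports ~0.03%).

## Interpreting the long-time runs

With physical diffusion coefficients (1.4–9 nm²/ns) the slowest radial
Neumann mode on a 5 µm cell decays with a time constant
`r_max²/(D α₁²) ≈ 2–5 ms`, so no concentrated initial condition can
pass a 5% flatness test by 1 ms on that grid — flattening times are a
property of the cell size as much as of the chemistry. The package's
long-time demonstration therefore sizes the cell from the dose–LET
relation at a conventional carbon fluence (1e7 /cm², r_max ≈ 1.78 µm),
on which a carbon-like track flattens completely by a few hundred µs;
on the 5 µm single-track grid the same run is still radially structured
at 100 µs, consistent with the physics above.

## Numerical edge cases

* Zero fields are flat at zero (flatten check treats mean 0 as flat).
* `D = 0` makes the diffusion update the identity; `κ = 0` the reaction
  update.
* Recording times are snapped onto the step grid by clipping `dt`, so
  recorded times are exact.
* The tridiagonal solver raises on a zero pivot; CN assembly always
  yields strictly diagonally dominant `M`, so this cannot trigger in
  normal use.
* All randomness (track sampling, uniform states, SSA) flows through
  explicit integer seeds; identical seeds give byte-identical outputs.

## A worked example

```{r example, eval = FALSE}
net <- build_default_network(list(po2 = 0.21))
grid <- radial_grid(bw = 20, r_max = 5000, h = 10000)
model <- low_let_preset(po2 = 0.21, seed = 7)
init <- synthetic_initial_state(model, grid, n_tracks = 1000)
cfg <- solver_config(t_in = 500, t_end = 1e4)
run <- run_simulation(init, net, cfg, beam = beam_spec(let = 0.2))
tail(run$gvalues)
```

The acceptance report (`scripts/acceptance.R`) recomputes the two
headline bounds from scratch: the solver-vs-oracle homogeneous-limit
deviation at 10 µs and the anoxic-reactant / oxic-product yield
difference at 1 µs, both of which the shipped configuration keeps well
under the 1% bound.
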