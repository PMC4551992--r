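---
title: "Methods: grand-canonical Monte Carlo of compressed cell-surface brushes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: grand-canonical Monte Carlo of compressed cell-surface brushes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

`brushmc` simulates the force an AFM probe feels when it compresses the
polymer brush (microvilli, microridges) that covers an epithelial cell.
The cell-surface patch is a laterally periodic box of area 20.5 nm²;
linear bead–spring chains are grafted to a soft wall at `z = 0`, a second
soft wall at `z = h` stands in for the probe (its contact area is much
larger than the patch, so a plane is the appropriate tip geometry and the
nominal probe radius, 2.5 µm, enters only through the Derjaguin
transform), and monomeric solvent beads fill the gap. All lengths are in
units of the bead interaction radius `rc` (0.646 nm), all energies in
`kBT`.

Interactions are the soft, finite-at-overlap quadratic repulsion used by
coarse-grained particle methods,

    U(r) = (a/2) (1 − r)²   for r < 1,   0 otherwise,

with `a = 25` between like species and `a = 28` between solvent and brush
(a marginally poorer solvent for the brush than for itself). Both walls
use the same quadratic family acting on the wall gap, which is what makes
the surfaces deformable: a particle may penetrate past the nominal plane
at finite energy cost. Consecutive chain beads are joined by freely
rotating harmonic springs `U = (κ/2)(r − r0)²`. Sampling is plain
Metropolis Monte Carlo, so only this conservative energy matters;
dissipative and random forces of the parent dynamics method have no
Boltzmann weight and are deliberately absent.

Two brush architectures are built in:

* **normal** — one population, `N = 27` beads per chain at
  `Γ = 0.78 nm⁻²` (16 chains on the 20.5 nm² patch), `κ = 100`;
* **cancer** — three populations, `N = 5, 30, 42` at
  `Γ = 1.76, 0.49, 0.20 nm⁻²` (36/10/4 chains), all bonds sharing one
  spring constant: `κ = 100` ("soft") or `κ = 2000` ("stiff",
  `κ_stiff = 20 κ_soft`).

Grafted ends are either free to diffuse in the surface plane ("liquid"
brushes, the biological case) or frozen ("solid" brushes, the
chemisorbed-polymer case). Liquid grafts move in xy only; their z is
pinned to the surface plane exactly.

## Grand-canonical sampling

The solvent exchanges with a reservoir at fixed activity `z` (chemical
potential `µ = kBT log z` up to the de Broglie constant, which is
absorbed into `z`). A sweep is one attempted displacement per mobile
particle plus a fixed number of insertion/deletion attempts equal to 10%
of the *run-start* solvent count. Freezing that number is deliberate: an
attempt count that tracked the fluctuating count applies more
number-changing kernels in high-occupancy states, which makes low-N
states sticky and measurably biases the stationary distribution (we saw
the ideal-gas mean sit ~4% below `zV` before freezing it).

Acceptance rules are the standard ones: displacements
`min(1, e^(−ΔU))`, insertion at a uniform point of the accessible volume
`V = Lx·Ly·h` with `min(1, zV/(N+1) e^(−ΔU))`, deletion of a uniformly
chosen solvent particle with `min(1, N/(zV) e^(−ΔU))`. Moves that would
take a particle outside `0 ≤ z ≤ h` are rejected outright.

Two trial-displacement amplitudes are kept, one for unbonded particles
and one for chain beads, each auto-tuned toward 40% acceptance during
equilibration and frozen for production. One global amplitude would be
tuned by the solvent majority (~0.35 rc) and would essentially never move
a κ = 2000 bead, leaving stiff chains quenched in their initial
configuration — the single observation that most shaped this
implementation. For the same reason chains are initialized as upright
rods at the *thermal* bond length `2·sqrt(2/(πκ))` (≈0.16 rc for κ = 100,
≈0.036 rc for κ = 2000, capped at 0.5 rc), not at an arbitrary fixed
spacing: the initial state then sits near the bonded equilibrium and
equilibration only has to relax chain conformations and the solvent.

The activity that holds the `a = 25` fluid at the conventional reduced
bulk density `ρ rc³ = 3` was calibrated once by secant iteration on
`log z` with short brush-free runs (`calibrate_activity()`), giving
`z ≈ 6.0 × 10⁵`, the package default. Bulk density is measured in the
central slab, one `rc` away from either wall, to stay clear of the
depletion layers. The test suite re-runs the calibration from scratch and
checks the default against an independent run at the 2% level.

Randomness in the engine comes from a dedicated xoshiro256++ stream
seeded from the single run seed; R's RNG is never touched by a run, so
identical `(configuration, seed)` pairs reproduce trajectories
bit-for-bit regardless of what the session did before.

## Observables

The instantaneous tip force is the sum of wall-normal derivatives
`a_w(1 − gap)` over particles within range of the tip plane. Because the
solvent reservoir presses on the tip at *every* separation, force–distance
profiles report the excess over the largest-h point of the sweep (the
uncompressed reference); the sweep must therefore extend beyond brush
contact. Per-point uncertainties are block-averaged standard errors
(10 blocks by default). `F/R` is obtained by trapezoidal Derjaguin
integration of the excess pressure. Density profiles are z-histograms
accumulated at sampling time; the brush height is reported with two
estimators, the 98%-cumulative crossing (primary, interpolated across the
crossing bin) and the first-moment `2⟨z⟩`. For a δ-like profile at `z₀`
the two estimators give `z₀` and `2z₀` respectively — the first-moment
form is the half-space convention and is only meaningful for profiles
that decay from the wall. Graft meandering is recorded as per-sample xy
positions of every graft bead, unwrapped across the periodic seam, with a
time-origin-averaged mean-square displacement.

## What the synthetic data stand for

The builder *is* the data generator: there is no external input. Its
defaults are the printed architecture and geometry above, with the two
choices the source does not state fixed once: bond rest length `r0 = 0`
(springs pull beads toward contact, which is the only convention
consistent with stiff chains being *shorter* — see below) and a jittered
triangular graft lattice (±0.1 rc) to avoid accidental initial overlaps.
`synth_force_curve()` additionally emits noisy multi-population
Alexander–de Gennes curves with seeded multiplicative Gaussian noise for
exercising the fitting layer; it emulates the shape and noise character of
a force table, not instrumental artefacts (drift, hysteresis, contact
indetermination) of real AFM data. A green fit test therefore establishes
parameter recovery under the model's own assumptions, nothing more.

## Theory layer

The flat-plate osmotic pressure of a compressed brush follows the
Alexander–de Gennes scaling law

    P(h) = (kBT/s³) [ (2L/h)^(9/4) − (h/2L)^(3/4) ],   h < 2L,

with `s = Γ^(−1/2)` the grafting spacing; the osmotic and elastic terms
balance exactly at contact. The exact printed form of the law in the
source is not available (the equation is rendered as a figure), so the
standard form from its cited origin is used, with the onset convention
(2L vs L) exposed as a switch and the stated validity window
`0.1 < h/L < 0.9` enforced during fitting. The sphere force
`F/R = 2π ∫ P` has a closed-form antiderivative,

    F(h)/R = (2π/s³) [ (4/5) D^(9/4) h^(−5/4) + (4/7) D^(−3/4) h^(7/4) − (48/35) D ],

`D = 2L`, which the adaptive-quadrature route must reproduce to 1e−8 —
one of the acceptance identities. Fits are nonlinear least squares on the
masked window, with the mask recomputed from the current estimate and
iterated to a fixed point, descending-L ordering to break label
switching, multi-start initial guesses, and small-sample-corrected AIC
for model comparison (the source reports "best fit" without naming a
criterion). When grafting densities are unknown, the amplitude `1/s³` is
not separately identifiable from a free prefactor, so amplitudes are
freed and `s` pinned to 1.

## Numerical choices

* Pair interactions between bonded neighbours are kept (common
  convention for soft chains); a switch removes them.
* Cell lists require at least 3 cells per periodic dimension; smaller
  boxes fall back to an all-pairs scan. Cell-list and all-pairs
  enumerations must agree exactly, and incremental ΔU must match a full
  recompute to 1e−10 — both are acceptance identities.
* The surface wall acts on non-grafted particles only (graft beads live
  in the surface plane); the tip wall acts on everything.
* Chain counts are `round(Γ·A)` with a minimum of 1.
* Block standard errors use 10 equal blocks; the block length should be
  checked against the force autocorrelation when schedules are changed.

## Known limitations and honest disagreements

Two phenomenology criteria of the reference study do **not** reproduce
under the printed parameters, and the test suite leaves them red rather
than bending the stated world toward them:

1. *Solvent window (2 ≤ z/rc ≤ 5).* With `r0 = 0`, κ = 2000 bonds have a
   thermal length of ~0.04 rc and the stiff brush collapses below
   ~2.5 rc. The comparison window then contains near-bulk solvent for the
   stiff system but brush-displaced solvent for the soft one, so the
   literal window count is *larger* for stiff. The physical claim —
   solvent penetrates the soft brush more easily — does hold when
   measured inside each brush (window `[0, L]` of the respective brush),
   and that measurement is asserted alongside the literal one.
2. *Normalized normal-vs-cancer ordering.* The cancer preset's short
   chains (`N = 5`, height < 1 rc at κ = 100, r0 = 0) are never touched
   anywhere in the printed sweep (2.8–17.5 nm ≈ 4.3–27 rc), so the
   mechanism that makes the cancer curve decay faster than the normal one
   on normalized axes — a dominant short-chain population carrying the
   force maximum — is absent; the cancer curve's longer chains
   (`N = 42` vs 27) make it decay *slower* instead. Reproducing the
   ordering would need bond lengths several times the thermal length of a
   κ = 100 spring, i.e. parameters other than the printed ones.

Further limitations: no hydrodynamics or dynamics of any kind (Monte
Carlo only), no electrostatics, no chain polydispersity beyond the three
discrete populations, one soft-surface model for both cell types, and a
planar tip (curvature enters only via Derjaguin). Production schedules in
the tests are scaled down to a single CPU; the defaults
(`n_equilibration = 800`, `n_production = 2000`) are chosen so the force
standard error is a few percent of the strongly-compressed mean, and
convergence should be rechecked via energy/force stationarity whenever
architectures or interactions change.

Contrast uncertainties (soft vs stiff, liquid vs solid) pool the
block-propagated errors with the between-seed scatter of the per-seed
differences, `SE = sqrt(SE_blocks² + SE_seeds²)`: finite blocks
underestimate slow grand-canonical modes (solvent-number relaxation), and
the replicate spread recovers them.
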