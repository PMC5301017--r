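---
title: "Methods: stochastic reaction-diffusion on tetrahedral meshes"
author: "tetrasplit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: stochastic reaction-diffusion on tetrahedral meshes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tetrasplit)
```

# The model

`tetrasplit` simulates mesoscopic reaction–diffusion systems: integer
molecule counts `n(tet, S)` of species `S` in the tetrahedra of an
unstructured mesh, evolving as a continuous-time Markov jump process.
Two kinds of kinetic events drive the state:

* **Reactions.** Mass-action reactions of order one or two inside a single
  tetrahedron. A rate constant `k` (1/s for order one, 1/(µM·s) for order
  two) is converted to a per-event rate with the compartment volume,
  `c = k / (602.214076 · V)` for second order, using the CODATA-exact
  conversion 1 µM·µm³ = 602.214076 molecules. Propensities are the
  standard combinatorial forms `c·nA`, `c·nA·nB` and `c·nA(nA−1)/2`.
* **Diffusion.** First-exit jumps between face-adjacent tetrahedra. The
  per-face rate uses the standard tetrahedral finite-volume discretization
  of Fick's law, `d_k = D · A_k / (h_k · V_i)`, with `A_k` the shared-face
  area, `h_k` the barycenter-to-barycenter distance and `V_i` the source
  volume. The local total `d_S,tet = Σ_k d_k` is the rate at which one
  molecule leaves the tet.

The assumptions are the usual ones for voxel-based stochastic
reaction–diffusion: well-mixedness inside each tetrahedron (tet size below
the reaction Kuramoto length), dilute mass-action kinetics, and isotropic
diffusion. Membrane/surface species and electrophysiology are out of scope.

# Solvers

## Exact spatial SSA

The reference solver treats every reaction instance and every
(tet, species) diffusion instance as one event of a global Gillespie
system. Waiting times are exponential in the total propensity `a0`; when
`a0 = 0` the clock jumps to the horizon (a depleted system is a valid
state, not an error). Two event-selection back ends share the same
distribution:

* **Direct**: hierarchical search — pick the tet by its propensity subtotal,
  then the event inside the tet. Cumulative-sum drift is controlled by
  periodic full rebuilds (every 10⁶ updates) and a rebuild-and-retry path
  if a search ever falls off the table.
* **Composition–rejection**: events live in power-of-two propensity groups
  (`a ∈ [2^(g−1), 2^g)` in group `g`); a group is chosen proportionally to
  its sum and the event by rejection sampling against the group's upper
  bound. Groups span 2^−40 ≈ 9·10⁻¹³ to 2^80 1/s; propensities below the
  floor are clamped into the lowest group, which keeps rejection sampling
  exact (the bound is still an upper bound), and zero-propensity events
  leave the structure entirely. Membership moves exactly once per boundary
  crossing.

After an event fires, only the propensities on its precomputed update
dependency list are recomputed. A reaction's list covers the events of its
own tet that read a species with nonzero net change. A diffusion event's
destination is drawn at fire time (proportional to the per-face geometry
factor), so its list is closed over *all* face neighbours — a deliberate
superset that stays valid for every possible destination. The incremental
tables can be audited at any point against a full recomputation, and the
test suite does so after capped runs of both back ends.

## Operator splitting

The approximate solver alternates two operators over a fixed diffusion
time window

```
tau = min over (S, tet) of 1 / d_S,tet
```

computed once at initialization from model and geometry alone; it never
changes during a run (molecule populations do not enter it).

1. **Reaction window.** The exact SSA restricted to reaction events runs
   for `tau`, accruing for each (tet, species) the time integral of the
   count (occupancy, molecule·s). Products created mid-window accrue from
   their creation time; the integral finalizes at the window boundary.
2. **Diffusion operator.** For each (tet, diffusive species) the expected
   number of leavers is `mu = mean-occupancy · d_S,tet · tau`, clamped to
   the available count; the integer draw is stochastic rounding,
   `floor(mu) + Bernoulli(frac(mu))`. Leavers are split among the
   neighbours **jointly multinomially** with probabilities `d_k / d_total`,
   which conserves the drawn total exactly. Arrivals are applied in a
   second phase so that molecules arriving within a window are never moved
   twice in that window.

Design choices worth recording, since the operator's exact form was
genuinely open:

* Stochastic rounding of `mu` (rather than a Poisson or binomial draw) is
  the single most consequential fidelity decision: it preserves the
  occupancy-based mean flux exactly, keeps counts integral, and never
  overdraws a tet. Clamping to the available count makes negative counts
  impossible by construction.
* Joint multinomial (rather than independent per-neighbour draws)
  conserves the leaver total exactly; per-neighbour independence would
  only conserve it in expectation.
* A final partial window of length `w < tau` is allowed; `mu` scales
  linearly with `w` (mean occupancy over `w` times `d·w`), so the mean
  rate is unchanged. Windows are also shortened to land exactly on
  recording times, which makes recorded states well-defined window
  boundaries; since shorter windows only tighten the splitting
  approximation, this is benign.

Splitting unavoidably introduces small errors relative to the exact SSA —
the approximation decouples reaction and diffusion within a window. The
package therefore treats agreement as a *statistical* criterion
(across-seed confidence intervals and Kolmogorov–Smirnov tests,
Benjamini–Hochberg corrected across the species × time grid), with two
exceptions that must hold exactly: per-species conservation under pure
diffusion, and integer bookkeeping of every window.

## Partition-parallel protocol

The mesh is partitioned over ranks (0-based ids, Metis `.epart`
convention); each rank owns the events of its hosted tets. One run-wide
`tau` is shared by all ranks (the per-rank minima reduce to a global
minimum at initialization). Each window every rank executes its reaction
window and diffusion operator locally. Diffusion with a same-rank
destination is applied directly; a cross-rank destination is registered in
the **remote change buffer** for the destination's rank: an append-only
vector of integer triples (destination tet, species, accumulated change).
Per (tet, species) the registering side keeps a location marker; a
matching entry at the marked location accumulates in place, and a mismatch
— the signature of a buffer reset since the last registration — appends a
fresh entry and updates the marker. Both paths are amortized O(1). The
live size is bounded by (#remotely hosted neighbour tets) × (#diffusive
species) and is zero when no cross-rank diffusion occurred in a window.

Each neighbour sends exactly one (possibly empty) buffer per window, which
gives every rank an unambiguous completion condition without global
barriers: a rank may start window `t1` as soon as all neighbours' buffers
for `t0` are applied. On the receiving side only the species-update
dependency lists `deps(S)` — the hosted events that read the changed
(tet, species) — need refreshing. Communication is strictly regional:
buffers exist only between face-adjacent ranks, and the loop stops with a
protocol error if a change ever targets a non-neighbour.

The canonical backend is a deterministic **virtual-rank scheduler**: ranks
execute round-robin in one process, each on its own RNG stream derived
from (master seed, rank). This makes the full protocol — including stale
markers, buffer bounds and conservation — exercisable and exactly
reproducible at desk scale; with one rank it degenerates bitwise to the
single-rank operator-splitting solver. Timing is attributed per rank to
`Tcomp` (reaction window + local diffusion), `Tsync` (receiving/applying
buffers) and `Tidle` (waiting), with `Ttotal = Tcomp + Tsync + Tidle`;
on virtual ranks `Tidle` is structurally ~0 and reported as measured.
Speedup and efficiency (`S_p/q = T_q/T_p`, `E_p/q = S_p/q·q/p`, and the
weak-scaling ratio) are reporting features over these timings —
hardware-dependent quantities, not correctness criteria.

# Meshes and fixtures

`cuboidMesh()` subdivides a box grid cell into six tetrahedra (Kuhn
subdivision, all sharing the cell diagonal). The pattern is translation
invariant, hence conforming across cells without parity flips — a
correctness requirement for face-neighbour diffusion — and the six tets
tile the cell exactly, so the total volume equals the box volume to
round-off. The 5-tet alternative needs mirrored cells and was rejected for
that reason. Gmsh MSH v2 ASCII (volume elements of type 4) and a minimal
native text format are supported for interchange; connectivity is always
rebuilt from the tet table, never trusted from a file. Tets are re-oriented
to positive volume on construction; volumes below 10⁻¹² µm³ — far below
any realistic µm-scale tet — are reported as degeneracies.

The bundled benchmark is the classic 10-species model: species A..J with
D = 100, 90, …, 10 µm²/s, whole-mesh initial totals 1000, …, 10000
(55,000 molecules), and four reversible reactions (kf/kb = 1000/100,
100/10, 10/1, 1/1 in 1/(µM·s) and 1/s). `makeBenchmark(scale)` places
`scale`-multiplied totals uniformly — deterministic largest-remainder
apportionment by tet volume, so totals are preserved exactly and fixture
construction is reproducible without consuming random numbers.

## What the synthetic fixtures do and do not emulate

The generated cuboid meshes have nearly uniform, well-shaped tets and the
benchmark distributes molecules uniformly, so parallel loading is balanced
by construction. Passing tests on these fixtures validate the *algorithmic
machinery* — rates, windows, buffers, dependency tables, conservation —
but say nothing about irregular biological meshes (sliver tets, wide
volume ranges), strong concentration gradients that unbalance ranks, or
cluster-scale wall-clock behaviour. Published headline speedups are
hardware-dependent cluster measurements and are deliberately not a
correctness surface here; dynamic load balancing is likewise out of scope.

# Numerical choices

* Randomness: all draws flow from R's own generator; per-rank streams are
  stored `.Random.seed` states seeded from (master seed, rank), swapped
  around each rank step. Every user-facing entry point requires a seed, and
  identical (config, seed) reruns are byte-identical on the virtual-rank
  backend.
* Propensity drift: incremental sums are doubles; both back ends rebuild
  from counts every 10⁶ updates and on any selection inconsistency, and
  selection falling off a freshly rebuilt table is a hard internal error.
* Degenerate inputs: `tau` is undefined without a positive diffusion rate —
  the error directs users to the pure-reaction exact solver. Isolated tets
  simply have `d_S,tet = 0`. Empty partitions warn (legal but wasteful);
  mismatched partition/mesh sizes are errors.
* Recording: the exact solver snapshots the jump-process state at the
  requested times; the window solvers snapshot at the window boundary that
  the schedule aligns to each requested time.

# Problem sizes in the test suite

The suite runs at desk scale by choice of fixture, not by weakening
criteria: the full-size 7500-tet benchmark mesh is used for the
window-computation oracle (a pure scan), while trajectory-level
comparisons use the same box with 30–240 tets, 10⁴ molecules for the
Einstein-relation check (cloud ≫ tet size and ≪ box size at the measured
time), 10⁴ seeded runs for waiting-time statistics, 500 runs for the
binding-equilibrium comparison against the analytic master-equation mean,
and 100 seeds per solver for the splitting-fidelity and
partition-invariance comparisons (1, 2, 4 and 8 virtual ranks).

# Known limitations

* The diffusion window makes the splitting solver first-order accurate in
  `tau`; systems whose reactions are much faster than `1/tau` inside a tet
  are handled (the reaction window is an exact SSA), but reaction-diffusion
  correlation within a window is lost.
* The virtual-rank backend executes ranks sequentially; it validates the
  protocol, not true concurrency, and timing splits on it are informative
  rather than predictive.
* Maximum reaction order is two; higher orders are rejected loudly rather
  than silently mis-scaled.
* No membrane potential / voltage-gated channels, no surface species, no
  dynamic load balancing, no mesh repair.
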