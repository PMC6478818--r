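---
title: "Fixation probability and time for the Moran process on graphs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fixation probability and time for the Moran process on graphs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(moranfix)
```

## The model

`moranfix` studies the discrete-time Moran birth–death process on a
structured population. The structure is a graph on `N` vertices, one
individual per vertex; edge weights are normalized per source into a
replacement kernel `w(u, v)`, the probability that an individual
reproducing at `u` places its offspring at `v` (self-loops allowed — an
offspring may replace its own parent). At each step one individual is
chosen to reproduce proportionally to fitness (`r` for mutants, 1 for
residents) and its offspring replaces the kernel-chosen neighbor, adopting
the parent's type. Starting from a single mutant, the population
eventually reaches one of two absorbing states: all-mutant (fixation) or
all-resident (extinction).

Three quantities summarize the dynamics, all measured in Moran steps:

* **fixation probability** `rho_v` — the chance the mutant lineage takes
  over, starting at vertex `v`;
* **absorption time** `a_v` — expected steps until the population is
  homogeneous, either way;
* **conditional fixation time** `tau_v` — expected steps over the
  trajectories that end in fixation only. Extinction trajectories are
  typically short, so `tau` usually exceeds `a`.

A *step* here is every birth–death event, including ones that change
nothing (a mutant's offspring replacing another mutant, or a self-loop
replacement). This convention matters: the weighted bipartite family
below spends most of its steps in self-replacements, and dropping them
would silently change every reported time.

Two initialization schemes place the initial mutant. Under **uniform**
initialization (mutants arising spontaneously) the start vertex is
uniform; under **temperature** initialization (mutants arising during
reproduction) vertex `v` is chosen with probability equal to its
temperature `t(v) = (1/N) sum_u w(u, v)`, its replacement rate.
Aggregated fixation probability and absorption time are the
scheme-weighted means. For the conditional fixation time the package
defaults to the *fixation-weighted* mixture
`sum_v pi(v) rho_v tau_v / sum_v pi(v) rho_v` — the expectation over
fixing trajectories when the start vertex is itself random — because
conditioning does not commute with averaging; the plain mean of `tau_v`
is available via `tau_aggregation = "mean"`. The suite validates the
weighted definition against a truncated trajectory summation on a
3-vertex star.

Whether the self-loop weight `w(v, v)` counts toward `t(v)` is a genuine
modeling choice; the package includes it by default (a self-replacement
is a replacement event, and the copy made at `v` can carry a mutation)
and exposes the exclusive convention through `include_selfloops` /
`temperature_selfloops`. For the weighted bipartite family the inclusive
convention is the meaningful one: excluding self-loops concentrates the
initial mutants on the hot small part, where lineages die quickly.

## Three solvers, one triangle

**Full-state engine** (`solve_fixation`). The process is an absorbing
Markov chain over all `2^N` mutant configurations. The transition matrix
is assembled in C++ and the three linear systems — `rho`, absorption
time, and the auxiliary `z = rho * tau` (plus its extinction mirror) —
are solved by sparse LU with a residual check at `1e-9`. Self-transitions
are retained in the systems. The state-space cap defaults to 14 vertices;
an 8-vertex graph solves in ~50 ms, a 12-vertex complete graph in ~35 s.

**Lumped solvers** (`complete_graph_stats`, `star_stats`,
`bipartite_stats`). Within each part of a (weighted) complete bipartite
graph all vertices are automorphic by construction, so the chain lumps
exactly onto mutant counts: a birth–death chain for the complete graph, a
two-dimensional `(i, j)` chain with `(m+1)(s+1)` states for bipartite
graphs, the star being the `(N-1, 1)` special case. All lumped systems
are solved by sparse LU as exact linear solves rather than the classical
product-sum formulas: the solves are unconditionally stable (no `r^k`
overflow for `r < 1` or large `N`), cost the same at these sizes, and
make the neutral case `r = 1` an ordinary input instead of a
removable-singularity special case. Routine sizes are `N` up to a few
thousand (a `(2000, 45)` chain solves in ~2 s); `N = 10^4` is feasible
(~30 s).

**Simulator** (`simulate_once`, `estimate`). Monte Carlo for anything
else. Reproducers are drawn by a two-pool scheme (mutant vs resident pool
by aggregate fitness, then uniform within the pool), targets by binary
search in precomputed cumulative kernel rows. Each run uses a
counter-seeded xoshiro256++ stream (`master_seed * 2^20 + run`), so
batches are reproducible, extendable, and independent of R's RNG state.
The optional `fast_forward` mode lumps runs of no-change steps by drawing
their count from the geometric law with the configuration's hold
probability, then drawing a type-changing event directly — exact in
distribution, and the only practical way to simulate heavily self-looped
graphs. Defaults: `1e5` runs for probabilities, `1e4` for times.

The tests close the triangle: full-state, lumped, and simulated results
must agree (to `1e-8` for the exact pair, within 3 standard errors for
the simulator) on the complete graph, the star, and balanced/weighted
bipartite graphs at `N = 8`.

## Graph families and the census

Constructors cover the complete graph `K_N`, the star `S_N`, cycles,
uniform random labeled trees (Prüfer sequences), connectivity-conditioned
Erdős–Rényi graphs (rejection sampling, 10,000-retry cap), stars/cycles
with extra random edges, and the two bipartite families:

* the **α-Balanced bipartite graph** `B_{N,α}`: complete bipartite with
  parts `N` and `N^(1-α)`;
* the **α-Weighted bipartite graph** `W_{N,α}`: the same, plus a
  self-loop of weight `N^(1-α/2) - N^(1-α)` on each large-part vertex, so
  that offspring migrate to the small part only with probability about
  `N^(-α/2)`.

The small-part size is rounded to the nearest integer (minimum 1); the
self-loop weight is kept as an exact real.

For `W_{N,α}` the choice of step-counting convention is substantive,
since most steps are self-loop self-replacements. `bipartite_stats()`
exposes both: with `count_holds = TRUE` (the default, and the package's
convention everywhere) the fixation time of `W_{N,0.5}` at `r = 1.1`
scales like `N^1.5 log N` across `N = 100..800`, whereas counting only
type-changing jumps (`count_holds = FALSE`) it scales like `N log N` —
the suite asserts both scalings with bounded ratios. The `N^{1+α} log N`
growth therefore belongs to the all-steps convention. The asymptotic theory treats
`N` as the large-part size; for finite-size comparisons at a fixed total
population the helper `bipartite_parts_for_total()` scans the large-part
size so the total matches, and the experiment drivers default to that
convention (switchable via `part_convention`).

`enumerate_connected_graphs(n)` generates one representative per
isomorphism class of connected graphs by canonical augmentation — every
connected graph has a non-cut vertex, so level `k` is built from level
`k-1` by attaching a new vertex to each nonempty subset, canonicalizing
(igraph's BLISS), and deduplicating. `count_connected_graphs(n)` is the
independent analytic census (Burnside count over vertex-permutation cycle
types, then the inverse Euler transform); both give 11,117 at `n = 8`
(the enumeration takes about two minutes and is cached per session, the
count microseconds; counts are exact below 2^53, ample through `n = 13`).
At `n = 9` the census gives 261,080.

## Tradeoffs, bounds, and the effective rate

`run_sweep()` solves every (or a stratified subsample of) `n`-vertex
graph, classifies each against `K_n` (amplifier/suppressor by fixation
probability, accelerator/decelerator by conditional fixation time; ties
within `1e-10` get no flag) and marks the Pareto front under (maximize
`rho`, minimize `tau`), with `1e-12` dominance ties kept. Under uniform
initialization at `n = 8, r = 1.1` the complete graph has the shortest
fixation time and the star the highest fixation probability — both ends
of the front; under temperature initialization the complete graph takes
both extremes and regular graphs are isothermal (all match its fixation
probability).

`absorption_lower_bound()` evaluates the universal bound
`(rho/r) N ln N` on the absorption time; the suite verifies it on every
connected graph of sizes 6 and 7. Natural logarithm throughout.

`effective_rate()` combines mutation supply and spread:
`t1 = 1/(N mu rho)` generations to produce a mutant destined to fix,
`t2 = tau/N` generations to fix it, rate `= 1/(t1 + t2)`.
`run_rate_curves()` evaluates it over a mutation-rate grid with exact
lumped inputs. At `N = 100, r = 1.1` the complete graph is best above
roughly `mu = 10^-3`, the star only below roughly `3·10^-6`, and balanced
bipartite graphs take the intermediate regime.

## What the generators emulate — and what passing tests show

The random-graph constructors (trees, Erdős–Rényi, perturbed stars and
cycles) are reference families for tradeoff scans, not models of any
empirical population; all inputs in this package are synthetic by
construction, since the object of study is the structure itself.
Simulation-based checks certify distributional correctness of the
implementation on small and mid-size graphs — they do not, and cannot,
certify asymptotic claims; those enter only as finite-size trends
(monotone convergence, bounded scaling ratios) at exactly solvable sizes.

## Numerical choices

* Linear systems: sparse LU (`Matrix`), residual check `1e-9` on the
  full-state systems; lumping agreement asserted to `1e-8`.
* Kernel rows must sum to 1 within `1e-9` on input (`1e-12` is met by all
  constructors); step-distribution mass checked to `1e-12`.
* Degenerate inputs: absorbing start configurations, `r <= 0`, empty
  part sizes, and oversized state spaces are rejected with errors rather
  than coerced.
* Erdős–Rényi connectivity by rejection with a retry cap; the uniform
  tree sampler is the Prüfer bijection, so "uniform over labeled trees"
  is exact.
* Enumeration order is the lexicographic order of canonical
  upper-triangular adjacency encodings — deterministic across sessions.

## Known limitations

* The finite-size convergence of `W_{N,α}` under temperature
  initialization is slow: at `α = 0.5, r = 1.1` the exact fixation
  probability computed by the lumped chain is still about 0.04 below the
  `1 - 1/r^2` limit at `N = 2000` (and about 0.03 at `N = 10^4`), with
  the gap shrinking only ~14% per doubling of `N`. The approach to the
  limit is visibly monotone at solvable sizes, but proximity to the limit
  itself lies beyond exact desk-scale computation; the corresponding
  acceptance check documents this honestly rather than loosening its
  band. The balanced family converges much faster (within 0.007 at
  `N = 2000` under uniform initialization).
* Exact full-state solves stop at 14 vertices by design; lumped solvers
  exist only for the vertex-transitive-by-parts families.
* Death–birth updating, frequency-dependent fitness, multiple mutant
  types, and clonal interference are out of scope; the effective rate of
  evolution assumes the sequential-fixation regime.
* Directed graphs are supported generically (strong connectivity
  enforced), but no directed families or enumerations are provided.
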