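---
title: "Methods: chaotic-map optimization and budget-constrained architecture search"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: chaotic-map optimization and budget-constrained architecture search}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chaonas)
```

This vignette documents the models, parameters and design decisions behind
`chaonas`, in the spirit of a statistical package's methods write-up: what
is computed, under which assumptions, and which choices were genuinely open
and how they were resolved.

## Chaotic maps as randomness sources

A chaotic map is a deterministic iterated function with sensitive
dependence on initial conditions; orbits of a good map fill their range
densely and with low autocorrelation, which makes them attractive
replacements for pseudo-random draws in population metaheuristics. The six
maps implemented are

| map | iteration | native range | analytic λ |
|---|---|---|---|
| logistic | $x' = 4x(1-x)$ | $[0,1]$ | $\ln 2 \approx 0.693$ |
| tent | $x/0.7$ if $x<0.7$, else $(1-x)/0.3$ | $[0,1]$ | $-0.7\ln 0.7 - 0.3\ln 0.3 \approx 0.611$ |
| sine | $x' = \sin(\pi x)$ | $[0,1]$ | — (estimated) |
| Hénon | $x' = 1 - 1.4x^2 + y,\; y' = 0.3x$ | attractor box | $\approx 0.419$ (accepted value) |
| Chebyshev | $x' = \cos(4\arccos x)$ | $[-1,1]$ | $\ln 4 \approx 1.386$ |
| circle | $x' = x + 0.5 - \tfrac{1.5}{2\pi}\sin(2\pi x) \bmod 1$ | $[0,1)$ | — (estimated) |

The Lyapunov exponent is estimated as the orbit average of
$\ln|f'(x_n)|$ for the 1-D maps, and by Benettin tangent-vector iteration
with per-step renormalization for the 2-D Hénon map (a 2-D map has no
scalar derivative; the largest exponent is the growth rate of a
Jacobian-propagated tangent vector). The piecewise-linear tent map has the
exact exponent $-p\ln p - (1-p)\ln(1-p)$ at breakpoint $p$, which together
with the conjugacy results for logistic and Chebyshev gives three
closed-form oracles the estimator must match; the test suite holds it to
±0.02 at $10^6$ steps. Two deliberate non-results: the sine map estimate
lands near $\ln 2$ (it is smoothly conjugate to a full unimodal family),
and the circle map at $\Omega = 0.5,\ K = 1.5$ is mode-locked with a
*negative* exponent. Both are reported as estimated, not asserted against
any external value, and the circle map doubles as a non-chaotic control in
comparative runs.

Numerical guards, all of which matter in practice:

* **Transient.** Orbits discard 100 steps before use so values are drawn
  from the attractor, not the arbitrary start.
* **Anti-absorption.** A tent or logistic orbit hitting 0 (or 1, which maps
  to 0) in floating point stays there forever. Values within $10^{-12}$ of
  an absorbing fixed point are nudged by $10^{-6}$. The Chebyshev endpoints
  ±1 get the same guard.
* **Seeding.** The starting point is uniform in $(0.05, 0.95)$, re-nudged
  if it happens to be a fixed point; everything downstream is a pure
  function of `(map, seed)`.
* **Normalization.** Chebyshev values are mapped from $[-1,1]$ and Hénon
  primary values from $[-1.5, 1.5]$ (clipped — transient excursions can
  leave the nominal box) onto $[0,1]$, so all consumers see unit-interval
  values. The Hénon rule is a package choice covering the attractor's
  x-range; nothing canonical exists.

## The optimizer

`heoa_optimize()` minimizes over a box. With budget $T$ and 0-based
iteration counter $t$:

**Exploration ($t < T/4$).** Every individual moves to
$\beta\,(1-t/T)\,(X_i - X_{best})\odot \mathrm{Levy} + X_{best}(1-t/T) +
(X_{mean}-X_{best})\,\lfloor r/f_{jump}\rfloor f_{jump}$, where
$\beta = 0.2(1-t/T)(X_i - X_{mean})$ element-wise, the Lévy steps use the
Mantegna scheme at $\gamma = 1.5$ (scale $\sigma \approx 0.6966$), and
$f_{jump} = (lb-ub)/\delta$ with $\delta = 1000$, the midpoint of the
sensible range $[100, 2000]$. The floor-quantized jump produces a lattice
of displacement magnitudes rather than a continuum, which is the point: it
scatters probes at discrete offsets around the mean.

**Development ($t \ge T/4$).** A stable ascending sort assigns roles with
cutoffs $\lceil 0.4N\rceil, \lceil 0.8N\rceil, \lceil 0.9N\rceil$. Leaders
contract ($\omega X e^{-t/(rT)}$ if an assessment draw falls below
$A = 0.6$, else $\omega X + R_n\mathbf{1}$); explorers take
$R_n \odot \exp((X_{worst}^2 - X_i^2)/2)$ element-wise; followers step a
random fraction $R_d \in [1, D]$ of the way to the best; losers reflect
about the best. All positions are clipped to the box; updates are accepted
unconditionally, and elitism lives solely in a separately tracked global
best that is never lost.

Choices that were genuinely open, and how they were fixed:

* The explorer exponent squares coordinates and overflows on wide domains
  (e.g. $[-100,100]^{30}$); it is clamped to $[-50, 50]$, preserving sign
  and ordering while keeping arithmetic finite. A plainly degenerate rule
  as printed, read in the most conservative repairable way; alternates
  (e.g. norm-based readings) are noted in the source.
* $R_d$ is a scalar uniform real in $[1, D]$; scalar-vs-vector ambiguity in
  the leader/loser noise is resolved as: leader additive noise and loser
  reflection use a *scalar* normal, explorer noise is *per element*.
* $X_{best}$ is the global best, not the iteration-local one.
* The exploration boundary is `t < T/4` on the 0-based counter, so a
  `T = 4` run has exactly one exploration iteration.
* Legacy coefficients (`c1`, `c2`, a linearly decaying `a`) are carried in
  the configuration for completeness but enter no update rule; no equation
  uses them, and inventing one would change the algorithm.

**Multi-chaotic variant.** With `chaotic_draws = TRUE` (default), the
scalar steering draws — the jump fraction $r$, the leader assessment $R$,
the follower fraction — come from the configured chaotic map; normal
deviates remain pseudo-random (a chaotic source is a substitute for
*uniform* variates; forcing it into normal tails would change the
distributions). With `reinit = TRUE`, whenever mean per-dimension
population spread, normalized by the box width (n-denominator standard
deviation, so two coincident individuals give exactly 0), falls below
0.01 during development, the worst $\lceil 0.2N\rceil$ individuals are
replaced by fresh chaotic positions. Setting
`map = "logistic", chaotic_draws = FALSE, reinit = FALSE` recovers the
original algorithm's behavior (logistic initialization, pseudo-random
steering).

Every stochastic component owns a named stream derived from the master
seed (`init`, `moves`, `reinit`, `gauss`, `unif`), so adding draws in one
component cannot perturb another and single-seed runs are exactly
reproducible.

A structural caveat the test suite respects: the leader contraction pulls
toward the origin, so origin-centered benchmarks (Sphere, Rastrigin) are
structurally easy and can reach exactly 0 by underflow. The shifted suite
members, whose optima sit at a seeded point in the middle half of the
domain, are the honest difficulty tests; this is exactly why the suite
includes them.

## Benchmark harness

Ten objectives (five classics and their seeded shifts) at a configurable
dimension, default 30. Shifts are drawn uniformly from the middle half of
the domain — away from bounds, destroying origin symmetry — and satisfy
$f_{shift}(x) = f_{base}(x - shift)$ exactly. Summaries use sample
statistics ($n-1$ denominator), success rate at tolerance $10^{-3}$
(all optima are 0), and convergence speed as the 1-based first crossing
with sentinel $T+1$ when never reached. The win table attributes each
function to the map with the lowest mean final best, ties broken toward
the earlier map in the fixed order logistic, tent, sine, Hénon, Chebyshev,
circle, so wins always sum to the number of functions. Final metaheuristic
fitness values are implementation-sensitive (they depend on every RNG
stream detail), so the package treats cross-map comparisons as the unit of
meaning — formats, conservation laws and qualitative ranks — rather than
asserting particular fitness magnitudes.

## Genome codec and parameter budget

The 28-gene codec: $L = \min(\lfloor 2 + 9x_1\rfloor, 10)$ (a uniform grid
on $x_1$ covers every depth in 2..10); layer kinds by the thresholds 0.33
and 0.67; channels $16\,\mathrm{round}((32 + 480x)/16)$ clipped to
$[32, 512]$ — the full 16-multiples lattice, 31 values; three typed
pooling slots over {none, max, avg} with positions $\lfloor xL\rfloor + 1$;
gene 26 reserved (the encoding carries four position genes but only three
typed slots; pairing the first three keeps the codec well-defined); FC
width by quarters over {64, 128, 256, 512}; dropout $0.8\,x_{28}$.
Decoding is total and pure: every genome yields an architecture, and
structural problems are the validator's to report (spatial collapse under
halving poolings, skip-first, colliding pooling slots — collisions are
coalesced earlier-slot-wins and reported).

Parameter counting fixes conventions so counts are reproducible: 3×3
kernels, biases, no normalization layers; depthwise separable =
$9C_{in} + C_{in} + C_{in}C_{out} + C_{out}$; skip = identity, zero
parameters, forwarding its input width; classifier = global average
pooling, then $C_{last}\to fc \to 4$ dense with biases. Global average
pooling is forced by arithmetic: a flatten head at 224×224 would by itself
dwarf the $10^6$ budget and contradict the premise of a sub-million-weight
network. The budget models an embedded accelerator: $10^6$ float32 weights
are 4 MB, several times a small FPGA's on-chip block RAM, so the gate
$params < 10^6$ with penalty −1000 makes every over-budget candidate
strictly dominated by any feasible one.

## Search, surrogate and fixtures

`nas_search()` negates the fitness into the minimizing optimizer over
$[0,1]^{28}$ (tent map, N = 20, T = 100 by default). Genomes failing
validation or the budget are penalized *before* the evaluator runs — the
evaluator contract (`(architecture, seed) -> accuracy in [0,1]`,
deterministic) is the expensive resource, and the per-generation feasible
fraction plus the cumulative call count are logged to make that economy
auditable. A training-based evaluator is just another
`external_evaluator()`; tests never require one.

The bundled surrogate is a closed form, monotone in depth and capacity
with ±0.02 content-hashed jitter:
$\mathrm{clip}(0.35 + 0.55(1 - e^{-params/3\cdot 10^5})(L/10) + 0.02u, 0, 1)$.
It reproduces the *structure* of the real problem (feasibility gate, a
landscape where capacity helps, deterministic re-evaluation) but none of
its substance: no data passes through it, so search results demonstrate
plumbing and constraint handling, not learned accuracy. The same honesty
applies to the image fixtures: four procedurally distinct texture classes
(scattered blobs / one eccentric peripheral blob / a sharp central spot /
concentric rings) over a radial background with seeded noise, balanced,
single-channel, pixels in $[0,1]$ — the right shapes, balance and value
ranges for pipeline tests, with no anatomical content whatsoever. Passing
tests say nothing about real MRI data.

The stratified splitter uses largest-remainder rounding per class with a
running global-deficit tie-break: per-class proportions are within one
item of 70/15/15, splits partition the indices, and the global totals are
as close to the fractions as integers allow (a balanced 4×750 set splits
exactly 2100/450/450; a per-class-only rule would give 452/448).

## Problem sizes in the shipped tests

Unit tests run at small scale (populations ≤ 12, ≤ 100 iterations, orbits
≤ $10^5$). The end-to-end checks use: $10^6$-step orbits for the four
analytically checkable exponents (±0.02); a $10^5$-point tent orbit for
the Kolmogorov–Smirnov uniformity bound 0.01; ten full-scale Sphere runs
(D = 30, N = 30, T = 500) for the $10^3\times$ median-improvement
property; and the full 6-map × 10-function grid at 3 runs × 150
iterations for the win-table machinery — run-count and iteration budget
are the package's chosen desk-scale for that grid, with the full 30 × 500
configuration available through `run_harness()` defaults and the CLI.

## Known limitations

* Five of the six update rules are as printed in their source family;
  where a printed rule is degenerate (explorer exponent) the repair is the
  most conservative one, documented above, and other readings would give a
  different optimizer.
* The optimizer is a global-best algorithm with no greedy acceptance;
  on some landscapes unconditional acceptance plus clipping concentrates
  the population at bounds. The diversity reinitialization exists to
  counter exactly that.
* Search-space cardinality is reported from the codec's own combinatorics
  when needed and is not a headline claim; pooling-slot coalescing makes
  naive products overcounts.
* Maximization problems must be negated by the caller; the native
  direction is minimization.
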