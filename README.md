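# chaonas

Chaotic-map human-evolution optimization and hardware-aware neural
architecture search, in R.

`chaonas` is for people who want to (a) study chaotic maps as structured
randomness sources for population metaheuristics and (b) run a constrained,
reproducible architecture search for compact convolutional classifiers that
must fit an embedded accelerator's memory budget. Everything runs at desk
scale: the search is exercised end-to-end with a deterministic surrogate
evaluator and procedurally generated image fixtures, so no GPU, dataset
download, or network access is needed.

## What is inside

**Chaotic generators.** Six maps with complementary dynamics — logistic
`x' = 4x(1−x)`, tent with breakpoint 0.7, sine `sin(πx)`, the 2-D Hénon map
(`a = 1.4`, `b = 0.3`), the degree-4 Chebyshev map `cos(4 arccos x)`, and a
sine circle map (`Ω = 0.5`, `K = 1.5`) — each with unit-interval
normalization, seeded orbit generation, and Lyapunov-exponent estimation
(log-derivative averaging for 1-D maps, Benettin tangent-vector iteration
for Hénon). Chaos is quantified by the exponent λ: the long-run divergence
rate of nearby trajectories, positive for a chaotic map.

**The optimizer.** A human-evolution-inspired population search over a box
`[lb, ub]^D`. The first quarter of the budget is an exploration phase:
Lévy-flight steps (Mantegna scheme, stability index γ = 1.5) around the
global best plus a quantized jump `⌊r/f_jump⌋·f_jump` toward the population
mean, with `f_jump = (lb − ub)/δ`. The remainder is a development phase in
which individuals are ranked into leaders (top 40 %), explorers (40–80 %),
followers (80–90 %) and losers (90–100 %), each with its own update rule
under the step schedule `ω = 0.2 cos(π/2 (1 − t/T))`. The multi-chaotic
variant draws the scalar steering randomness from a chaotic map and
re-seeds the worst 20 % of the population from the map whenever normalized
diversity drops below 0.01.

**Benchmark harness.** Sphere, Rosenbrock, Rastrigin, Ackley and Griewank
plus seeded shifted variants (optimum displaced into the middle half of the
domain), with per-run records, summary statistics (mean, sd, median, best,
worst, success rate at 10⁻³, convergence speed), and a per-function win
table across maps.

**NAS layer.** A genome is 28 values in `[0,1]` decoded deterministically
into a network: depth L ∈ 2..10, per-layer kind (standard conv / depthwise
separable / skip), channels on the 16-multiples lattice `[32, 512]`, three
typed pooling slots with positions, an FC width in {64, 128, 256, 512} and
a dropout rate in `[0, 0.8]`. Fitness scalarizes validation accuracy
against compactness,

```
Fitness = 0.7 · acc − 0.3 · params/10⁶,   with −1000 if params ≥ 10⁶,
```

so any over-budget candidate is strictly dominated by every feasible one —
the gate models an FPGA whose on-chip memory cannot hold a million float32
weights. Structurally invalid or over-budget genomes are penalized *before*
the evaluator is called. A stratified 70/15/15 splitter and a balanced
4-class synthetic image generator round out the pipeline.

## Worked example

```r
library(chaonas)

chaos_lyapunov_table(n = 1e6, seed = 1)
#>   map       lyapunov
#> 1 logistic     0.693
#> 2 tent         0.611
#> 3 sine         0.689
#> 4 henon        0.419
#> 5 chebyshev    1.39
#> 6 circle      -0.328
```

Logistic, tent, Hénon and Chebyshev reproduce their analytic exponents
(ln 2, −0.7 ln 0.7 − 0.3 ln 0.3, ≈0.419, ln 4). The circle map at these
constants is mode-locked (λ < 0): it is retained as a non-chaotic control.

```r
res <- heoa_optimize(objective("rastrigin", dim = 30),
                     heoa_config(pop_size = 30, max_iters = 500,
                                 map = "tent", seed = 42))
res
#> <heoa_result> map=tent N=30 T=500 seed=42
#>   best fitness: 0 (initial 468.115), 15030 evaluations
```

15030 evaluations is exactly N + T·N = 30 + 500·30 (no diversity
reinitializations triggered here); `tidy(res)` returns the per-iteration
trace and `autoplot(res)` plots it. Origin-centered functions are easy for
this update family — the shifted suite members are the meaningful tests.

```r
nas <- nas_search(pop_size = 20, generations = 40, seed = 42)
nas
#> <nas_result> surrogate evaluator, 609 evaluator calls
#>   best fitness 0.4211 (accuracy 0.7808, 418228 params, under budget: TRUE)
```

609 evaluator calls out of 820 evaluations: the rest were rejected by the
structural/budget gate without scoring. The returned architecture always
satisfies the parameter budget.

```r
budget_report(20, 100, 0.6, 11, batches_per_epoch(2100, 32))
#>   effective_runs total_epochs total_batches
#> 1           1200        13200        871200
```

A command-line front end over the same functions ships in
`inst/cli/chaonas.R` (subcommands `lyapunov`, `orbit`, `optimize`,
`benchmark`, `decode`, `nas`, `fixtures`, `budget`).

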