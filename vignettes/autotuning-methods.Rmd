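---
title: "Methods: the annealed multi-weight swarm and the synthetic instrument"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the annealed multi-weight swarm and the synthetic instrument}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(ipsotune)
```

## The optimization problem

Tuning a quadrupole mass spectrometer means driving three coupled groups of
control values to a state where (i) peaks appear at their true masses, (ii)
peak widths sit inside the unit-mass-resolution windows, and (iii) the peak
intensity clears a pass threshold.  `ipsotune` treats each stage as a bounded
optimization problem over instrument controls and solves it with a particle
swarm variant designed to avoid the local optima that defeat simple
iterative tuners.

## Standard PSO and the improved variant

Standard PSO moves `M` particles through the search box.  Particle `j`
updates its velocity as

    v_j <- w * v_j + c1 * (p_j - x_j) + c2 * (g - x_j)

with `p_j` its personal best, `g` the swarm best, and moves to
`x_j + v_j`, clamped to the box; bests are updated greedily.  The
acceleration coefficients `c1`, `c2` are fresh uniform draws in `[0, 2]`
per update by default (a config switch fixes them); this follows common
practice where the attraction strengths themselves are randomized.

The improved optimizer (`mode = "ipso"` in `run_optimizer()`) adds three
mechanisms:

1. **Multi-weight proposals.**  Instead of one inertia weight, every
   particle computes four candidate velocities from the linear,
   exponential, power and random weight schedules (`compute_inertia_weight()`),
   evaluates the four candidate positions, and keeps the fittest (ties break
   to the declared order L, E, P, R).  Selection happens *before* boundary
   clamping, so a candidate far outside the particle's current box still
   informs the choice of direction even though the executed step is clamped.
2. **Dynamic position boundaries.**  Each particle's feasible box narrows
   around its personal best: elementwise `p ± alpha*|p - x|` where the
   particle is displaced from its best, `p ± beta*|p|` where it sits on it,
   always intersected with the static box.  We read the update with absolute
   values (the raw difference form can invert the bounds) and widen an
   exactly-zero box by a floor of `1e-6` of the static range so particles
   never freeze.  Small coefficients turn each particle into a contracting
   local search; large ones leave the box slack until the particle's own
   oscillation has collapsed.
3. **Annealed best acceptance.**  With temperature `T` cooled by
   `T <- eta * T` each iteration, the reported swarm best follows the
   all-time history argmax when `exp(-dE/T) > eps` (with
   `dE = f(g) - max_j f(x_j)`), and otherwise *regresses* to the
   current-iteration best — an escape move that lets the attractor leave an
   exhausted basin.  Personal bests are treated analogously with their own
   threshold draws.  `eps` is a fresh uniform draw per test by default; a
   fixed value is available, and `eps = 0` provably disables escapes (the
   comparison is evaluated in log space, so this holds even when
   `exp(-dE/T)` underflows).  The optimizer always returns the history best
   alongside the reported best, so escape moves never lose the best solution
   found.

Determinism: one seeded RNG drives everything.  Per iteration the draw
order is, for each particle, `c1`, `c2`, then the random-schedule weight if
active; after evaluation, the global annealing threshold, then one
per-particle threshold.  Two runs with the same seed are bitwise identical,
and the improved mode with a singleton schedule, static bounds and
`eps = 0` reproduces standard PSO trajectories exactly.

## Two parameter regimes

The dynamic-boundary coefficients and the cooling rate put the optimizer on
a spectrum between exploration and exploitation, and the package
deliberately uses different defaults in its two applications:

* **Instrument tuning** (`tune_config()`): `alpha = 0.1`, `beta = 0.05`,
  `T0 = 80`, `eta = 0.9`, iteration cap 50 — tight boxes and fast cooling.
  The tuning objectives are smooth and near-separable, so contracting local
  refinement around each particle's best is exactly what is wanted.
* **Benchmark comparisons** (`compare_algorithms()`): `alpha = 2`,
  `beta = 0.5`, and cooling scaled to the budget as
  `eta = 0.9^(50/budget)`.  With the tuning values, a 300-iteration run
  collapses the temperature to ~1e-12, at which point every late
  regression is escape-accepted and the reported bests churn randomly;
  tight boxes additionally reduce the swarm to independent local searches.
  The loose boxes only bind once a particle's oscillation has already
  collapsed — which is the stated purpose of the dynamic boundary — and the
  scaled cooling preserves the same total temperature decay as a
  50-iteration run at `eta = 0.9`.  These defaults were fixed by pilot runs
  during development.

## The benchmark suite

`make_problem()` builds eight shifted/rotated test problems on
`[-100, 100]^D` with seeded shift vectors (inside `[-80, 80]^D`) and
QR-based random rotations: a sum-of-different-powers unimodal function
(bias 200), Rosenbrock (400), expanded Schaffer F6 (600), Schwefel (1000),
two hybrids that split the rotated coordinates into 4 and 6 base-function
chunks (1500, 2000), and two compositions of 5 and 6 shifted components
mixed by distance-based Gaussian weights (2500, 2800).  The official
CEC2017 shift/rotation tables are not reproduced; the constructions share
the structural form and bias values, and every instance places its global
optimum exactly at the drawn shift vector.  Numerical choices worth noting:

* The Schwefel kernel `z*sin(sqrt(|z|))` is centred on its analytic
  optimum (located numerically once, to 1e-12) and coordinates are
  saturated at ±500, keeping every instance bounded below by its bias
  without the piecewise boundary terms of the official suite.  The
  Schwefel problem itself carries the conventional printed constant
  418.9829 per dimension, so its value at the optimum is 1000 + 1.3e-4.
* Composition weights are `exp(-d^2 / (2 D sigma^2)) / d`, normalised to
  sum to one, with the first component's shift equal to the global
  optimum; a candidate exactly on a component shift takes that component
  alone.
* Per-base coordinate shrink factors keep magnitudes sane on the wide
  domain (e.g. 0.02048 for Rosenbrock, 0.0512 for the rastrigin-like
  base), in the spirit of the official lambda factors.

## The synthetic instrument

`instrument_ground_truth()` hides a true instrument state behind a simple
forward model:

* **Mass axis**: DAC = `omega * mass + zeta` (defaults 50 DAC units per
  m/z, intercept 120); a detuned DAC displaces the peak centroid by the
  DAC error divided by `omega`.
* **Resolution**: each anchor mass (59.05, 616.46, 906.67 m/z) has a true
  OFFSET in `[-8, 8]`; the FWHM grows linearly at 0.08 m/z per offset unit
  away from it, floored at 0.2 m/z, with targets 0.6/0.7/0.725 m/z at the
  three anchors (the midpoints of the acceptance windows).
* **Intensity**: a separable Gaussian response over (CUR, GS1, DP, EP)
  with optimum (20, 40, 80, 10) and widths about a quarter of each axis
  box — ion-source responses are broad on real instruments — floored at a
  2% residual transmission, scaled to an apex of 1e6 counts.  An optional
  decoy mode (a second, strictly lower response peak) exists specifically
  to exercise the optimizer's escape behaviour.
* **Noise**: 3% multiplicative intensity noise, 0.005 m/z mass-reading
  jitter, and a flat 50-count baseline on a 0.01 m/z grid spanning ±3 m/z
  around the target.

Peak metrology (`measure_peak()`) is deliberately explicit: apex sample,
intensity-weighted centroid over the contiguous run above half maximum,
and FWHM from linearly interpolated half-maximum crossings.  A flank that
never drops below half maximum inside the window yields a missing FWHM; an
apex below the detection floor raises a typed no-peak error.  Tuning
objectives average three acquisitions per evaluation to tame noise.

What the simulator does *not* emulate: ion optics, space charge,
isotope patterns, peak asymmetry, drift over time, or the absolute
count-per-second scale of any real instrument.  Passing tests demonstrate
that the tuning logic recovers a hidden linear/Gaussian instrument state
under realistic noise — not that it would tune any particular hardware.

## The staged tuning pipeline

`run_autotune()` follows the staged procedure: alternate mass-axis and
resolution calibration until the stage-I condition holds at every anchor,
then optimise the source parameters until the intensity threshold is met.

* **Stage-I objective**: `lambda2*(FW - TFW)^2 + lambda3*(MASS - TMASS)^2`
  per anchor (both weights default to 1), terminated at `eps_I`.  We set
  `eps_I = lambda2 * (0.8 * halfwidth)^2` of each FWHM window: at the full
  halfwidth the condition only implies the window at its exact boundary,
  where a fresh noisy measurement flips outside with ~50% probability; the
  20% margin dwarfs the ~0.01 m/z FWHM measurement noise.
* **Mass axis**: per anchor, the correction
  `DAC <- DAC + omega * (target - measured)` converges in one step when
  the slope estimate is exact.  The loop iterates to an internal target of
  0.05 m/z — tighter than the 0.2 m/z pass bound — because the residual
  mass error enters the stage-I objective that the resolution stage cannot
  reduce.  The line is refit over all anchors afterwards and its R^2
  recorded.
* **Resolution**: the selected anchors' offsets are optimised jointly by
  the improved swarm (swarm size 30, one particle warm-started at the
  current offsets so progress accumulates across alternation passes).
  The first alternation pass calibrates all anchors jointly; later passes
  revisit only anchors still failing the condition, which converges much
  faster than repeating the full joint search.
* **Stage II**: the swarm maximises the measured apex intensity over the
  (CUR, GS1, DP, EP) box and stops once it reaches the pass threshold
  (7e5 counts by default, 70% of the clean apex).  The weighted
  single-expression form of the evaluation function is retained for stage
  I; for stage II we terminate directly on the intensity threshold, which
  is the flowchart reading of the termination condition.  Setting the
  threshold above the reachable intensity turns the stage into a pure
  refinement run to the iteration cap, which is how the parameter-recovery
  checks obtain sub-percent recovery of the hidden optimum.

Problem sizes used by the automated checks were chosen to keep the full
suite comfortably interactive: benchmark comparisons run 10 seeds at
dimension 10, population 100 and 300 iterations; tuning checks run the
pipeline's default swarm (30 particles, 50-iteration stages, up to 6
alternation passes) on the default-noise instrument.

## Known limitations

* The dynamic-boundary update is aggressive: coordinates of a particle
  whose personal best sits near zero can barely move while the particle
  rests on its best (`beta * |p|` is then tiny).  The width floor prevents
  a hard freeze, and the defaults place instrument optima away from zero,
  but highly zero-crossing search problems are better served by the loose
  benchmark regime.
* Stage II optimises intensity at one reference anchor; the simulated
  response is mass-independent, so this is exact here but would be an
  approximation on hardware.
* The repeatability and compliance checks quantify behaviour on the
  synthetic instrument only; absolute intensities and their
  coefficients of variation are not comparable to hardware values.
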