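---
title: "Chance-constrained reserve selection: model, engines and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Chance-constrained reserve selection: model, engines and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(probreserve)
```

## The planning problem

Systematic conservation planning divides a region into planning units,
assigns each a cost, and asks for the cheapest selection that holds at
least a target amount `T_j` of every conservation feature, usually with a
compactness incentive on the boundary length of the selected set.  The
classic formulation treats the occurrence data as certain.  In practice
they rarely are: species distribution models and habitat maps attach a
probability, not a fact, to each occurrence, and threatening processes
(bleaching, fire, degradation, succession) can remove whole sites from
the system after they are protected.

`probreserve` replaces the deterministic target constraint with a
chance constraint: feature `j` must meet its target with probability at
least `P_j`.  Two probability modes cover the common data situations:

* **species mode** (`species_2d`): every occurrence `(j, i)` carries its
  own existence probability, e.g. a thresholded-free SDM prediction or a
  habitat-map accuracy;
* **threat mode** (`threat_1d`): every planning unit carries one loss
  probability that applies to all features it contains, e.g. a
  catastrophic-event risk or a condition/degradation estimate.

Both reduce to a single per-occurrence survival probability
`1 - q_ij`; a `deterministic` mode (all `q_ij = 0`) recovers the classic
problem.  Survival events are assumed independent across planning units
and features; covariation (e.g. a spatially correlated catastrophe
hitting neighbouring reefs together) is outside the model, and results
should be read with that in mind.

## Capture probability

Given a selection `x`, the retained amount of feature `j` is a sum of
independent scaled Bernoulli variables, so its capture probability is a
Poisson-binomial tail.  Two engines compute it.

**Exact engine.** When the amounts of the selected carriers lie on a
common grid (in particular when all amounts are equal, the usual case for
presence/absence data) the distribution of the retained amount is built
by convolution — cost `O(k · total)` with `k` carriers — at any problem
size.  Off-grid amounts fall back to enumeration of the `2^k` survival
outcomes, refused above `k = 20` (the default `enumeration_limit`) with
an error advising the approximation.  Certain carriers (`q = 0`) are
folded into a deterministic base amount first and impossible ones
(`q = 1`) dropped, so only genuinely uncertain carriers are enumerated.
An amount within `1e-9` of the target counts as meeting it, matching the
`>=` of the target constraint.

**Normal approximation.** Inside an annealer the exact tail is too
expensive, so the default engine appeals to the central limit theorem:
the retained amount is approximated as normal with mean
`mu_j = sum r_ij x_i (1 - q_ij)` and variance
`sigma2_j = sum r_ij^2 x_i q_ij (1 - q_ij)`, and
`p_j = Pr(Z >= z_j)` with `z_j = (T_j - mu_j) / sigma_j`, evaluated with
the complementary normal CDF (`stats::pnorm`).  The quantity driving the
z-score is treated as a variance (and its square root used in the
standardisation) — anything else would not give a standard score.  The
approximation is deliberately crude for few carriers (two carriers of
probability 0.5 give an exact 0.75 but an approximate 0.5) and tightens
as carriers accumulate; the test suite checks |approx − exact| ≤ 0.05 on
homogeneous 50-unit features across presence probabilities 0.2–0.8.

**Degenerate variance.** When every selected carrier is certain the
variance is numerically zero (threshold `1e-12`) and the z-score is
undefined; the retained amount is a point mass at `mu_j`, so the engine
returns `p = 1` if `mu_j` reaches the target and `0` otherwise.  This
limit rule is this package's own reconstruction of behaviour the original
tooling leaves unspecified.

## The objective

```
total = sum_i c_i x_i
      + b * boundary_length(x)
      + y * sum_j F_j R_j * rep_penalty_j
      + w * sum_j F_j R_j * H(P_j - p_j) * s_j
```

* **Boundary length**: each stored segment between a selected and an
  unselected unit counts once; a self-segment (a unit's exposed outer
  edge) counts while its unit is selected.  This is the unordered
  equivalent of the ordered double-sum formulation and matches the
  community `bound.dat` convention.
* **Representation penalty**: `R_j` is the representation cost —
  the cost of the greedy (ascending cost-per-amount, id-ascending
  tie-break) set of units that meets feature j's target on its own —
  computed once at problem construction and cached.  `"step"` style
  charges `y F_j R_j` while the target is unmet; `"proportional"` style
  scales by the unmet fraction, which gives the annealer a gradient on
  coarse-amount features.  A target held exactly counts as met: charging
  a penalty at equality would contradict the `>=` in the constraint.
* **Probability penalty**: charged only while `p_j < P_j` (Heaviside),
  proportional to the shortfall.  The default `"normalized"` style
  divides the shortfall by `P_j`, making penalties comparable across
  features with different reliability requirements; `"raw"` style uses
  the plain difference, which is the arithmetic of the worked 4-unit
  example (`penalty = 0.3` when one unit leaves species 4 at `p = 0.6`
  against `P = 0.9`).  Features with `P_j = 0` opt out of the
  probability constraint entirely and participate only in the
  deterministic representation penalty — the normalized shortfall would
  be undefined for them.
* Both penalty terms are carried, each with its own weight (`y`, `w`).
  A formulation with the probability penalty alone would leave
  features without probability targets unconstrained; setting `y = 0`
  recovers it when wanted.  With all probabilities equal to 1 and
  targets met, both penalties vanish and the objective reduces to the
  classic cost-plus-boundary form (a property the test suite asserts).

## Solvers

**Simulated annealing** proposes uniform random single-unit flips among
the non-locked units and accepts a flip with objective change `d` when
`d < 0` or with probability `exp(-d / temperature)`.  The temperature
decays geometrically over `temperature_steps` steps spread across
`iterations` flips.  No annealing schedule is canonical for this problem,
so the default is adaptive: the initial temperature is the 90th
percentile of |d| over 100 random flips from the initial solution (so
early acceptance is near-indiscriminate), the final temperature is
`1e-4` of it, and both are overridable.  Flip deltas are evaluated
incrementally — cost and boundary in `O(degree)`, probability states only
for the features the flipped unit carries — and the per-feature state is
rebuilt from scratch at every temperature step to cap floating-point
drift.  The inner loop is compiled (Rcpp) for the normal-approximation
engine, which is how the original field tooling is built and what makes
`1e5`-flip schedules practical; the exact engine runs the same algorithm
in R and is meant for small instances.  Locked-in and locked-out units
(statuses 2 and 3) are never proposed; status 1 units start selected but
are free to leave.

**Improvement** (`improve()`) runs steepest-descent passes — apply the
best improving flip until none exists — guaranteeing a single-flip local
optimum.  **`solve_exact()`** enumerates all selections of up to 20 free
units as a testing oracle, breaking objective ties (within `1e-9`)
toward fewer selected units and then the lexicographically smallest id
set, so results are reproducible.  `run_batch()` derives one seed per
repetition from the master seed, runs anneal-plus-improve, and
aggregates per-unit selection frequencies (the summed solution, the
field's irreplaceability heuristic).

## Synthetic landscapes

`random_problem()` generates the seeded fixtures the test suite runs on:
a rook-adjacency grid with unit-length shared edges and exposed perimeter
edges stored as per-cell self-segments (a corner cell's self-segment has
length 2), lognormal unit costs (default `meanlog 0`, `sdlog 0.3` — mild,
realistic cost heterogeneity), and features occupying a uniform-random
30% of cells by default with amount 1 and Beta(2, 2) existence
probabilities — a broad, symmetric spread of SDM-like probabilities.
Default targets are half of each feature's occupied amount, penalty
factors 5, probability targets 0.9.  What these landscapes do *not*
emulate: spatial autocorrelation in species occurrence or cost,
correlated survival between neighbouring units, heavy-tailed occurrence
amounts, and the scale of real planning regions (the suite works at tens
to hundreds of units).  Passing tests therefore demonstrate correctness
of the machinery, not performance claims on real regional datasets.

The three 4-unit worked examples (`figure1_problem()`) carry unit costs
and no boundary segments, so the printed probability arithmetic is the
only active mathematics.

## Numerical choices

* Variance below `1e-12` is degenerate (point mass).
* Amounts or probabilities within `1e-9` of a target count as meeting it.
* The objective decomposition (`total = cost + b·boundary + rep + prob`)
  is maintained to `1e-9` under arbitrarily long chains of incremental
  flips (drift is capped by periodic recomputation).
* The exhaustive solver's tie window is `1e-9`; the annealer records a
  new best only when it improves by more than `1e-12`.
* The upper-tail probability is computed continuously via `pnorm`, not
  from tabulated percentiles; partners agree to machine precision with
  the symmetric identity `tail(z) + tail(-z) = 1`.

## Problem sizes in the test suite

The suite validates the exact engine against brute-force enumeration on
200 random instances of up to 12 uncertain carriers, the annealer against
the exhaustive optimum on twenty 10-unit landscapes (best of ten `1e5`-flip
runs each), incremental deltas against full re-evaluation over `1e4`
random flips, and the CLT gap on 50-carrier homogeneous features — sizes
chosen so the whole suite runs in well under a minute per property while
still exercising every code path.

## Known limitations

* Independence of survival events is assumed throughout; no covariance
  or spatial autocorrelation of losses.
* One probability mode per problem; mixed per-site and per-occurrence
  uncertainty is a mode conflict at read time.
* No multi-zone problems and no asymmetric connectivity; the boundary
  term is symmetric.
* The greedy representation cost `R_j` is an upper-bound heuristic (as
  in the classic tooling), not the optimal covering cost.
* Off-grid amount sets larger than 20 uncertain carriers have no exact
  tail; use the normal approximation there.
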