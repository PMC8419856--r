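# probreserve

Chance-constrained reserve selection by simulated annealing.

`probreserve` is a decision-support engine for systematic conservation
planning.  It solves the minimum-set reserve design problem — pick the
cheapest, suitably compact set of planning units that meets a
representation target for every conservation feature — in settings where
the data are uncertain: a feature mapped to a site may not actually be
there (species-distribution-model output, habitat-map accuracy), or a site
and everything in it may be lost over the planning horizon (bleaching,
fire, degradation).  Instead of the deterministic constraint "hold at
least T_j of feature j", each feature must meet its target *with a
user-specified probability*.  It is written for conservation planners and
researchers who already work with Marxan-style input tables.

## The model

A selection is an indicator vector x over N planning units with costs c_i.
Feature j occurs in unit i at level r_ij, and each occurrence survives the
planning horizon independently with probability 1 − q_ij, where q_ij is
either the site loss probability (threat mode, one value per unit) or one
minus the occurrence existence probability (species mode, one value per
occurrence).  The amount of feature j retained is then a sum of
independent scaled Bernoulli variables, and its capture probability is the
Poisson-binomial tail

    p_j(x, T_j) = Pr( Σ_i r_ij x_i B_ij ≥ T_j ),   B_ij ~ Bernoulli(1 − q_ij).

The solver minimises the four-term objective

    Σ_i c_i x_i                                   site cost
    + b · (boundary length of the selected set)   compactness
    + y · Σ_j F_j R_j · rep-shortfall penalty_j    missed targets
    + w · Σ_j F_j R_j · H(P_j − p_j) · s_j         missed probability targets

where F_j is the feature penalty factor, R_j the representation cost of
meeting feature j's target on its own (greedy cheapest-per-amount), P_j
the probability target, H the Heaviside step and s_j the probability
shortfall (P_j − p_j, optionally normalized by P_j).  Good solutions are
found by simulated annealing over single-unit flips with a geometric
cooling schedule, followed by steepest-descent improvement; small
instances can be solved exhaustively.

Computing p_j exactly inside an annealer is too expensive at realistic
sizes, so the default engine approximates the retained amount by a normal
distribution with mean μ_j = Σ r_ij x_i (1 − q_ij) and variance
σ²_j = Σ r²_ij x_i q_ij (1 − q_ij), and takes the upper tail at the
standard score z_j = (T_j − μ_j)/σ_j.  The exact Poisson-binomial engine
(dynamic programming on a common amount grid, enumeration otherwise)
remains available for evaluation, reporting and small problems.

## Worked example

The package ships the classic 4-unit illustration: two species in species
mode, one occurring in units p2 (probability 0.9) and p3 (0.3) with
probability target 0.8, the other in p2 (0.6), p3 (0.8) and p4 (0.1) with
probability target 0.9; every representation target is one occurrence.

```r
library(probreserve)
prob <- figure1_problem(3)
cfg <- run_config(prob_weight = 5, engine = "exact", repetitions = 5, seed = 1,
                  schedule = anneal_schedule(2000, 20))
res <- run_batch(prob, cfg)
res
#> 5 annealing runs; best objective 2 (run 1)
#> objective range: [2, 2]
best <- res$solutions[[res$best_index]]
prob$pu$id[best == 1]
#> [1] 2 3
evaluate(prob, best, cfg)
#> objective total 2 = cost 2 + boundary 0 + representation penalty 0
#>   + probability penalty 0 [engine exact]
mv <- missing_values_report(prob, best, cfg)
mv[, c("id", "target", "held", "ptarget", "prob", "prob_shortfall", "prob_target_met")]
#>   id target held ptarget prob prob_shortfall prob_target_met
#> 1  3      1    2     0.8 0.93              0            TRUE
#> 2  4      1    2     0.9 0.92              0            TRUE
```

Selecting p2 alone would capture species 4 with probability only 0.6
(shortfall 0.3 against its 0.9 target); adding p3 lifts the capture
probabilities to 0.93 and 0.92, so both probability targets are met and
only the two unit costs remain in the objective.  A deterministic solver
would have been satisfied with a single occurrence of each species and
would never have added the second unit.

A command-line interface is installed as `exec/probreserve`
(`solve --input input.dat`, `validate --input DIR`,
`generate --spec spec.json --out DIR`), reading the classic `input.dat` /
`pu.dat` / `spec.dat` / `puvspr.dat` / `bound.dat` table dialect with the
probability extensions (`prob` columns, `ptarget1d`/`ptarget2d`).

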