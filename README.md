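# consdp

Stochastic dynamic programming for conservation and natural-resource
management, under the uncertainties that actually plague it.

Managers of biological systems choose actions repeatedly over time —
harvest regulations, habitat protection, removals, translocations — and
each action yields an immediate return while shifting the odds on the
system's future. `consdp` solves this family of discrete, discounted
Markov decision problems in five variants that differ by what is hidden
from the manager:

* **MDP** — environmental variation only: the classic Bellman recursion
  `V(x) = max_a [ R(a|x) + λ Σ_x' P(x'|x,a) V(x') ]`, solved by value
  iteration or backward induction.
* **Adaptive management** — structural uncertainty: K rival transition
  models with Bayesian weights `q`, solved over a simplex grid in both
  *active* mode (anticipated learning enters the backup via the updated
  weights `q'`) and *passive* mode (planning at the current weights,
  learning only after the fact). The gap between them is the value of
  information.
* **POMDP** — partial observability: belief filtering
  `b'(x') ∝ f(o'|x',a) Σ_x P(x'|x,a) b(x)`, exact finite-horizon
  alpha-vector backup with dominance pruning, and a point-based
  lower-bound solver for larger instances.
* **MOMDP** — mixed observability: jointly observable `x` and hidden
  `y`, with the belief on `y` alone; includes the embedding that casts
  adaptive management as a mixed-observability process.
* **Nonstationary** — the governing model itself drifts by a Markov
  chain `P(y'|y)`; filtering is predict-then-correct and the value
  recursion takes the return under the prior weights, the transition
  under the drifted weights, and the continuation at the corrected
  weights.

Every layered solver provably collapses onto the simpler ones (known
model ⇒ MDP at the simplex corners; perfect monitoring ⇒ MDP; identity
drift ⇒ stationary adaptive; the adaptive/MOMDP embedding is
value-identical), and the test suite enforces these identities against
independent brute-force oracles: exhaustive stationary-policy
enumeration, expectimax belief trees, and joint-distribution filters.

## Worked example: a harvested population

The bundled generator builds one biology — abundance classes 0–100, a
productive and a degraded growth regime, three harvest levels — under
every uncertainty treatment:

```r
library(consdp)
fam <- harvest_problem()

sol <- value_iteration(fam$mdp)
solution_table(fam$mdp, sol)
#>   state action   value
#> 1    n0   none   0.000
#> 2   n25   none 116.748
#> 3   n50  light 138.369
#> 4   n75  heavy 157.251
#> 5  n100  heavy 171.329
```

The optimal known-model policy rests the collapsed and low classes,
harvests lightly at mid abundance, and takes heavily at high abundance;
the values are expected cumulative discounted returns (here, units of
harvested animals at λ = 0.9).

With the growth model uncertain, compare anticipatory and
after-the-fact learning from a 50–50 prior at mid abundance:

```r
act <- solve_active_adaptive(fam$adaptive, grid = 50)
pas <- solve_passive_adaptive(fam$adaptive, grid = 50)
realized <- evaluate_adaptive_policy(fam$adaptive, pas)

grid_value_at(act, "n50", c(0.5, 0.5))
#> [1] 91.40383
simplex_interpolate(act$grid, realized["n50", ], c(0.5, 0.5))
#> [1] 91.33859
```

Active planning is worth 91.40 versus 91.34 for the passively planned
policy evaluated under the true updating dynamics — a small but strictly
nonnegative value of information, as theory requires.

## Command line

A thin Rscript entry point (`inst/cli/consdp`) exposes the same
functionality as verbs over the label-keyed JSON problem format:
`generate`, `validate`, `solve-mdp`, `solve-adaptive --mode
active|passive`, `solve-pomdp --method exact|point-based`,
`solve-momdp`, `solve-nonstationary`, `sweep` (rival drift scenarios
with a policy-disagreement table), `reduce` (adaptive → MOMDP), and
`simulate`. Every run writes a RunRecord JSON with the resolved options
and output digests.

## Further reading

The methods vignette
(`vignettes/conservation-decision-processes.Rmd`) documents the model
family, the simplex-grid value representation, the within-period event
ordering under drift, all numerical tolerances, and the limits of the
synthetic testbed.
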