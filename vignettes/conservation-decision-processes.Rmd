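---
title: "Markov decision frameworks for conservation management"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Markov decision frameworks for conservation management}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(consdp)
```

## The problem family

Conservation decisions are sequential: a manager chooses an action at each
decision point (harvest regulations, habitat protection, translocation),
collects an immediate return, and changes the odds on where the system goes
next.  `consdp` treats this as a family of discrete Markov decision
problems that differ only in which sources of uncertainty they admit:

| process class | hidden quantity | belief object |
|---|---|---|
| `mdp_problem` | none | — |
| `adaptive_problem` | which of K rival models is true | model weights `q` |
| `pomdp_problem` | the system state itself | belief `b` over states |
| `momdp_problem` | a hidden state component `y` | belief `b_y` over `y` |
| `nonstationary_problem` | the governing model, which *drifts* | weights `q` under a model chain |

All five share one backbone: a discrete state space, a discrete action
set, row-stochastic transition kernels $P(x'|x,a)$ (environmental and
demographic noise already marginalized in), a return table $R(a|x)$ in
management units, and a per-step discount $\lambda \in [0,1]$.  The
fully observed optimum solves the Bellman recursion

$$V(x) = \max_a \Big[ R(a|x) + \lambda \sum_{x'} P(x'|x,a)\, V(x') \Big],$$

and each uncertainty layer re-derives this recursion over an augmented
state.  The package's central design commitment is that every layered
solver must *provably collapse back* onto the simpler ones — those
reductions are the backbone of the test suite, not just documentation.

## Structural uncertainty and the model state

Under structural uncertainty the manager carries K rival transition
models with weights $q_k$ summing to one.  Observing a transition
$(x, a, x')$ updates the weights by Bayes' rule,
$q'_k \propto q_k P_k(x'|x,a)$, and planning happens over pairs
$(x, q)$.  Two optimization modes are supported:

* **active** (`solve_active_adaptive`): the continuation value inside
  the backup is read at the *updated* weights $q'$, so the anticipated
  information content of an action contributes to its value;
* **passive** (`solve_passive_adaptive`): the backup reads the
  continuation at the *current* weights.  Learning still happens in
  simulation — the weights are updated after every transition — it is
  simply not anticipated during planning.

The difference between the active optimum and the realized value of the
passively planned policy (`evaluate_adaptive_policy`, which fixes the
passive policy and evaluates it under the true updating dynamics) is the
value of information of anticipatory management.  It is nonnegative by
construction, and the acceptance suite verifies this at every grid
point.

## Representing values on the belief simplex

The model weights (and hidden-state beliefs) live on a continuous
simplex, so values cannot be tabulated exactly.  `consdp` uses a regular
simplex grid of resolution `m` (`simplex_grid`) with barycentric
interpolation on the standard Freudenthal subdivision
(`simplex_weights`).  This representation was chosen because

* interpolation weights are convex and sum to one, so interpolated
  values never leave the convex hull of the grid values and interpolated
  beliefs never leave the simplex;
* linear functions are reproduced exactly, and grid points reproduce
  themselves exactly — in particular simplex *corners* are fixed points
  of the Bayes update, which is what makes the corner-collapse identity
  (`q_k = 1` recovers the known-model solution) hold to solver
  tolerance rather than to grid tolerance;
* refining `m` gives Cauchy-type convergence of grid values without any
  change to the solver.

Defaults are `m = 50` for two models and `m = 20` for three, a
desk-scale compromise between interpolation error and the
$\binom{m+K-1}{K-1}$ growth of the grid.  Each solver precomputes, per
action, a dense transition operator on the augmented state $(x, g)$
whose entries combine branch probabilities with the interpolation
weights of the updated belief; value iteration is then a sequence of
matrix products, stopped when the sup-norm residual falls below `tol`
(default `1e-8`, giving a fixed-point error of at most
$\mathrm{tol}\cdot\lambda/(1-\lambda)$).  Greedy actions use the
lowest action index on ties, so policies are deterministic and testable.

Off-grid policy lookups during simulation
(`adaptive_greedy_action` and friends) do a one-step greedy lookahead
against the interpolated value function rather than interpolating the
policy table itself; interpolating discrete action indices is
meaningless, and the lookahead is consistent with how the value was
computed.

## Partial observability

When the state itself is monitored with error, status is carried as a
belief $b$ filtered by predict-then-correct:
$b'(x') \propto f(o'|x',a) \sum_x P(x'|x,a) b(x)$, with the observation
marginal $P(o'|b,a)$ as normalizer.  Two solvers are provided, chosen so
that one can serve as the oracle for the other:

* `solve_pomdp_exact` performs the exact finite-horizon cross-sum
  backup over alpha vectors, enumerating every assignment of successor
  vectors to observations.  Pruning uses pointwise dominance only — it
  is sound (never removes a vector that contributes to the upper
  envelope's maximum at any belief) and sufficient at the tiny sizes
  where exactness is wanted.  A guard refuses backups whose cross-sum
  would exceed a configurable cap and directs the caller to the
  point-based solver.
* `solve_pomdp_point_based` repeats point-based backups at a fixed
  belief set, initialized from the constant lower-bound vector
  $\min R /(1-\lambda)$, so its value function is a lower bound of the
  infinite-horizon optimum everywhere.  Tests verify the bound against
  a deep exact solve plus the discounting tail
  $\lambda^h R_{\max}/(1-\lambda)$.

Zero-probability observation branches are skipped inside backups (they
contribute nothing to the expectation and would otherwise produce 0/0
updates); at filtering time the same situation raises an
impossible-evidence error naming the offending action and observation,
because it signals a malformed model rather than valid data.

Observations taken *before* a transition appear in the formal
architecture of these models but never enter any recursion (only the
post-transition observation carries evidence); the package therefore
does not model them.

## Mixed observability

Many conservation systems split naturally into an observable component
`x` (habitat class, say) and a hidden one `y` (a cryptic population, or
an unknown model).  `momdp_problem` carries a joint kernel
$P(x',y'|x,y,a)$ and hidden-component observation model
$f(o_y'|x',y',a)$; the observable component needs no observation space
since $o_x \equiv x'$.  The belief lives on `y` alone — dimension
$|Y|-1$ instead of $|X||Y|-1$ — which is the computational point of the
mixed formulation, and `solve_momdp` reuses the same simplex-grid
machinery as the adaptive solver on exactly that lower-dimensional
simplex.

Two embeddings connect the classes:

* `adaptive_to_momdp` encodes the model index as a *static* hidden
  state with a single uninformative observation symbol.  Using a dummy
  symbol with probability one (rather than a special-cased "no
  observation" code path) means the ordinary mixed update reproduces the
  model-weight update verbatim, and the mixed solver reproduces the
  active adaptive solution to solver tolerance.
* `nonstationary_to_momdp` gives the hidden state the drift matrix as
  its own dynamics, $P(x',y'|x,y,a) = P(y'|y) P_{y'}(x'|x,a)$, which
  makes the mixed filter coincide with the nonstationary
  predict-then-correct filter.

## Nonstationarity

Systemic change — climate-driven shifts in vital rates, progressive
habitat degradation — is modeled as a Markov chain on model space: a
row-stochastic drift matrix $P(y'|y)$ applied every period.  The
within-period event order is fixed as *return, then model drift, then
state transition*: the immediate return is valued under the prior
weights $q$, the state transition under the drift-predicted weights
$q'$, and the continuation at the corrected weights $q''$ obtained by
Bayes-conditioning $q'$ on the observed transition.  Alternative
orderings genuinely change values, so the order is pinned both in the
solver and by an oracle test that enumerates the event sequence
directly.  An identity drift matrix collapses everything back to the
stationary adaptive solution, exactly.

Drift matrices are scenario inputs, never estimated: any specification
of future systemic change is speculative, so the supported workflow
(`scenario_sweep`) solves under a set of named rival drift scenarios and
tabulates where their policies disagree.  Drift is time-homogeneous and
independent of states and actions; driver-shift stories are accommodated
by encoding the shifted regimes as distinct models.

## Oracles

Every recursion in the package is checked against an independent
brute-force implementation that shares no code with the solver it
checks:

* `enumerate_stationary_policies` evaluates all $|A|^{|X|}$ stationary
  policies by exact linear solve;
* `expectimax_tree` recursively alternates max over actions and
  expectation over stochastic branches, carrying the class-appropriate
  augmented state;
* `joint_filter_oracle` enumerates all hidden paths consistent with an
  evidence sequence and normalizes their joint probabilities.

Monte-Carlo rollouts (`rollout`) complete the chain from solved values
to simulated management: hidden quantities are drawn from their declared
priors, the class filter runs step by step, and the truncation horizon
for effectively infinite rollouts is chosen from the explicit bias bound
$\lambda^T R_{\max}/(1-\lambda)$ (`truncation_horizon`).

## The synthetic harvest testbed

The package ships no field data; it generates its study systems.
`harvest_problem` builds one shared biology — a population on discrete
abundance classes, per-class growth multipliers, harvest fractions per
action, return proportional to expected harvest — and exposes it under
each uncertainty treatment: a known-model baseline, a two-model adaptive
version contrasting a productive and a degraded growth regime, a
partially observed version with a monitoring confusion matrix, and a
nonstationary version in which the productive regime decays (default
drift 0.05 per period toward the degraded model, 0.02 back).  Expected
abundance after growth and harvest is split between the two adjacent
grid classes so the mean dynamics are preserved on the discrete grid;
heavy harvest collapses future abundance classes, which is what makes
"take now versus conserve for later" genuinely bite in tests.  The
default discount is 0.9, a conventional choice for multi-decadal
renewable-resource planning.

What these fixtures emulate — and what they do not: the generator
reproduces the *structure* of small harvest-management problems
(density-independent growth per class, mean-preserving discretization,
confusion-matrix monitoring), not the demography of any species.  There
is no age structure, no spatial structure, no environmental
autocorrelation, and noise enters only through class redistribution and
monitoring error.  Passing tests therefore certify the solvers and
their cross-class identities, not the realism of any particular
parameterization.

`random_mdp` and `random_model_set` provide seeded random instances:
Dirichlet kernel rows with a concentration control, and rival kernels at
a calibrated per-row total-variation distance built by moving a fixed
amount of probability mass from the high-probability half of each row to
the rest (disjoint donor/recipient supports make the realized distance
equal the target; targets above 1/2 may be clipped by the simplex
boundary).

## Numerical choices, in one place

* Row-stochasticity tolerance `1e-12` everywhere in memory; file input
  renormalizes rows off by at most `1e-6` with a note and rejects worse.
* Value-iteration default `tol = 1e-8` on the sup-norm residual.
* Arg-max ties: lowest action index, at every level (backups, grid
  solvers, alpha sets).
* Alpha-vector deduplication/dominance tolerance `1e-12`.
* Beliefs are clipped at zero and renormalized after each update to
  absorb roundoff at the simplex boundary.
* Impossible evidence (zero likelihood under every hypothesis) is an
  error naming the evidence, never a silent renormalization.
* Rewards are state-and-action dependent, `R(a|x)`; a next-state
  dependent form `R(x,a,x')` is deliberately not supported, matching
  how returns are written throughout this model family.  Whether costs
  are netted into `R` is the user's choice; the package treats `R` as
  the already-netted return.
* Model-specific reward tables are allowed in a `model_set` but default
  to one shared table, the common applied case.

## Problem sizes used in the shipped checks

The bundled tests and the acceptance script run at deliberately small
sizes — 2–5 states, 2–3 actions, K = 2 models, grid resolutions 10–60,
exact alpha backups to horizon 10, 400–2000 rollout replicates — chosen
so the whole verification suite solves dozens of problem instances in a
few minutes on a single core while still exercising every code path.
The solvers themselves accept any sizes; the practical ceiling is the
exact POMDP backup (exponential in the observation count) and the
simplex grid (combinatorial in K), which is the standard trade-off for
this class of methods.

## Known limitations

* Continuous state, action, or observation spaces are out of scope.
* Exact POMDP solution is finite-horizon only; infinite-horizon
  partially observed values are lower-bounded by the point-based solver
  rather than computed exactly.
* Structural uncertainty and hidden system state are combined only
  through the mixed-observability embeddings above; a joint
  belief over (model, state) pairs beyond those embeddings is not
  implemented.
* Drift matrices cannot be learned from data, only compared as
  scenarios.
* Simplex-grid solvers interpolate a convex value function piecewise
  linearly, so off-grid values carry an upward bias that shrinks with
  `m`; tests that compare across solvers at off-grid points use
  explicit interpolation allowances rather than pretending the bias
  away.
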