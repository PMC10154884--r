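#' A nonstationary hidden-model decision problem
#'
#' The governing model itself drifts over time by a Markov chain on model
#' space: within each period the manager collects the immediate return
#' under the prior model weights, the model then transitions
#' \eqn{y \to y'} with probabilities \eqn{P(y'|y)}, and the system state
#' transitions under the *posterior* model.  Filtering is
#' predict-then-correct: drift the model weights forward, then
#' Bayes-correct them against the observed state transition.
#'
#' @inheritParams adaptive_problem
#' @param drift `K x K` row-stochastic model-transition matrix
#'   \eqn{P(y'|y)}.
#' @return object of class `nonstationary_problem`.
#' @export
nonstationary_problem <- function(states, actions, models, prior, drift,
                                  discount,
                                  horizon = horizon_spec("infinite")) {
  structure(
    list(states = as.character(states), actions = as.character(actions),
         models = models, prior = as.numeric(prior),
         drift = as.matrix(drift), discount = as.numeric(discount),
         horizon = horizon),
    class = c("nonstationary_problem", "consdp_problem"))
}

#' @export
validate_problem.nonstationary_problem <- function(problem, ...) {
  v <- validate_problem.adaptive_problem(problem, ...)
  K <- problem$models$K
  d <- problem$drift
  if (!all(dim(d) == c(K, K)))
    v <- c(v, sprintf("drift matrix is not %d x %d", K, K))
  else if (!check_row_stochastic(d))
    v <- c(v, "drift matrix is not row-stochastic")
  v
}

#' A named drift scenario
#'
#' Nonstationary drift is necessarily speculative, so analyses are run
#' over a set of rival drift scenarios rather than a single estimate.
#'
#' @param name scenario name.
#' @param drift row-stochastic model-transition matrix.
#' @param description free-text note.
#' @return object of class `drift_scenario`.
#' @export
drift_scenario <- function(name, drift, description = "") {
  drift <- as.matrix(drift)
  if (!check_row_stochastic(drift)) stopf("drift matrix is not row-stochastic")
  structure(list(name = name, drift = drift, description = description),
            class = "drift_scenario")
}

#' Drift-predict the model weights
#'
#' \eqn{q'(y') = \sum_y q(y) P(y'|y)} — one step of the model-transition
#' chain applied to the current weights, before any data arrive.
#'
#' @param q model-weight vector.
#' @param drift row-stochastic model-transition matrix.
#' @return predicted weight vector.
#' @export
predict_model_belief <- function(q, drift) {
  drop(q %*% as.matrix(drift))
}

#' Predict-then-correct model-state update under drift
#'
#' Drifts the weights forward with [predict_model_belief()], then
#' Bayes-corrects against the observed state transition under the
#' posterior model:
#' \deqn{q''(y') = q'(y') P_{y'}(x'|x,a) / \sum_j q'(j) P_j(x'|x,a).}
#' With an identity drift matrix this reduces exactly to
#' [update_model_belief()].
#'
#' @param q current model weights.
#' @param x,a,x_next observed transition (labels or indices).
#' @param problem a [nonstationary_problem()].
#' @return corrected weight vector.
#' @export
nonstationary_update <- function(q, x, a, x_next, problem) {
  x <- resolve_index(x, problem$states, "state")
  a <- resolve_index(a, problem$actions, "action")
  xn <- resolve_index(x_next, problem$states, "state")
  qp <- predict_model_belief(q, problem$drift)
  lik <- vapply(problem$models$kernels, function(kr) kr[[a]][x, xn], numeric(1))
  post <- qp * lik
  denom <- sum(post)
  if (denom <= 0)
    stopf("impossible evidence: transition (x=%s, a=%s, x'=%s) has zero probability under every drift-predicted model",
          problem$states[x], problem$actions[a], problem$states[xn])
  post / denom
}

## grid operators for the nonstationary recursion: immediate return under
## the prior weights q, transition under the drift-predicted q', and
## continuation at the corrected q''
nonstationary_grid_ops <- function(problem, grid) {
  nX <- length(problem$states)
  nA <- length(problem$actions)
  nG <- nrow(grid$points)
  n <- nX * nG
  rewards <- vector("list", nA)
  trans <- vector("list", nA)
  for (a in seq_len(nA)) {
    Ra <- numeric(n)
    Ma <- matrix(0, n, n)
    for (g in seq_len(nG)) {
      q <- grid$points[g, ]
      qp <- predict_model_belief(q, problem$drift)
      Rq <- averaged_reward(q, problem$models)
      for (x in seq_len(nX)) {
        i <- xg_index(x, g, nX)
        Ra[i] <- Rq[x, a]
        lik <- vapply(problem$models$kernels,
                      function(kr) kr[[a]][x, ], numeric(nX))
        if (nX == 1L) lik <- matrix(lik, 1L)
        pmix <- drop(lik %*% qp)             # P(x'|x,a,q')
        for (xn in seq_len(nX)) {
          if (pmix[xn] <= 0) next
          qn <- qp * lik[xn, ] / pmix[xn]    # q''
          qn <- pmax(qn, 0); qn <- qn / sum(qn)
          sw <- simplex_weights(grid, qn)
          jj <- xg_index(xn, sw$idx, nX)
          Ma[i, jj] <- Ma[i, jj] + pmix[xn] * sw$w
        }
      }
    }
    rewards[[a]] <- Ra
    trans[[a]] <- Ma
  }
  list(rewards = rewards, trans = trans)
}

#' Solve a nonstationary hidden-model problem
#'
#' Value iteration (or backward induction for finite horizons) on the
#' augmented state `(x, q)`: at every grid point the returned value
#' satisfies
#' \deqn{V(x,q) = \max_a [ R(a|x,q) + \lambda \sum_{x'} P(x'|x,a,q')
#'   V(x', q''(x,a,x')) ]}
#' within `tol`, where \eqn{q'} is the drift-predicted and \eqn{q''} the
#' corrected model state.  An identity drift matrix reproduces
#' [solve_active_adaptive()].
#'
#' @param problem a [nonstationary_problem()].
#' @param grid a [simplex_grid()] over models, or an integer resolution.
#' @param tol convergence threshold.
#' @return a `grid_solution`.
#' @export
solve_nonstationary <- function(problem, grid = 50L, tol = 1e-8) {
  v <- validate_problem(problem)
  if (length(v)) stopf("invalid problem:\n%s", paste("-", v, collapse = "\n"))
  if (!inherits(grid, "simplex_grid")) grid <- simplex_grid(problem$models$K, grid)
  if (grid$K != problem$models$K) stopf("grid dimension must equal K")
  ops <- nonstationary_grid_ops(problem, grid)
  sol <- if (problem$horizon$kind == "finite")
    grid_backward_induction(ops, problem$discount, problem$horizon$T)
  else {
    if (problem$discount >= 1) stopf("infinite horizon requires discount < 1")
    grid_value_iteration(ops, problem$discount, tol)
  }
  grid_result(sol$value, sol$policy, problem$states, problem$actions,
              grid, sol$iterations)
}

#' Solve a nonstationary problem under several drift scenarios
#'
#' Solves the problem once per scenario and tabulates where the optimal
#' policies disagree, giving the range of policy implications across
#' rival assumptions about nonstationary change.
#'
#' @param problem a [nonstationary_problem()] (its own drift matrix is
#'   ignored in favor of each scenario's).
#' @param scenarios list of [drift_scenario()] objects.
#' @param grid,tol as in [solve_nonstationary()].
#' @return list with `solutions` (named per scenario) and `disagreement`,
#'   a data frame of (state, grid point, per-scenario action label) rows
#'   restricted to cells where scenarios differ.
#' @export
scenario_sweep <- function(problem, scenarios, grid = 50L, tol = 1e-8) {
  if (length(scenarios) < 1L) stopf("need at least one scenario")
  if (!inherits(grid, "simplex_grid")) grid <- simplex_grid(problem$models$K, grid)
  sols <- lapply(scenarios, function(sc) {
    p <- problem
    p$drift <- sc$drift
    solve_nonstationary(p, grid, tol)
  })
  names(sols) <- vapply(scenarios, `[[`, character(1), "name")
  pol <- vapply(sols, function(s) as.integer(s$policy),
                integer(length(sols[[1L]]$policy)))
  if (is.null(dim(pol))) pol <- matrix(pol, nrow = 1L)
  differ <- apply(pol, 1L, function(r) length(unique(r)) > 1L)
  nX <- length(problem$states)
  idx <- which(differ)
  dis <- data.frame(
    state = problem$states[(idx - 1L) %% nX + 1L],
    grid_point = apply(grid$points[(idx - 1L) %/% nX + 1L, , drop = FALSE],
                       1L, paste, collapse = "/"),
    stringsAsFactors = FALSE)
  for (s in seq_along(sols))
    dis[[names(sols)[s]]] <- problem$actions[pol[idx, s]]
  list(solutions = sols, disagreement = dis)
}

#' Embed a nonstationary problem as a mixed-observability problem
#'
#' The hidden component is the model index with the drift matrix as its
#' own dynamics: \eqn{P(x',y'|x,y,a) = P(y'|y) P_{y'}(x'|x,a)}, matching
#' the within-period ordering return, model drift, state transition.
#' Filtering this embedding with [mixed_belief_update()] reproduces
#' [nonstationary_update()] exactly.
#'
#' @param problem a [nonstationary_problem()].
#' @return a [momdp_problem()].
#' @export
nonstationary_to_momdp <- function(problem) {
  nX <- length(problem$states)
  K <- problem$models$K
  nA <- length(problem$actions)
  kernel <- vector("list", nA)
  obs <- vector("list", nA)
  rewards <- array(0, c(nX, K, nA))
  for (a in seq_len(nA)) {
    ker <- array(0, c(nX, K, nX, K))
    for (y in seq_len(K)) for (yn in seq_len(K))
      ker[, y, , yn] <- problem$drift[y, yn] *
        problem$models$kernels[[yn]][[a]]
    kernel[[a]] <- ker
    obs[[a]] <- array(1, c(nX, K, 1L))
    for (y in seq_len(K))
      rewards[, y, a] <- problem$models$rewards[[y]][, a]
  }
  momdp_problem(problem$states, paste0("model", seq_len(K)),
                problem$actions, kernel,
                observations = "none", obs_model = obs,
                rewards = rewards, discount = problem$discount,
                initial_belief = problem$prior, horizon = problem$horizon)
}
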