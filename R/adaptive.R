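#' A set of rival system models
#'
#' Structural uncertainty is represented by `K` rival models of the same
#' managed system: each model has its own transition kernel
#' \eqn{P_k(x'|x,a)} and (optionally) its own reward table
#' \eqn{R_k(a|x)}.  When a single reward table is supplied it is shared by
#' every model, which is the common applied case.
#'
#' @param kernels list of `K` kernels, each a list with one
#'   \eqn{|X| \times |X|} matrix per action.
#' @param rewards either one \eqn{|X| \times |A|} matrix shared by all
#'   models, or a list of `K` such matrices.
#' @return object of class `model_set`.
#' @export
model_set <- function(kernels, rewards) {
  K <- length(kernels)
  if (K < 1L) stopf("need at least one model")
  if (is.matrix(rewards)) rewards <- rep(list(rewards), K)
  if (length(rewards) != K)
    stopf("rewards must be one shared table or one table per model")
  structure(list(K = K, kernels = kernels, rewards = rewards),
            class = "model_set")
}

#' An adaptive-management problem
#'
#' A managed system whose dynamics are uncertain among `K` rival models,
#' with a Bayesian model state `q` (a probability vector of model weights)
#' updated from observed state transitions.  Policies assign an action to
#' every combination of system state and model state.
#'
#' @param states,actions,discount,horizon as in [mdp_problem()].
#' @param models a [model_set()].
#' @param prior length-`K` probability vector of prior model weights.
#' @return object of class `adaptive_problem`.
#' @export
adaptive_problem <- function(states, actions, models, prior,
                             discount, horizon = horizon_spec("infinite")) {
  structure(
    list(states = as.character(states), actions = as.character(actions),
         models = models, prior = as.numeric(prior),
         discount = as.numeric(discount), horizon = horizon),
    class = c("adaptive_problem", "consdp_problem"))
}

#' @export
validate_problem.adaptive_problem <- function(problem, ...) {
  v <- character()
  K <- problem$models$K
  if (length(problem$prior) != K || !is_prob_vector(problem$prior))
    v <- c(v, "prior is not a probability vector of length K")
  for (k in seq_len(K)) {
    sub <- mdp_problem(problem$states, problem$actions,
                       problem$models$kernels[[k]],
                       problem$models$rewards[[k]],
                       problem$discount, problem$horizon)
    vk <- validate_problem(sub)
    if (length(vk)) v <- c(v, paste0("model ", k, ": ", vk))
  }
  v
}

## the MDP obtained by assuming model k is true
model_mdp <- function(problem, k) {
  mdp_problem(problem$states, problem$actions,
              problem$models$kernels[[k]], problem$models$rewards[[k]],
              problem$discount, problem$horizon)
}

#' Bayesian model-state update
#'
#' After observing a transition from `x` to `x_next` under action `a`, the
#' model weights are updated by Bayes' rule:
#' \deqn{q'_k = q_k P_k(x'|x,a) / \sum_j q_j P_j(x'|x,a).}
#'
#' @param q current model weights (probability vector of length `K`).
#' @param x,a,x_next state, action and next-state, given as labels or
#'   1-based indices.
#' @param models a [model_set()] (an [adaptive_problem()] is also
#'   accepted).
#' @param states,actions label vectors used to resolve labels when
#'   `models` is a bare [model_set()].
#' @return updated probability vector.
#' @export
update_model_belief <- function(q, x, a, x_next, models,
                                states = NULL, actions = NULL) {
  if (inherits(models, "adaptive_problem") ||
      inherits(models, "nonstationary_problem")) {
    states <- models$states; actions <- models$actions
    models <- models$models
  }
  x <- resolve_index(x, states, "state")
  a <- resolve_index(a, actions, "action")
  x_next <- resolve_index(x_next, states, "state")
  lik <- vapply(models$kernels, function(kr) kr[[a]][x, x_next], numeric(1))
  post <- q * lik
  denom <- sum(post)
  if (denom <= 0)
    stopf("impossible evidence: transition (x=%s, a=%s, x'=%s) has zero probability under every weighted model",
          as.character(x), as.character(a), as.character(x_next))
  post / denom
}

resolve_index <- function(i, labels, what) {
  if (is.character(i)) {
    if (is.null(labels)) stopf("%s labels needed to resolve '%s'", what, i)
    j <- match(i, labels)
    if (is.na(j)) stopf("unknown %s label '%s'", what, i)
    return(j)
  }
  as.integer(i)
}

#' Model-averaged transition kernel
#'
#' \eqn{P(x'|x,a,q) = \sum_k q_k P_k(x'|x,a)} — the predictive kernel under
#' the current model weights.
#'
#' @inheritParams update_model_belief
#' @return list of per-action row-stochastic matrices.
#' @export
averaged_transition <- function(q, models) {
  if (inherits(models, "adaptive_problem")) models <- models$models
  nA <- length(models$kernels[[1L]])
  lapply(seq_len(nA), function(a) {
    Reduce(`+`, Map(function(w, kr) w * kr[[a]], q, models$kernels))
  })
}

#' Model-averaged reward table
#'
#' \eqn{R(a|x,q) = \sum_k q_k R_k(a|x)}.
#'
#' @inheritParams update_model_belief
#' @return reward matrix.
#' @export
averaged_reward <- function(q, models) {
  if (inherits(models, "adaptive_problem")) models <- models$models
  Reduce(`+`, Map(`*`, q, models$rewards))
}

## Precompute grid operators for the adaptive recursion.
## active:  continuation read at the Bayes-updated q' (interpolated)
## passive: continuation read at the current grid point q (frozen)
adaptive_grid_ops <- function(problem, grid, passive = FALSE) {
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
      Rq <- averaged_reward(q, problem$models)
      for (x in seq_len(nX)) {
        i <- xg_index(x, g, nX)
        Ra[i] <- Rq[x, a]
        lik <- vapply(problem$models$kernels,
                      function(kr) kr[[a]][x, ], numeric(nX))
        if (nX == 1L) lik <- matrix(lik, 1L)   # models in columns
        pmix <- drop(lik %*% q)                # P(x'|x,a,q)
        for (xn in seq_len(nX)) {
          if (pmix[xn] <= 0) next
          if (passive) {
            Ma[i, xg_index(xn, g, nX)] <- Ma[i, xg_index(xn, g, nX)] + pmix[xn]
          } else {
            qn <- q * lik[xn, ] / pmix[xn]
            qn <- pmax(qn, 0); qn <- qn / sum(qn)
            sw <- simplex_weights(grid, qn)
            jj <- xg_index(xn, sw$idx, nX)
            Ma[i, jj] <- Ma[i, jj] + pmix[xn] * sw$w
          }
        }
      }
    }
    rewards[[a]] <- Ra
    trans[[a]] <- Ma
  }
  list(rewards = rewards, trans = trans)
}

solve_adaptive_impl <- function(problem, grid, tol, passive) {
  v <- validate_problem(problem)
  if (length(v)) stopf("invalid problem:\n%s", paste("-", v, collapse = "\n"))
  if (!inherits(grid, "simplex_grid")) grid <- simplex_grid(problem$models$K, grid)
  if (grid$K != problem$models$K) stopf("grid dimension must equal K")
  ops <- adaptive_grid_ops(problem, grid, passive = passive)
  sol <- if (problem$horizon$kind == "finite")
    grid_backward_induction(ops, problem$discount, problem$horizon$T)
  else {
    if (problem$discount >= 1) stopf("infinite horizon requires discount < 1")
    grid_value_iteration(ops, problem$discount, tol)
  }
  grid_result(sol$value, sol$policy, problem$states, problem$actions,
              grid, sol$iterations)
}

#' Solve an adaptive-management problem (active learning)
#'
#' Active adaptive optimization: the continuation value inside the Bellman
#' recursion is read at the *Bayes-updated* model state, so anticipated
#' learning influences the choice of action.  At every grid point the
#' returned value satisfies
#' \deqn{V(x,q) = \max_a [ R(a|x,q) + \lambda \sum_{x'} P(x'|x,a,q)
#'   V(x', q'(x,a,x')) ]}
#' within `tol`, with off-grid \eqn{q'} interpolated barycentrically.
#'
#' @param problem an [adaptive_problem()].
#' @param grid a [simplex_grid()] over the `K` models, or an integer
#'   resolution `m` from which one is built.
#' @param tol sup-norm convergence threshold.
#' @return a `grid_solution`: `value` and `policy` matrices of shape
#'   `|X| x n_grid_points`, plus the grid.
#' @export
solve_active_adaptive <- function(problem, grid = 50L, tol = 1e-8) {
  solve_adaptive_impl(problem, grid, tol, passive = FALSE)
}

#' Solve an adaptive-management problem (passive learning)
#'
#' Passive adaptive optimization: the planning recursion reads the
#' continuation value at the *current* model state, so learning does not
#' influence the choice of action.  During simulation the model state is
#' still updated after every transition — learning happens, it is just not
#' anticipated.
#'
#' @inheritParams solve_active_adaptive
#' @return a `grid_solution`.
#' @export
solve_passive_adaptive <- function(problem, grid = 50L, tol = 1e-8) {
  solve_adaptive_impl(problem, grid, tol, passive = TRUE)
}

#' Evaluate a fixed grid policy under the true (updating) dynamics
#'
#' Fixes the action prescribed at every (state, grid point) cell and
#' evaluates the resulting policy on the belief-augmented chain in which
#' the model state *is* Bayes-updated at every transition.  This is the
#' realized value of following, e.g., a passively planned policy, and is
#' the quantity to compare against the active optimum when measuring the
#' value of information.
#'
#' @param problem an [adaptive_problem()] with infinite horizon.
#' @param solution a `grid_solution` whose policy is to be evaluated.
#' @return matrix of realized values, shape `|X| x n_grid_points`.
#' @export
evaluate_adaptive_policy <- function(problem, solution) {
  grid <- solution$grid
  ops <- adaptive_grid_ops(problem, grid, passive = FALSE)
  n <- length(ops$rewards[[1L]])
  pol <- as.integer(solution$policy)
  R <- vapply(seq_len(n), function(i) ops$rewards[[pol[i]]][i], numeric(1))
  M <- t(vapply(seq_len(n), function(i) ops$trans[[pol[i]]][i, ], numeric(n)))
  V <- solve(diag(n) - problem$discount * M, R)
  matrix(V, length(problem$states), nrow(grid$points),
         dimnames = list(problem$states, NULL))
}

#' Greedy action of a grid solution at an exact (state, belief) pair
#'
#' Off-grid model states are handled by a one-step greedy lookahead
#' against the interpolated value function, which is how simulations act
#' on a solved policy.
#'
#' @param problem the problem the solution came from.
#' @param solution a `grid_solution`.
#' @param x state index or label.
#' @param q model-state vector.
#' @return integer action index.
#' @export
adaptive_greedy_action <- function(problem, solution, x, q) {
  x <- resolve_index(x, problem$states, "state")
  nX <- length(problem$states)
  lam <- problem$discount
  Rq <- averaged_reward(q, problem$models)
  best <- -Inf; best_a <- 1L
  for (a in seq_along(problem$actions)) {
    lik <- vapply(problem$models$kernels, function(kr) kr[[a]][x, ], numeric(nX))
    if (nX == 1L) lik <- matrix(lik, 1L)
    pmix <- drop(lik %*% q)
    cont <- 0
    for (xn in seq_len(nX)) {
      if (pmix[xn] <= 0) next
      qn <- q * lik[xn, ] / pmix[xn]
      qn <- pmax(qn, 0); qn <- qn / sum(qn)
      cont <- cont + pmix[xn] * grid_value_at(solution, xn, qn)
    }
    qa <- Rq[x, a] + lam * cont
    if (qa > best + 1e-12) { best <- qa; best_a <- a }
  }
  best_a
}

#' Simulate adaptive management under a solved policy
#'
#' Draws trajectories with one of the rival models acting as the true
#' system, updating the model state by Bayes' rule after every observed
#' transition, and acting greedily with respect to the solution's
#' interpolated value function.
#'
#' @param problem an [adaptive_problem()].
#' @param solution a `grid_solution` from one of the adaptive solvers.
#' @param true_model_index which model generates the data (1-based).
#' @param horizon number of decision steps per replicate.
#' @param n_reps number of replicates.
#' @param seed integer seed; trajectories are reproducible given the seed.
#' @param start_state initial state index (default 1).
#' @return list with matrices `states`, `actions` (`n_reps x horizon`),
#'   array `q_path` (`n_reps x (horizon+1) x K`) and vector `returns` of
#'   per-replicate discounted returns.
#' @export
simulate_adaptive <- function(problem, solution, true_model_index,
                              horizon, n_reps, seed, start_state = 1L) {
  if (true_model_index < 1L || true_model_index > problem$models$K)
    stopf("true_model_index must be in 1..K")
  if (horizon < 1L || n_reps < 1L) stopf("horizon and n_reps must be >= 1")
  set.seed(as.integer(seed))
  K <- problem$models$K
  nX <- length(problem$states)
  kernels <- problem$models$kernels[[true_model_index]]
  rewards <- problem$models$rewards[[true_model_index]]
  states <- matrix(0L, n_reps, horizon)
  actions <- matrix(0L, n_reps, horizon)
  q_path <- array(NA_real_, c(n_reps, horizon + 1L, K))
  returns <- numeric(n_reps)
  for (r in seq_len(n_reps)) {
    x <- as.integer(start_state)
    q <- problem$prior
    q_path[r, 1L, ] <- q
    rew <- numeric(horizon)
    for (t in seq_len(horizon)) {
      a <- adaptive_greedy_action(problem, solution, x, q)
      xn <- sample.int(nX, 1L, prob = kernels[[a]][x, ])
      rew[t] <- rewards[x, a]
      q <- update_model_belief(q, x, a, xn, problem$models)
      states[r, t] <- x; actions[r, t] <- a
      q_path[r, t + 1L, ] <- q
      x <- xn
    }
    returns[r] <- discounted_sum(rew, problem$discount)
  }
  list(states = states, actions = actions, q_path = q_path, returns = returns)
}
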