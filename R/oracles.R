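## Brute-force oracles: independent, enumeration-based implementations of
## each value recursion and filter, used as ground truth in the test
## suite.  They deliberately share no code with the solvers they check.

#' Enumerate all stationary policies of an MDP
#'
#' Evaluates every one of the \eqn{|A|^{|X|}} stationary policies by exact
#' linear solve and returns the best.  This is the ground-truth oracle for
#' infinite-horizon value iteration.
#'
#' @param problem an [mdp_problem()] with \eqn{\lambda < 1}.
#' @param cap refuse instances with more than `cap` policies.
#' @return list with `value` (per-state optimum over policies), `policy`
#'   (the arg-max policy for the start of the state ordering) and
#'   `n_policies`.
#' @export
enumerate_stationary_policies <- function(problem, cap = 4096L) {
  assert_valid(problem)
  nX <- length(problem$states)
  nA <- length(problem$actions)
  n_pol <- nA^nX
  if (n_pol > cap)
    stopf("%d stationary policies exceed the cap of %d", n_pol, cap)
  ## the discounted optimum dominates at every state, so the per-state
  ## maximum over policies is attained by a single policy
  best_v <- rep(-Inf, nX)
  best_pol <- rep(1L, nX)
  best_sum <- -Inf
  grid <- as.matrix(expand.grid(rep(list(seq_len(nA)), nX)))
  for (i in seq_len(nrow(grid))) {
    pol <- as.integer(grid[i, ])
    v <- policy_value(problem, pol)
    best_v <- pmax(best_v, v)
    if (sum(v) > best_sum) { best_sum <- sum(v); best_pol <- pol }
  }
  list(value = best_v, policy = best_pol, n_policies = n_pol)
}

#' Exact finite-horizon value by expectimax tree enumeration
#'
#' Recursively alternates maximization over actions with expectation over
#' stochastic branches, carrying the augmented state appropriate to the
#' problem class (`x` for an MDP; `(x, q)` with Bayes updating for an
#' adaptive problem; `b` with observation branching for a POMDP;
#' `(x, b_y)` for a mixed problem; `(x, q)` with drift for a
#' nonstationary problem).  An independent implementation of each finite
#' recursion, used as ground truth.
#'
#' @param problem any problem class of this package.
#' @param depth number of decisions remaining.
#' @param ... class-specific start point: `x` (MDP, adaptive,
#'   nonstationary, mixed — index), `q` (adaptive/nonstationary weights),
#'   `b` (POMDP belief), `b_y` (mixed hidden belief).
#' @param terminal_decision if `TRUE`, depth 0 takes one final
#'   reward-only decision instead of valuing 0.
#' @return optimal expected discounted return from the start point.
#' @export
expectimax_tree <- function(problem, depth, ...) UseMethod("expectimax_tree")

#' @rdname expectimax_tree
#' @param x start state index.
#' @export
expectimax_tree.mdp_problem <- function(problem, depth, x,
                                        terminal_decision = FALSE, ...) {
  rec <- function(x, d) {
    if (d == 0L)
      return(if (terminal_decision) max(problem$rewards[x, ]) else 0)
    best <- -Inf
    for (a in seq_along(problem$actions)) {
      val <- problem$rewards[x, a]
      p <- problem$kernel[[a]][x, ]
      for (xn in which(p > 0))
        val <- val + problem$discount * p[xn] * rec(xn, d - 1L)
      best <- max(best, val)
    }
    best
  }
  rec(as.integer(x), as.integer(depth))
}

#' @rdname expectimax_tree
#' @param q model-weight start point.
#' @param mode `"active"` (continuation at updated weights) or
#'   `"passive"` (continuation at current weights).
#' @export
expectimax_tree.adaptive_problem <- function(problem, depth, x, q = problem$prior,
                                             mode = c("active", "passive"),
                                             terminal_decision = FALSE, ...) {
  mode <- match.arg(mode)
  rec <- function(x, q, d) {
    if (d == 0L)
      return(if (terminal_decision) max(averaged_reward(q, problem$models)[x, ]) else 0)
    Rq <- averaged_reward(q, problem$models)
    best <- -Inf
    for (a in seq_along(problem$actions)) {
      val <- Rq[x, a]
      lik <- vapply(problem$models$kernels, function(kr) kr[[a]][x, ],
                    numeric(length(problem$states)))
      if (length(problem$states) == 1L) lik <- matrix(lik, 1L)
      pmix <- drop(lik %*% q)
      for (xn in which(pmix > 0)) {
        qn <- if (mode == "active") q * lik[xn, ] / pmix[xn] else q
        val <- val + problem$discount * pmix[xn] * rec(xn, qn, d - 1L)
      }
      best <- max(best, val)
    }
    best
  }
  rec(as.integer(x), q, as.integer(depth))
}

#' @rdname expectimax_tree
#' @param b belief start point.
#' @export
expectimax_tree.pomdp_problem <- function(problem, depth,
                                          b = problem$initial_belief, ...) {
  rec <- function(b, d) {
    if (d == 0L) return(0)
    best <- -Inf
    for (a in seq_along(problem$actions)) {
      val <- sum(b * problem$rewards[, a])
      marg <- observation_marginal(b, a, problem)
      for (o in which(marg > 0)) {
        bn <- belief_update(b, a, o, problem)
        val <- val + problem$discount * marg[o] * rec(bn, d - 1L)
      }
      best <- max(best, val)
    }
    best
  }
  rec(b, as.integer(depth))
}

#' @rdname expectimax_tree
#' @param b_y hidden-belief start point.
#' @export
expectimax_tree.momdp_problem <- function(problem, depth, x,
                                          b_y = problem$initial_belief, ...) {
  nX <- length(problem$x_states)
  nY <- length(problem$y_states)
  nO <- length(problem$observations)
  rec <- function(x, b, d) {
    if (d == 0L) return(0)
    best <- -Inf
    for (a in seq_along(problem$actions)) {
      ker <- problem$kernel[[a]]
      f <- problem$obs_model[[a]]
      val <- sum(b * problem$rewards[x, , a])
      for (xn in seq_len(nX)) for (o in seq_len(nO)) {
        w <- vapply(seq_len(nY), function(yn)
          sum(b * ker[x, , xn, yn]) * f[xn, yn, o], numeric(1))
        pj <- sum(w)
        if (pj <= 0) next
        val <- val + problem$discount * pj * rec(xn, w / pj, d - 1L)
      }
      best <- max(best, val)
    }
    best
  }
  rec(as.integer(x), b_y, as.integer(depth))
}

#' @rdname expectimax_tree
#' @export
expectimax_tree.nonstationary_problem <- function(problem, depth, x,
                                                  q = problem$prior, ...) {
  rec <- function(x, q, d) {
    if (d == 0L) return(0)
    Rq <- averaged_reward(q, problem$models)
    qp <- predict_model_belief(q, problem$drift)
    best <- -Inf
    for (a in seq_along(problem$actions)) {
      val <- Rq[x, a]
      lik <- vapply(problem$models$kernels, function(kr) kr[[a]][x, ],
                    numeric(length(problem$states)))
      if (length(problem$states) == 1L) lik <- matrix(lik, 1L)
      pmix <- drop(lik %*% qp)
      for (xn in which(pmix > 0)) {
        qn <- qp * lik[xn, ] / pmix[xn]
        val <- val + problem$discount * pmix[xn] * rec(xn, qn, d - 1L)
      }
      best <- max(best, val)
    }
    best
  }
  rec(as.integer(x), q, as.integer(depth))
}

#' Exact conditional distribution of a hidden quantity by enumeration
#'
#' Ground-truth check of the iterated filters: enumerates every hidden
#' path consistent with an evidence sequence, weights each by its joint
#' probability with the evidence, and normalizes.
#'
#' @param problem an adaptive, POMDP, mixed or nonstationary problem.
#' @param evidence class-specific evidence list:
#'   adaptive/nonstationary — list of steps `list(x=, a=, x_next=)`
#'   (indices); POMDP — list of steps `list(a=, o=)`; mixed — list of
#'   steps `list(x=, a=, x_next=, o=)`.
#' @param ... unused.
#' @return exact posterior probability vector over the hidden quantity
#'   (model index, state, or hidden component) after the sequence.
#' @export
joint_filter_oracle <- function(problem, evidence, ...) {
  UseMethod("joint_filter_oracle")
}

#' @export
joint_filter_oracle.adaptive_problem <- function(problem, evidence, ...) {
  ## the model index is fixed over time: weight each model by the
  ## likelihood of the whole transition sequence
  w <- problem$prior
  for (step in evidence) {
    lik <- vapply(problem$models$kernels,
                  function(kr) kr[[step$a]][step$x, step$x_next], numeric(1))
    w <- w * lik
  }
  if (sum(w) <= 0) stopf("impossible evidence sequence")
  w / sum(w)
}

#' @export
joint_filter_oracle.pomdp_problem <- function(problem, evidence, ...) {
  nX <- length(problem$states)
  ## forward enumeration over state paths: w[x] = P(x_t = x, evidence)
  w <- problem$initial_belief
  for (step in evidence) {
    a <- step$a; o <- step$o
    wn <- numeric(nX)
    for (x in seq_len(nX)) for (xn in seq_len(nX))
      wn[xn] <- wn[xn] + w[x] * problem$kernel[[a]][x, xn] *
        problem$obs_model[[a]][xn, o]
    w <- wn
  }
  if (sum(w) <= 0) stopf("impossible evidence sequence")
  w / sum(w)
}

#' @export
joint_filter_oracle.momdp_problem <- function(problem, evidence, ...) {
  nY <- length(problem$y_states)
  w <- problem$initial_belief
  for (step in evidence) {
    ker <- problem$kernel[[step$a]]
    f <- problem$obs_model[[step$a]]
    wn <- numeric(nY)
    for (y in seq_len(nY)) for (yn in seq_len(nY))
      wn[yn] <- wn[yn] + w[y] * ker[step$x, y, step$x_next, yn] *
        f[step$x_next, yn, step$o]
    w <- wn
  }
  if (sum(w) <= 0) stopf("impossible evidence sequence")
  w / sum(w)
}

#' @export
joint_filter_oracle.nonstationary_problem <- function(problem, evidence, ...) {
  K <- problem$models$K
  ## hidden path is the model trajectory: drift, then emit the observed
  ## state transition under the post-drift model
  w <- problem$prior
  for (step in evidence) {
    wn <- numeric(K)
    for (y in seq_len(K)) for (yn in seq_len(K))
      wn[yn] <- wn[yn] + w[y] * problem$drift[y, yn] *
        problem$models$kernels[[yn]][[step$a]][step$x, step$x_next]
    w <- wn
  }
  if (sum(w) <= 0) stopf("impossible evidence sequence")
  w / sum(w)
}

#' Truncation horizon for effectively infinite rollouts
#'
#' Smallest `T` with \eqn{\lambda^T R_{max}/(1-\lambda) \le \epsilon},
#' bounding the bias of truncating a discounted return.
#'
#' @param lambda discount factor < 1.
#' @param r_max maximum absolute one-step reward.
#' @param eps tolerated truncation bias.
#' @return integer horizon.
#' @export
truncation_horizon <- function(lambda, r_max, eps = 1e-6) {
  if (lambda <= 0) return(1L)
  if (r_max <= 0) return(1L)
  as.integer(ceiling(log(eps * (1 - lambda) / r_max) / log(lambda)))
}

#' Monte-Carlo rollout of a policy
#'
#' Simulates the process class of `problem` under a solved policy and
#' accumulates discounted returns.  Hidden quantities (true model, hidden
#' state) are drawn from the declared priors; the class-appropriate filter
#' is applied step by step; the policy is read greedily from the solution
#' representation.  Reproducible given `seed`.
#'
#' @param problem any problem class of this package.
#' @param policy class-specific policy representation: an integer
#'   state-to-action vector (MDP), a `grid_solution` (adaptive, mixed,
#'   nonstationary), or an alpha-vector set (POMDP).
#' @param horizon steps per replicate.
#' @param n_reps replicates.
#' @param seed integer seed.
#' @param start_state start state index where applicable.
#' @param ... unused.
#' @return list of class `rollout_result` with `returns`, `mean`, `se`,
#'   `n_reps`, `horizon`, `seed`, and `truncation_bound` (the bias bound
#'   \eqn{\lambda^T R_{max}/(1-\lambda)}, `Inf` if \eqn{\lambda = 1}).
#' @export
rollout <- function(problem, policy, horizon, n_reps, seed, ...) {
  UseMethod("rollout")
}

rollout_result <- function(returns, problem, horizon, n_reps, seed) {
  lam <- problem$discount
  r_max <- max(abs(unlist(if (!is.null(problem$models))
    problem$models$rewards else problem$rewards)))
  bound <- if (lam < 1) lam^horizon * r_max / (1 - lam) else Inf
  structure(list(returns = returns, mean = mean(returns),
                 se = stats::sd(returns) / sqrt(n_reps),
                 n_reps = n_reps, horizon = horizon, seed = seed,
                 truncation_bound = bound),
            class = "rollout_result")
}

#' @rdname rollout
#' @export
rollout.mdp_problem <- function(problem, policy, horizon, n_reps, seed,
                                start_state = 1L, ...) {
  set.seed(as.integer(seed))
  nX <- length(problem$states)
  policy <- as.integer(policy)
  returns <- numeric(n_reps)
  disc <- problem$discount^(seq_len(horizon) - 1L)
  for (r in seq_len(n_reps)) {
    x <- as.integer(start_state)
    rew <- numeric(horizon)
    for (t in seq_len(horizon)) {
      a <- policy[x]
      rew[t] <- problem$rewards[x, a]
      x <- sample.int(nX, 1L, prob = problem$kernel[[a]][x, ])
    }
    returns[r] <- sum(rew * disc)
  }
  rollout_result(returns, problem, horizon, n_reps, seed)
}

#' @rdname rollout
#' @export
rollout.adaptive_problem <- function(problem, policy, horizon, n_reps, seed,
                                     start_state = 1L, ...) {
  ## the true model is drawn from the prior in each replicate
  set.seed(as.integer(seed))
  nX <- length(problem$states)
  returns <- numeric(n_reps)
  for (r in seq_len(n_reps)) {
    k <- sample.int(problem$models$K, 1L, prob = problem$prior)
    x <- as.integer(start_state)
    q <- problem$prior
    rew <- numeric(horizon)
    for (t in seq_len(horizon)) {
      a <- adaptive_greedy_action(problem, policy, x, q)
      rew[t] <- problem$models$rewards[[k]][x, a]
      xn <- sample.int(nX, 1L, prob = problem$models$kernels[[k]][[a]][x, ])
      q <- update_model_belief(q, x, a, xn, problem$models)
      x <- xn
    }
    returns[r] <- discounted_sum(rew, problem$discount)
  }
  rollout_result(returns, problem, horizon, n_reps, seed)
}

#' @rdname rollout
#' @export
rollout.pomdp_problem <- function(problem, policy, horizon, n_reps, seed, ...) {
  res <- evaluate_pomdp_policy(problem, policy, horizon, n_reps, seed)
  rollout_result(res$returns, problem, horizon, n_reps, seed)
}

#' @rdname rollout
#' @export
rollout.momdp_problem <- function(problem, policy, horizon, n_reps, seed,
                                  start_state = 1L, ...) {
  set.seed(as.integer(seed))
  nX <- length(problem$x_states)
  nY <- length(problem$y_states)
  nO <- length(problem$observations)
  returns <- numeric(n_reps)
  for (r in seq_len(n_reps)) {
    x <- as.integer(start_state)
    y <- sample.int(nY, 1L, prob = problem$initial_belief)
    b <- problem$initial_belief
    rew <- numeric(horizon)
    for (t in seq_len(horizon)) {
      a <- momdp_greedy_action(problem, policy, x, b)
      rew[t] <- problem$rewards[x, y, a]
      ker <- problem$kernel[[a]]
      joint <- ker[x, y, , ]                     # |X| x |Y| over (x', y')
      pick <- sample.int(nX * nY, 1L, prob = as.vector(joint))
      xn <- (pick - 1L) %% nX + 1L
      yn <- (pick - 1L) %/% nX + 1L
      o <- sample.int(nO, 1L, prob = problem$obs_model[[a]][xn, yn, ])
      b <- mixed_belief_update(x, b, a, xn, o, problem)
      x <- xn; y <- yn
    }
    returns[r] <- discounted_sum(rew, problem$discount)
  }
  rollout_result(returns, problem, horizon, n_reps, seed)
}

#' @rdname rollout
#' @export
rollout.nonstationary_problem <- function(problem, policy, horizon, n_reps,
                                          seed, start_state = 1L, ...) {
  set.seed(as.integer(seed))
  nX <- length(problem$states)
  K <- problem$models$K
  returns <- numeric(n_reps)
  for (r in seq_len(n_reps)) {
    x <- as.integer(start_state)
    y <- sample.int(K, 1L, prob = problem$prior)
    q <- problem$prior
    rew <- numeric(horizon)
    for (t in seq_len(horizon)) {
      a <- nonstationary_greedy_action(problem, policy, x, q)
      rew[t] <- problem$models$rewards[[y]][x, a]
      y <- sample.int(K, 1L, prob = problem$drift[y, ])   # model drifts
      xn <- sample.int(nX, 1L, prob = problem$models$kernels[[y]][[a]][x, ])
      q <- nonstationary_update(q, x, a, xn, problem)
      x <- xn
    }
    returns[r] <- discounted_sum(rew, problem$discount)
  }
  rollout_result(returns, problem, horizon, n_reps, seed)
}

#' Greedy action of a nonstationary solution at an exact (x, q) pair
#'
#' @param problem a [nonstationary_problem()].
#' @param solution a `grid_solution` from [solve_nonstationary()].
#' @param x state index or label.
#' @param q model-weight vector.
#' @return integer action index.
#' @export
nonstationary_greedy_action <- function(problem, solution, x, q) {
  x <- resolve_index(x, problem$states, "state")
  nX <- length(problem$states)
  lam <- problem$discount
  Rq <- averaged_reward(q, problem$models)
  qp <- predict_model_belief(q, problem$drift)
  best <- -Inf; best_a <- 1L
  for (a in seq_along(problem$actions)) {
    lik <- vapply(problem$models$kernels, function(kr) kr[[a]][x, ], numeric(nX))
    if (nX == 1L) lik <- matrix(lik, 1L)
    pmix <- drop(lik %*% qp)
    val <- Rq[x, a]
    for (xn in seq_len(nX)) {
      if (pmix[xn] <= 0) next
      qn <- qp * lik[xn, ] / pmix[xn]
      qn <- pmax(qn, 0); qn <- qn / sum(qn)
      val <- val + lam * pmix[xn] * grid_value_at(solution, xn, qn)
    }
    if (val > best + 1e-12) { best <- val; best_a <- a }
  }
  best_a
}
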