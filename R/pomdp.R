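#' A partially observable decision problem
#'
#' The managed system evolves as in [mdp_problem()], but the state is
#' hidden: after each transition, monitoring yields an observation `o'`
#' with distribution \eqn{f(o'|x',a)} depending on the *next* state and the
#' action taken.  System status is carried as a belief state `b`, a
#' probability distribution over states, updated by Bayes' rule.
#'
#' @inheritParams mdp_problem
#' @param observations character vector of unique observation labels.
#' @param obs_model list with one \eqn{|X| \times |O|} matrix per action;
#'   rows index the next state `x'`, columns the observation, rows sum
#'   to 1.
#' @param initial_belief length-`|X|` probability vector (default
#'   uniform).
#' @return object of class `pomdp_problem`.
#' @export
pomdp_problem <- function(states, actions, kernel, rewards, discount,
                          observations, obs_model,
                          initial_belief = NULL,
                          horizon = horizon_spec("infinite")) {
  base <- mdp_problem(states, actions, kernel, rewards, discount, horizon)
  base$observations <- as.character(observations)
  base$obs_model <- lapply(obs_model, as.matrix)
  base$initial_belief <- initial_belief %||%
    rep(1 / length(states), length(states))
  class(base) <- c("pomdp_problem", class(base))
  base
}

#' @export
validate_problem.pomdp_problem <- function(problem, ...) {
  v <- NextMethod()
  nX <- length(problem$states)
  nO <- length(problem$observations)
  if (anyDuplicated(problem$observations))
    v <- c(v, "observation labels not unique")
  if (length(problem$obs_model) != length(problem$actions))
    v <- c(v, "need one observation matrix per action")
  for (a in seq_along(problem$obs_model)) {
    f <- problem$obs_model[[a]]
    if (!all(dim(f) == c(nX, nO)))
      v <- c(v, sprintf("observation matrix for action '%s' is not %d x %d",
                        problem$actions[a], nX, nO))
    else if (!check_row_stochastic(f))
      v <- c(v, sprintf("observation matrix for action '%s' is not row-stochastic",
                        problem$actions[a]))
  }
  if (!is_prob_vector(problem$initial_belief) ||
      length(problem$initial_belief) != nX)
    v <- c(v, "initial_belief is not a probability vector over states")
  v
}

#' Bayesian belief-state update
#'
#' Predict-then-correct filtering of the hidden state: the prior belief is
#' pushed through the transition kernel and reweighted by the likelihood
#' of the observation,
#' \deqn{b'(x') = f(o'|x',a) \sum_x P(x'|x,a) b(x) / P(o'|b,a).}
#'
#' @param b belief (probability vector over states).
#' @param a action label or index.
#' @param o_next observation label or index.
#' @param problem a [pomdp_problem()].
#' @return updated belief.
#' @export
belief_update <- function(b, a, o_next, problem) {
  a <- resolve_index(a, problem$actions, "action")
  o <- resolve_index(o_next, problem$observations, "observation")
  pred <- drop(b %*% problem$kernel[[a]])
  post <- problem$obs_model[[a]][, o] * pred
  denom <- sum(post)
  if (denom <= 0)
    stopf("impossible evidence: observation '%s' after action '%s' has zero probability",
          problem$observations[o], problem$actions[a])
  post / denom
}

#' Marginal observation distribution
#'
#' \eqn{P(o'|b,a) = \sum_{x'} f(o'|x',a) \sum_x P(x'|x,a) b(x)} — the
#' normalizing constant of the belief update, as a full vector over
#' observations.
#'
#' @inheritParams belief_update
#' @return probability vector over observations.
#' @export
observation_marginal <- function(b, a, problem) {
  a <- resolve_index(a, problem$actions, "action")
  pred <- drop(b %*% problem$kernel[[a]])
  out <- drop(pred %*% problem$obs_model[[a]])
  names(out) <- problem$observations
  out
}

#' Belief-averaged immediate return
#'
#' \eqn{R(a|b) = \sum_x b(x) R(a|x)}.
#'
#' @param b belief vector.
#' @param a action label or index.
#' @param rewards reward matrix, or a problem holding one.
#' @param actions action labels (needed only to resolve an action label
#'   against a bare matrix).
#' @return scalar expected return.
#' @export
expected_reward <- function(b, a, rewards, actions = NULL) {
  if (is.list(rewards) && !is.null(rewards$rewards)) {
    actions <- rewards$actions
    rewards <- rewards$rewards
  }
  a <- resolve_index(a, actions, "action")
  sum(b * rewards[, a])
}

## drop pointwise-dominated (and duplicate) alpha vectors
prune_alpha <- function(alphas, actions_of, tol = 1e-12) {
  n <- ncol(alphas)
  if (n <= 1L) return(list(alphas = alphas, actions = actions_of))
  keep <- rep(TRUE, n)
  for (i in seq_len(n)) {
    if (!keep[i]) next
    for (j in seq_len(n)) {
      if (i == j || !keep[j]) next
      if (all(alphas[, j] >= alphas[, i] - tol) &&
          (any(alphas[, j] > alphas[, i] + tol) || j < i)) {
        keep[i] <- FALSE
        break
      }
    }
  }
  list(alphas = alphas[, keep, drop = FALSE], actions = actions_of[keep])
}

#' Value of an alpha-vector set at a belief
#'
#' @param alpha_set list with `alphas` (a `|X| x n` matrix, one column per
#'   vector) and `actions` (the action index each vector backs).
#' @param b belief vector.
#' @return list with `value` (max inner product) and `action` (action of
#'   the maximizing vector, lowest column on ties).
#' @export
alpha_value <- function(alpha_set, b) {
  scores <- drop(b %*% alpha_set$alphas)
  i <- argmax_first(scores)
  list(value = unname(scores[i]), action = alpha_set$actions[i])
}

#' Exact finite-horizon POMDP solution
#'
#' Computes the optimal piecewise-linear convex value function for each
#' stage by exact cross-sum backup: for every action, every assignment of
#' a successor alpha vector to each observation is enumerated, so
#' \deqn{V_t(b) = \max_a [ R(a|b) + \lambda \sum_{o'} P(o'|b,a)
#'   V_{t+1}(b') ]}
#' holds for *all* beliefs.  Pointwise-dominance pruning keeps the sets
#' small; a guard refuses backups whose cross-sum would exceed `cap`
#' candidate vectors, directing the caller to
#' [solve_pomdp_point_based()].
#'
#' @param problem a [pomdp_problem()].
#' @param horizon number of decisions to plan (terminal value zero).
#' @param cap maximum number of candidate vectors tolerated in one backup.
#' @return list of `horizon` alpha-vector sets; element `h` is optimal
#'   when `h` decisions remain (element `horizon` is the stage-0 set).
#' @export
solve_pomdp_exact <- function(problem, horizon, cap = 200000L) {
  v <- validate_problem(problem)
  if (length(v)) stopf("invalid problem:\n%s", paste("-", v, collapse = "\n"))
  nX <- length(problem$states)
  nA <- length(problem$actions)
  nO <- length(problem$observations)
  lam <- problem$discount
  Gamma <- list(alphas = matrix(0, nX, 1L), actions = 1L)
  out <- vector("list", horizon)
  for (h in seq_len(horizon)) {
    nPrev <- ncol(Gamma$alphas)
    if (nA * nPrev^nO > cap)
      stopf("exact backup would enumerate %g candidate vectors (cap %d); use solve_pomdp_point_based",
            nA * nPrev^nO, cap)
    all_alphas <- NULL
    all_actions <- integer()
    for (a in seq_len(nA)) {
      ## gamma[[o]]: |X| x nPrev back-projections lambda * P f_o alpha
      gamma <- lapply(seq_len(nO), function(o) {
        lam * problem$kernel[[a]] %*%
          (problem$obs_model[[a]][, o] * Gamma$alphas)
      })
      combos <- Reduce(function(acc, o) {
        ## cross-sum: every previous partial sum plus every choice for o
        res <- NULL
        for (j in seq_len(nPrev))
          res <- cbind(res, acc + gamma[[o]][, j])
        res
      }, seq_len(nO), accumulate = FALSE,
      init = matrix(problem$rewards[, a], nX, 1L))
      all_alphas <- cbind(all_alphas, combos)
      all_actions <- c(all_actions, rep(a, ncol(combos)))
    }
    Gamma <- prune_alpha(all_alphas, all_actions)
    out[[h]] <- Gamma
  }
  out
}

#' Point-based POMDP solution (infinite horizon)
#'
#' Repeats point-based backups at a fixed set of beliefs until the value
#' at those points stops changing.  Initialized from the uniform
#' lower-bound vector \eqn{\min_{x,a} R / (1-\lambda)}, so the returned
#' value function is a lower bound of the optimal infinite-horizon value
#' everywhere — the standard guarantee of point-based backup.
#'
#' @param problem a [pomdp_problem()] with \eqn{\lambda < 1}.
#' @param belief_set list (or matrix rows) of beliefs to back up at; must
#'   be nonempty.  The initial belief is added if absent.
#' @param tol maximum change at the belief points at convergence.
#' @param max_iter backup-sweep cap.
#' @return an alpha-vector set (list with `alphas`, `actions`,
#'   `iterations`).
#' @export
solve_pomdp_point_based <- function(problem, belief_set, tol = 1e-6,
                                    max_iter = 1000L) {
  v <- validate_problem(problem)
  if (length(v)) stopf("invalid problem:\n%s", paste("-", v, collapse = "\n"))
  if (problem$discount >= 1) stopf("point-based solver requires discount < 1")
  if (is.matrix(belief_set))
    belief_set <- lapply(seq_len(nrow(belief_set)), function(i) belief_set[i, ])
  if (length(belief_set) == 0L) stopf("belief set must be nonempty")
  if (!any(vapply(belief_set,
                  function(b) max(abs(b - problem$initial_belief)) < 1e-12,
                  logical(1))))
    belief_set <- c(belief_set, list(problem$initial_belief))
  nX <- length(problem$states)
  nA <- length(problem$actions)
  nO <- length(problem$observations)
  lam <- problem$discount
  low <- min(problem$rewards) / (1 - lam)
  Gamma <- list(alphas = matrix(low, nX, 1L), actions = 1L)
  vals_at <- function(G) vapply(belief_set,
                                function(b) alpha_value(G, b)$value, numeric(1))
  old <- vals_at(Gamma)
  for (it in seq_len(max_iter)) {
    new_alphas <- NULL
    new_actions <- integer()
    for (b in belief_set) {
      best_val <- -Inf; best_alpha <- NULL; best_a <- 1L
      for (a in seq_len(nA)) {
        alpha_a <- problem$rewards[, a]
        for (o in seq_len(nO)) {
          g_o <- lam * problem$kernel[[a]] %*%
            (problem$obs_model[[a]][, o] * Gamma$alphas)
          j <- argmax_first(drop(b %*% g_o))
          alpha_a <- alpha_a + g_o[, j]
        }
        val <- sum(b * alpha_a)
        if (val > best_val + 1e-15) {
          best_val <- val; best_alpha <- alpha_a; best_a <- a
        }
      }
      new_alphas <- cbind(new_alphas, best_alpha)
      new_actions <- c(new_actions, best_a)
    }
    Gamma <- prune_alpha(cbind(Gamma$alphas, new_alphas),
                         c(Gamma$actions, new_actions))
    cur <- vals_at(Gamma)
    delta <- max(abs(cur - old))
    old <- cur
    if (delta <= tol)
      return(list(alphas = Gamma$alphas, actions = Gamma$actions,
                  iterations = it))
  }
  list(alphas = Gamma$alphas, actions = Gamma$actions, iterations = max_iter)
}

#' Simulate a POMDP policy given by an alpha-vector set
#'
#' Draws hidden-state trajectories, samples observations from the
#' monitoring model, filters the belief with [belief_update()] and acts
#' greedily with respect to `alpha_set` at the filtered belief.
#'
#' @param problem a [pomdp_problem()].
#' @param alpha_set alpha-vector set (as from the solvers).
#' @param horizon steps per replicate.
#' @param n_reps replicates.
#' @param seed integer seed.
#' @return list with `returns` (per-replicate discounted return), `mean`
#'   and `se`.
#' @export
evaluate_pomdp_policy <- function(problem, alpha_set, horizon, n_reps, seed) {
  set.seed(as.integer(seed))
  nX <- length(problem$states)
  returns <- numeric(n_reps)
  for (r in seq_len(n_reps)) {
    x <- sample.int(nX, 1L, prob = problem$initial_belief)
    b <- problem$initial_belief
    rew <- numeric(horizon)
    for (t in seq_len(horizon)) {
      a <- alpha_value(alpha_set, b)$action
      rew[t] <- problem$rewards[x, a]
      xn <- sample.int(nX, 1L, prob = problem$kernel[[a]][x, ])
      o <- sample.int(length(problem$observations), 1L,
                      prob = problem$obs_model[[a]][xn, ])
      b <- belief_update(b, a, o, problem)
      x <- xn
    }
    returns[r] <- discounted_sum(rew, problem$discount)
  }
  list(returns = returns, mean = mean(returns),
       se = stats::sd(returns) / sqrt(n_reps))
}
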