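#' Construct a discrete Markov decision problem
#'
#' Bundles the ingredients of a fully observed, structurally known decision
#' process: a discrete state space, a discrete action set, one row-stochastic
#' transition matrix \eqn{P(x'|x,a)} per action, a reward table
#' \eqn{R(a|x)}, a per-step discount factor \eqn{\lambda} and a horizon
#' specification.  All stochasticity (environmental variation, demographic
#' noise) is assumed to have been marginalized into the transition kernel.
#'
#' @param states character vector of unique state labels.
#' @param actions character vector of unique action labels.
#' @param kernel list with one \eqn{|X| \times |X|} matrix per action
#'   (named by action or in action order); rows index the current state,
#'   columns the next state, and each row sums to 1.
#' @param rewards numeric \eqn{|X| \times |A|} matrix of immediate returns
#'   \eqn{R(a|x)} (management units, e.g. net benefit), rows indexed by
#'   state, columns by action.
#' @param discount per-step discount factor in \eqn{[0, 1]};
#'   \eqn{\lambda = 1} is only meaningful with a finite horizon.
#' @param horizon a horizon specification from [horizon_spec()]; defaults
#'   to an infinite horizon.
#' @return an object of class `mdp_problem`.
#' @seealso [validate_problem()], [value_iteration()],
#'   [finite_horizon_solve()]
#' @examples
#' p <- mdp_problem(
#'   states  = c("low", "high"),
#'   actions = c("rest", "harvest"),
#'   kernel  = list(rest    = rbind(c(0.4, 0.6), c(0.1, 0.9)),
#'                  harvest = rbind(c(0.9, 0.1), c(0.6, 0.4))),
#'   rewards = rbind(c(0, 1), c(0, 3)),
#'   discount = 0.9)
#' value_iteration(p)$value
#' @export
mdp_problem <- function(states, actions, kernel, rewards, discount,
                        horizon = horizon_spec("infinite")) {
  states <- as.character(states)
  actions <- as.character(actions)
  kernel <- lapply(kernel, as.matrix)
  if (is.null(names(kernel)) || !all(nzchar(names(kernel))))
    names(kernel) <- actions[seq_along(kernel)]
  rewards <- as.matrix(rewards)
  dimnames(rewards) <- list(states, actions[seq_len(ncol(rewards))])
  p <- structure(
    list(states = states, actions = actions, kernel = kernel,
         rewards = rewards, discount = as.numeric(discount),
         horizon = horizon),
    class = c("mdp_problem", "consdp_problem"))
  p
}

#' Horizon specification
#'
#' @param kind `"infinite"` or `"finite"`.
#' @param T number of decision epochs (decisions are taken at times
#'   `0, ..., T-1`); required when `kind = "finite"`.
#' @param terminal_values optional per-state value vector applied at time
#'   `T` (defaults to all zero).
#' @param terminal_decision if `TRUE`, the terminal stage itself optimizes
#'   one last action, so the stage-`T` value is \eqn{\max_a R(a|x)} instead
#'   of `terminal_values`.
#' @return a list of class `horizon_spec`.
#' @export
horizon_spec <- function(kind = c("infinite", "finite"), T = NULL,
                         terminal_values = NULL, terminal_decision = FALSE) {
  kind <- match.arg(kind)
  if (kind == "finite") {
    if (is.null(T) || T < 1) stopf("finite horizon requires T >= 1")
    T <- as.integer(T)
  } else if (!is.null(T)) {
    stopf("T must be absent for an infinite horizon")
  }
  structure(list(kind = kind, T = T, terminal_values = terminal_values,
                 terminal_decision = isTRUE(terminal_decision)),
            class = "horizon_spec")
}

#' Validate a decision problem
#'
#' Collects every violation of the structural invariants (label uniqueness,
#' shape consistency, row stochasticity within 1e-12, finite rewards,
#' discount range, discount/horizon compatibility) instead of failing on
#' the first.  Solvers call this and refuse invalid problems.
#'
#' @param problem a problem object.
#' @param ... unused.
#' @return character vector of human-readable violations; empty if valid.
#' @export
validate_problem <- function(problem, ...) UseMethod("validate_problem")

#' @export
validate_problem.mdp_problem <- function(problem, ...) {
  v <- character()
  nX <- length(problem$states)
  nA <- length(problem$actions)
  if (anyDuplicated(problem$states)) v <- c(v, "state labels not unique")
  if (anyDuplicated(problem$actions)) v <- c(v, "action labels not unique")
  if (nA < 1) v <- c(v, "need at least one action")
  if (length(problem$kernel) != nA)
    v <- c(v, sprintf("kernel has %d matrices for %d actions",
                      length(problem$kernel), nA))
  for (a in seq_along(problem$kernel)) {
    m <- problem$kernel[[a]]
    if (!all(dim(m) == c(nX, nX))) {
      v <- c(v, sprintf("kernel for action '%s' is not %d x %d",
                        problem$actions[a], nX, nX))
      next
    }
    bad <- which(abs(rowSums(m) - 1) > ROW_SUM_TOL)
    for (i in bad)
      v <- c(v, sprintf("kernel row (action '%s', state '%s') sums to %.12g",
                        problem$actions[a], problem$states[i], rowSums(m)[i]))
    if (any(!is.finite(m)) || any(m < -ROW_SUM_TOL) || any(m > 1 + ROW_SUM_TOL))
      v <- c(v, sprintf("kernel for action '%s' has entries outside [0,1]",
                        problem$actions[a]))
  }
  if (!all(dim(problem$rewards) == c(nX, nA)))
    v <- c(v, sprintf("reward table is not %d x %d", nX, nA))
  else if (any(!is.finite(problem$rewards)))
    v <- c(v, "reward table has non-finite entries")
  lam <- problem$discount
  if (!is.finite(lam) || lam < 0 || lam > 1)
    v <- c(v, sprintf("discount %g outside [0,1]", lam))
  if (isTRUE(lam == 1) && problem$horizon$kind == "infinite")
    v <- c(v, "discount 1 requires a finite horizon")
  tv <- problem$horizon$terminal_values
  if (!is.null(tv) && length(tv) != nX)
    v <- c(v, "terminal_values length differs from number of states")
  v
}

assert_valid <- function(problem) {
  v <- validate_problem(problem)
  if (length(v))
    stopf("invalid problem:\n%s", paste("-", v, collapse = "\n"))
  invisible(problem)
}

## action-value table Q(x,a) = R(a|x) + lambda * sum_x' P(x'|x,a) V(x')
q_values <- function(V, problem) {
  lam <- problem$discount
  Q <- vapply(seq_along(problem$kernel),
              function(a) problem$rewards[, a] + lam * drop(problem$kernel[[a]] %*% V),
              numeric(length(V)))
  matrix(Q, nrow = length(V))
}

#' One Bellman backup
#'
#' Applies the dynamic-programming optimality operator once:
#' \deqn{V'(x) = \max_a [ R(a|x) + \lambda \sum_{x'} P(x'|x,a) V(x') ],}
#' returning both the updated value table and the greedy policy (arg-max,
#' lowest action index on ties).
#'
#' @param V numeric per-state value vector.
#' @param problem an [mdp_problem()].
#' @return list with `value` (numeric vector) and `policy` (integer vector
#'   of action indices, named by state with action labels as values via
#'   `actions[policy]`).
#' @export
bellman_backup <- function(V, problem) {
  assert_valid(problem)
  if (length(V) != length(problem$states) || any(!is.finite(V)))
    stopf("V must be a finite vector with one entry per state")
  Q <- q_values(V, problem)
  pol <- apply(Q, 1L, argmax_first)
  list(value = apply(Q, 1L, max), policy = as.integer(pol))
}

#' Solve a discounted infinite-horizon problem by value iteration
#'
#' Iterates the Bellman operator until the sup-norm residual drops below
#' `tol`.  Because the operator is a \eqn{\lambda}-contraction, the returned
#' value table is within \eqn{tol \cdot \lambda/(1-\lambda)} of the unique
#' fixed point.
#'
#' @param problem an [mdp_problem()] with infinite horizon and
#'   \eqn{\lambda < 1}.
#' @param tol sup-norm residual threshold (default 1e-8).
#' @param max_iter iteration cap.
#' @return list with `value`, `policy` (integer action indices), and
#'   `iterations`.
#' @export
value_iteration <- function(problem, tol = 1e-8, max_iter = 100000L) {
  if (problem$horizon$kind != "infinite")
    stopf("value_iteration requires an infinite horizon; use finite_horizon_solve")
  if (problem$discount >= 1)
    stopf("value_iteration requires discount < 1; use finite_horizon_solve")
  assert_valid(problem)
  V <- numeric(length(problem$states))
  for (it in seq_len(max_iter)) {
    b <- bellman_backup(V, problem)
    res <- max(abs(b$value - V))
    V <- b$value
    if (res <= tol)
      return(list(value = V, policy = b$policy, iterations = it))
  }
  stopf("value iteration did not converge in %d iterations", max_iter)
}

#' Solve a finite-horizon problem by backward induction
#'
#' Decisions are taken at times `0, ..., T-1`; the stage-`T` value is the
#' terminal valuation (`terminal_values`, default all zero), or, when the
#' horizon is configured with a terminal decision, one last optimization
#' \eqn{V_T(x) = \max_a R(a|x)}.  Each earlier stage is one Bellman backup
#' of its successor.
#'
#' @param problem an [mdp_problem()] with a finite horizon.
#' @return list with `value` (a `(T+1) x |X|` matrix, row `t+1` holding
#'   \eqn{V_t}) and `policy` (same shape, integer action indices; the
#'   terminal row is `NA` unless a terminal decision is configured).
#' @export
finite_horizon_solve <- function(problem) {
  assert_valid(problem)
  h <- problem$horizon
  if (h$kind != "finite")
    stopf("finite_horizon_solve requires a finite horizon")
  nX <- length(problem$states)
  T <- h$T
  V <- matrix(NA_real_, T + 1L, nX,
              dimnames = list(paste0("t", 0:T), problem$states))
  pol <- matrix(NA_integer_, T + 1L, nX,
                dimnames = dimnames(V))
  if (h$terminal_decision) {
    V[T + 1L, ] <- apply(problem$rewards, 1L, max)
    pol[T + 1L, ] <- apply(problem$rewards, 1L, argmax_first)
  } else {
    V[T + 1L, ] <- h$terminal_values %||% numeric(nX)
  }
  for (t in rev(seq_len(T))) {
    b <- bellman_backup(V[t + 1L, ], problem)
    V[t, ] <- b$value
    pol[t, ] <- b$policy
  }
  list(value = V, policy = pol)
}

#' Evaluate a stationary policy exactly
#'
#' Solves the linear system \eqn{V = R_\pi + \lambda P_\pi V} where
#' \eqn{R_\pi} and \eqn{P_\pi} pick out the policy's action in each state.
#'
#' @param problem an [mdp_problem()] with \eqn{\lambda < 1}.
#' @param policy integer vector of action indices, one per state.
#' @return numeric per-state value vector.
#' @export
policy_value <- function(problem, policy) {
  assert_valid(problem)
  if (problem$discount >= 1 && problem$horizon$kind == "infinite")
    stopf("policy_value requires discount < 1 for an infinite horizon")
  nX <- length(problem$states)
  policy <- as.integer(policy)
  if (length(policy) != nX || any(policy < 1L | policy > length(problem$actions)))
    stopf("policy must map every state to a valid action index")
  P <- t(vapply(seq_len(nX),
                function(x) problem$kernel[[policy[x]]][x, ],
                numeric(nX)))
  R <- problem$rewards[cbind(seq_len(nX), policy)]
  drop(solve(diag(nX) - problem$discount * P, R))
}
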