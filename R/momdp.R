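#' A mixed-observability decision problem
#'
#' Some state components are observed exactly (`x`, e.g. habitat
#' condition) while others are hidden (`y`, e.g. the status of a cryptic
#' population, or an unknown transition model).  The belief lives only on
#' the hidden component, which is the dimensionality advantage of the
#' mixed formulation over a flat partially observable model.
#'
#' @param x_states character labels of the observable component.
#' @param y_states character labels of the hidden component.
#' @param actions character action labels.
#' @param kernel list with one 4-d array per action, dimensions
#'   `(|X|, |Y|, |X|, |Y|)` giving \eqn{P(x',y'|x,y,a)}; for each
#'   `(x, y)` the entries over `(x', y')` sum to 1.
#' @param observations character labels of the hidden-component
#'   observations `o_y` (the observable component needs none: `o_x = x'`).
#' @param obs_model list with one 3-d array per action, dimensions
#'   `(|X|, |Y|, |O|)` giving \eqn{f(o_y'|x',y',a)}.
#' @param rewards 3-d array `(|X|, |Y|, |A|)` of returns \eqn{R(a|x,y)}.
#' @param discount per-step discount factor.
#' @param initial_belief prior over hidden states (default uniform).
#' @param horizon a [horizon_spec()].
#' @return object of class `momdp_problem`.
#' @export
momdp_problem <- function(x_states, y_states, actions, kernel,
                          observations, obs_model, rewards, discount,
                          initial_belief = NULL,
                          horizon = horizon_spec("infinite")) {
  structure(
    list(x_states = as.character(x_states),
         y_states = as.character(y_states),
         actions = as.character(actions),
         kernel = kernel, observations = as.character(observations),
         obs_model = obs_model, rewards = rewards,
         discount = as.numeric(discount),
         initial_belief = initial_belief %||%
           rep(1 / length(y_states), length(y_states)),
         horizon = horizon),
    class = c("momdp_problem", "consdp_problem"))
}

#' @export
validate_problem.momdp_problem <- function(problem, ...) {
  v <- character()
  nX <- length(problem$x_states); nY <- length(problem$y_states)
  nA <- length(problem$actions); nO <- length(problem$observations)
  if (anyDuplicated(problem$x_states)) v <- c(v, "x state labels not unique")
  if (anyDuplicated(problem$y_states)) v <- c(v, "y state labels not unique")
  if (length(problem$kernel) != nA) v <- c(v, "need one joint kernel per action")
  for (a in seq_len(nA)) {
    ker <- problem$kernel[[a]]
    if (!all(dim(ker) == c(nX, nY, nX, nY))) {
      v <- c(v, sprintf("joint kernel for action '%s' has wrong shape",
                        problem$actions[a]))
      next
    }
    for (x in seq_len(nX)) for (y in seq_len(nY)) {
      s <- sum(ker[x, y, , ])
      if (abs(s - 1) > ROW_SUM_TOL)
        v <- c(v, sprintf("joint kernel row (action '%s', x '%s', y '%s') sums to %.12g",
                          problem$actions[a], problem$x_states[x],
                          problem$y_states[y], s))
    }
    f <- problem$obs_model[[a]]
    if (!all(dim(f) == c(nX, nY, nO)))
      v <- c(v, sprintf("observation array for action '%s' has wrong shape",
                        problem$actions[a]))
    else for (x in seq_len(nX)) for (y in seq_len(nY)) {
      s <- sum(f[x, y, ])
      if (abs(s - 1) > ROW_SUM_TOL)
        v <- c(v, sprintf("observation row (action '%s', x' '%s', y' '%s') sums to %.12g",
                          problem$actions[a], problem$x_states[x],
                          problem$y_states[y], s))
    }
  }
  if (!all(dim(problem$rewards) == c(nX, nY, nA)))
    v <- c(v, "reward array has wrong shape")
  if (!is_prob_vector(problem$initial_belief) ||
      length(problem$initial_belief) != nY)
    v <- c(v, "initial_belief is not a probability vector over hidden states")
  if (!is.finite(problem$discount) || problem$discount < 0 || problem$discount > 1)
    v <- c(v, "discount outside [0,1]")
  v
}

#' Hidden-belief update for a mixed-observability problem
#'
#' Conditions the hidden-component belief on the full evidence of one
#' step: the action, the exactly observed next `x'`, and the
#' hidden-component observation `o_y'`:
#' \deqn{b'(y') \propto \sum_y b(y) P(x',y'|x,y,a) f(o_y'|x',y',a).}
#'
#' @param x,x_next observable states (labels or indices).
#' @param b_y belief over hidden states.
#' @param a action label or index.
#' @param o_y_next hidden-component observation label or index.
#' @param problem a [momdp_problem()].
#' @return updated hidden belief.
#' @export
mixed_belief_update <- function(x, b_y, a, x_next, o_y_next, problem) {
  x <- resolve_index(x, problem$x_states, "x state")
  a <- resolve_index(a, problem$actions, "action")
  xn <- resolve_index(x_next, problem$x_states, "x state")
  o <- resolve_index(o_y_next, problem$observations, "observation")
  nY <- length(problem$y_states)
  ker <- problem$kernel[[a]]
  f <- problem$obs_model[[a]]
  w <- vapply(seq_len(nY), function(yn)
    sum(b_y * ker[x, , xn, yn]) * f[xn, yn, o], numeric(1))
  denom <- sum(w)
  if (denom <= 0)
    stopf("impossible evidence: (x=%s, a=%s, x'=%s, o_y'=%s) has zero probability",
          problem$x_states[x], problem$actions[a], problem$x_states[xn],
          problem$observations[o])
  w / denom
}

## grid operators for the mixed recursion: augmented state (x, g),
## stochastic branch (x', o_y')
momdp_grid_ops <- function(problem, grid) {
  nX <- length(problem$x_states)
  nY <- length(problem$y_states)
  nA <- length(problem$actions)
  nO <- length(problem$observations)
  nG <- nrow(grid$points)
  n <- nX * nG
  rewards <- vector("list", nA)
  trans <- vector("list", nA)
  for (a in seq_len(nA)) {
    ker <- problem$kernel[[a]]
    f <- problem$obs_model[[a]]
    Ra <- numeric(n)
    Ma <- matrix(0, n, n)
    for (g in seq_len(nG)) {
      b <- grid$points[g, ]
      for (x in seq_len(nX)) {
        i <- xg_index(x, g, nX)
        Ra[i] <- sum(b * problem$rewards[x, , a])
        for (xn in seq_len(nX)) for (o in seq_len(nO)) {
          w <- vapply(seq_len(nY), function(yn)
            sum(b * ker[x, , xn, yn]) * f[xn, yn, o], numeric(1))
          pj <- sum(w)                      # P(x', o_y' | x, b, a)
          if (pj <= 0) next
          bn <- pmax(w / pj, 0); bn <- bn / sum(bn)
          sw <- simplex_weights(grid, bn)
          jj <- xg_index(xn, sw$idx, nX)
          Ma[i, jj] <- Ma[i, jj] + pj * sw$w
        }
      }
    }
    rewards[[a]] <- Ra
    trans[[a]] <- Ma
  }
  list(rewards = rewards, trans = trans)
}

#' Solve a mixed-observability problem on a hidden-belief grid
#'
#' Value iteration (or backward induction, when the problem's horizon is
#' finite) over the augmented state `(x, b_y)` with `b_y` discretized on a
#' simplex grid.  At every grid point the returned value satisfies
#' \deqn{V(x,b_y) = \max_a [ R(a|x,b_y) + \lambda \sum_{x'} \sum_{o_y'}
#'   P(x',o_y'|x,b_y,a) V(x', b_y') ]}
#' within `tol`, with off-grid updated beliefs interpolated.
#'
#' @param problem a [momdp_problem()].
#' @param grid a [simplex_grid()] over hidden states, or an integer
#'   resolution.
#' @param tol convergence threshold (infinite horizon).
#' @return a `grid_solution` with `value` and `policy` of shape
#'   `|X| x n_grid_points`.
#' @export
solve_momdp <- function(problem, grid = 50L, tol = 1e-8) {
  v <- validate_problem(problem)
  if (length(v)) stopf("invalid problem:\n%s", paste("-", v, collapse = "\n"))
  nY <- length(problem$y_states)
  if (!inherits(grid, "simplex_grid")) grid <- simplex_grid(nY, grid)
  if (grid$K != nY) stopf("grid dimension must equal |Y|")
  ops <- momdp_grid_ops(problem, grid)
  sol <- if (problem$horizon$kind == "finite")
    grid_backward_induction(ops, problem$discount, problem$horizon$T)
  else {
    if (problem$discount >= 1) stopf("infinite horizon requires discount < 1")
    grid_value_iteration(ops, problem$discount, tol)
  }
  grid_result(sol$value, sol$policy, problem$x_states, problem$actions,
              grid, sol$iterations)
}

#' Embed an adaptive-management problem as a mixed-observability problem
#'
#' The hidden component is the (static) model index: the joint kernel
#' keeps `y` fixed and moves `x` under model `y`'s dynamics, observations
#' are restricted to the fully observable system state (a single
#' uninformative hidden-observation symbol), rewards are the
#' model-specific tables, and the hidden prior is the model prior.
#' Solving the embedding reproduces the active adaptive solution.
#'
#' @param problem an [adaptive_problem()].
#' @return a [momdp_problem()].
#' @export
adaptive_to_momdp <- function(problem) {
  nX <- length(problem$states)
  K <- problem$models$K
  nA <- length(problem$actions)
  kernel <- vector("list", nA)
  obs <- vector("list", nA)
  rewards <- array(0, c(nX, K, nA))
  for (a in seq_len(nA)) {
    ker <- array(0, c(nX, K, nX, K))
    for (y in seq_len(K))
      ker[, y, , y] <- problem$models$kernels[[y]][[a]]
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

#' Greedy action of a mixed solution at an exact (x, belief) pair
#'
#' @inheritParams solve_momdp
#' @param solution a `grid_solution` from [solve_momdp()].
#' @param x observable state label or index.
#' @param b_y hidden belief.
#' @return integer action index.
#' @export
momdp_greedy_action <- function(problem, solution, x, b_y) {
  x <- resolve_index(x, problem$x_states, "x state")
  nX <- length(problem$x_states)
  nY <- length(problem$y_states)
  nO <- length(problem$observations)
  lam <- problem$discount
  best <- -Inf; best_a <- 1L
  for (a in seq_along(problem$actions)) {
    ker <- problem$kernel[[a]]
    f <- problem$obs_model[[a]]
    val <- sum(b_y * problem$rewards[x, , a])
    for (xn in seq_len(nX)) for (o in seq_len(nO)) {
      w <- vapply(seq_len(nY), function(yn)
        sum(b_y * ker[x, , xn, yn]) * f[xn, yn, o], numeric(1))
      pj <- sum(w)
      if (pj <= 0) next
      bn <- pmax(w / pj, 0); bn <- bn / sum(bn)
      val <- val + lam * pj * grid_value_at(solution, xn, bn)
    }
    if (val > best + 1e-12) { best <- val; best_a <- a }
  }
  best_a
}
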