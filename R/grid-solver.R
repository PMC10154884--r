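## Shared machinery for belief-space solvers (adaptive, MOMDP,
## nonstationary).  Each solver reduces to value iteration on an augmented
## state (x, g) where g ranges over simplex grid points: it precomputes,
## per action, the immediate reward vector and a dense transition operator
## M_a with M_a[(x,g), (x',g')] = P(branch) * barycentric weight of the
## updated belief at grid vertex g'.  One backup is then
## Q_a = R_a + lambda * M_a %*% V.

## ops: list(rewards = list of per-action vectors length nX*nG,
##           trans   = list of per-action (nX*nG) x (nX*nG) matrices)
grid_backup <- function(V, ops, lambda) {
  nA <- length(ops$rewards)
  Q <- vapply(seq_len(nA),
              function(a) ops$rewards[[a]] + lambda * drop(ops$trans[[a]] %*% V),
              numeric(length(V)))
  Q <- matrix(Q, nrow = length(V))
  list(value = apply(Q, 1L, max), policy = as.integer(apply(Q, 1L, argmax_first)))
}

grid_value_iteration <- function(ops, lambda, tol, max_iter = 100000L) {
  n <- length(ops$rewards[[1L]])
  V <- numeric(n)
  for (it in seq_len(max_iter)) {
    b <- grid_backup(V, ops, lambda)
    res <- max(abs(b$value - V))
    V <- b$value
    if (res <= tol)
      return(list(value = V, policy = b$policy, iterations = it))
  }
  stopf("grid value iteration did not converge in %d iterations", max_iter)
}

grid_backward_induction <- function(ops, lambda, T, terminal = NULL) {
  n <- length(ops$rewards[[1L]])
  V <- terminal %||% numeric(n)
  pol <- NULL
  for (t in seq_len(T)) {
    b <- grid_backup(V, ops, lambda)
    V <- b$value
    pol <- b$policy
  }
  list(value = V, policy = pol, iterations = T)
}

## flat index of augmented state (x, g): state-major within grid blocks
xg_index <- function(x, g, nX) (g - 1L) * nX + x

## assemble a value/policy result into labeled tables
grid_result <- function(V, pol, states, actions, grid, extra_iter) {
  nX <- length(states)
  nG <- nrow(grid$points)
  vm <- matrix(V, nX, nG, dimnames = list(states, NULL))
  pm <- matrix(pol, nX, nG, dimnames = list(states, NULL))
  structure(list(value = vm, policy = pm, grid = grid,
                 states = states, actions = actions,
                 iterations = extra_iter),
            class = "grid_solution")
}

#' Read a grid solution at an arbitrary belief
#'
#' Interpolates the tabulated value of a belief-space solution (adaptive,
#' mixed-observability or nonstationary) at an off-grid belief/model-state
#' vector.
#'
#' @param solution a `grid_solution` as returned by the belief-space
#'   solvers.
#' @param x state label or index (observable component).
#' @param q probability vector on the solution's simplex.
#' @return interpolated value (scalar).
#' @export
grid_value_at <- function(solution, x, q) {
  if (is.character(x)) x <- match(x, solution$states)
  simplex_interpolate(solution$grid, solution$value[x, ], q)
}
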