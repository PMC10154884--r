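#' Regular grid on the probability simplex
#'
#' Enumerates every length-`K` probability vector whose entries are
#' multiples of `1/m`.  The grid is the solution representation used by all
#' belief-space solvers in this package: values are stored at grid points
#' and read off-grid by barycentric interpolation on the standard
#' (Freudenthal) simplicial subdivision, which preserves convex
#' combinations and never leaves the simplex.
#'
#' @param K dimension of the simplex (number of models / hidden states).
#' @param m grid resolution (number of subdivisions per edge), `m >= 1`.
#' @return object of class `simplex_grid` with `points` (an
#'   `n_points x K` matrix, rows summing to 1), `m`, `K` and an internal
#'   vertex index.  `n_points = choose(m + K - 1, K - 1)`.
#' @examples
#' g <- simplex_grid(K = 2, m = 4)
#' g$points
#' @export
simplex_grid <- function(K, m) {
  K <- as.integer(K); m <- as.integer(m)
  if (K < 1L) stopf("K must be >= 1")
  if (m < 1L) stopf("grid resolution m must be >= 1")
  counts <- compositions_of(m, K)            # n x K integer matrix
  pts <- counts / m
  index <- new.env(hash = TRUE, parent = emptyenv())
  keys <- apply(counts, 1L, paste, collapse = ",")
  for (i in seq_along(keys)) assign(keys[i], i, envir = index)
  structure(list(points = pts, counts = counts, m = m, K = K,
                 .index = index),
            class = "simplex_grid")
}

## all K-tuples of nonnegative integers summing to m, lexicographic
compositions_of <- function(m, K) {
  if (K == 1L) return(matrix(m, 1L, 1L))
  out <- vector("list", m + 1L)
  for (first in 0:m) {
    rest <- compositions_of(m - first, K - 1L)
    out[[first + 1L]] <- cbind(first, rest, deparse.level = 0)
  }
  do.call(rbind, out)
}

grid_lookup <- function(grid, counts) {
  key <- paste(counts, collapse = ",")
  idx <- get0(key, envir = grid$.index, inherits = FALSE)
  if (is.null(idx)) stopf("point (%s)/%d is not on the grid", key, grid$m)
  idx
}

#' Barycentric interpolation weights on a simplex grid
#'
#' Locates the sub-simplex of the Freudenthal subdivision containing `q`
#' and returns the enclosing grid vertices with convex weights, so that
#' any function tabulated at grid points extends piecewise-linearly to the
#' whole simplex.  Exact (weight 1) at grid points; exact for linear
#' functions everywhere.
#'
#' @param grid a [simplex_grid()].
#' @param q probability vector of length `grid$K`.
#' @return list with `idx` (grid row indices) and `w` (matching convex
#'   weights summing to 1).
#' @export
simplex_weights <- function(grid, q) {
  K <- grid$K
  if (length(q) != K || !is_prob_vector(q, tol = 1e-9))
    stopf("q must be a length-%d probability vector", K)
  m <- grid$m
  if (K == 1L) return(list(idx = 1L, w = 1))
  ## cumulative coordinates: x_i = m * sum_{j >= i} q_j, x_1 = m
  x <- m * rev(cumsum(rev(q)))
  x[1L] <- m
  v <- floor(x + 1e-9)
  d <- x - v
  d[d < 1e-9] <- 0           # snap near-integer coordinates to the lattice
  d[1L] <- 0
  ord <- order(d, decreasing = TRUE)         # stable; d[1] == 0 sorts last
  ord <- ord[d[ord] > 0]
  n_vert <- length(ord) + 1L
  idx <- integer(n_vert)
  w <- numeric(n_vert)
  cum <- v
  dd <- c(1, d[ord], 0)
  for (j in seq_len(n_vert)) {
    counts <- cum - c(cum[-1L], 0)           # back to occupation numbers
    idx[j] <- grid_lookup(grid, as.integer(round(counts)))
    w[j] <- dd[j] - dd[j + 1L]
    if (j <= length(ord)) cum[ord[j]] <- cum[ord[j]] + 1
  }
  keep <- w > 1e-15
  list(idx = idx[keep], w = w[keep] / sum(w[keep]))
}

#' Interpolate a grid-tabulated function at an arbitrary simplex point
#'
#' @param grid a [simplex_grid()].
#' @param values numeric vector with one value per grid point.
#' @param q probability vector of length `grid$K`.
#' @return interpolated scalar.
#' @export
simplex_interpolate <- function(grid, values, q) {
  sw <- simplex_weights(grid, q)
  sum(sw$w * values[sw$idx])
}

## indices of the K corner points e_k of the grid
simplex_corners <- function(grid) {
  vapply(seq_len(grid$K), function(k) {
    counts <- integer(grid$K); counts[k] <- grid$m
    grid_lookup(grid, counts)
  }, integer(1))
}
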