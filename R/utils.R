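`%||%` <- function(a, b) if (is.null(a)) b else a

ROW_SUM_TOL <- 1e-12

is_prob_vector <- function(p, tol = ROW_SUM_TOL) {
  is.numeric(p) && all(is.finite(p)) && all(p >= -tol) &&
    abs(sum(p) - 1) <= tol
}

## rows of `m` must each be a probability distribution
check_row_stochastic <- function(m, tol = ROW_SUM_TOL) {
  if (any(!is.finite(m))) return(FALSE)
  if (any(m < -tol) || any(m > 1 + tol)) return(FALSE)
  all(abs(rowSums(m) - 1) <= tol)
}

## deterministic arg-max: lowest index wins on ties
argmax_first <- function(x) which.max(x)

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

## discounted sum of a reward stream r_0, r_1, ...
discounted_sum <- function(rewards, lambda) {
  if (length(rewards) == 0L) return(0)
  sum(rewards * lambda^(seq_along(rewards) - 1L))
}
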