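#' @export
print.mdp_problem <- function(x, ...) {
  cat(sprintf("<%s> %d states, %d actions, discount %g, %s horizon\n",
              class(x)[1], length(x$states), length(x$actions),
              x$discount,
              if (x$horizon$kind == "finite")
                sprintf("finite (T = %d)", x$horizon$T) else "infinite"))
  cat("  states:", paste(x$states, collapse = ", "), "\n")
  cat("  actions:", paste(x$actions, collapse = ", "), "\n")
  if (!is.null(x$observations))
    cat("  observations:", paste(x$observations, collapse = ", "), "\n")
  invisible(x)
}

#' @export
print.adaptive_problem <- function(x, ...) {
  cat(sprintf("<%s> %d states, %d actions, %d rival models, discount %g\n",
              class(x)[1], length(x$states), length(x$actions),
              x$models$K, x$discount))
  cat("  prior model weights:", paste(signif(x$prior, 4), collapse = ", "),
      "\n")
  if (!is.null(x$drift)) {
    cat("  model drift matrix:\n")
    print(signif(x$drift, 4))
  }
  invisible(x)
}

#' @export
print.nonstationary_problem <- print.adaptive_problem

#' @export
print.momdp_problem <- function(x, ...) {
  cat(sprintf(
    "<momdp_problem> %d observable x %d hidden states, %d actions, %d observations, discount %g\n",
    length(x$x_states), length(x$y_states), length(x$actions),
    length(x$observations), x$discount))
  cat("  hidden prior:", paste(signif(x$initial_belief, 4), collapse = ", "),
      "\n")
  invisible(x)
}

#' @export
print.grid_solution <- function(x, ...) {
  cat(sprintf(
    "<grid_solution> %d states x %d grid points (simplex K = %d, m = %d), %d sweeps\n",
    nrow(x$value), ncol(x$value), x$grid$K, x$grid$m, x$iterations))
  cat(sprintf("  value range [%.4g, %.4g]\n", min(x$value), max(x$value)))
  invisible(x)
}

#' @export
print.rollout_result <- function(x, ...) {
  cat(sprintf(
    "<rollout_result> %d reps x %d steps (seed %d): mean %.6g, se %.3g\n",
    x$n_reps, x$horizon, x$seed, x$mean, x$se))
  if (is.finite(x$truncation_bound))
    cat(sprintf("  truncation bias bound %.3g\n", x$truncation_bound))
  invisible(x)
}
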