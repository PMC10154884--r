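## Problem-file format: JSON, label-keyed.  Probabilities are always
## keyed by state/action/observation labels, never by position, so files
## stay meaningful if spaces are reordered.  Input rows whose sums drift
## from 1 by at most 1e-6 are renormalized with a note to stderr (beyond
## that, a hard error); round trips are exact to writing precision.

FORMAT_VERSION <- "1.0"
HARD_ROW_TOL <- 1e-6

note <- function(fmt, ...) message(sprintf(fmt, ...))

## named-list <-> matrix helpers ------------------------------------------

named_from_matrix <- function(m, row_labels, col_labels) {
  out <- list()
  for (i in seq_along(row_labels)) {
    row <- as.list(m[i, ])
    names(row) <- col_labels
    out[[row_labels[i]]] <- row
  }
  out
}

matrix_from_named <- function(lst, row_labels, col_labels, where,
                              renormalize = FALSE) {
  m <- matrix(NA_real_, length(row_labels), length(col_labels),
              dimnames = list(row_labels, col_labels))
  unknown_rows <- setdiff(names(lst), row_labels)
  if (length(unknown_rows))
    stopf("%s: unknown label '%s'", where, unknown_rows[1])
  for (r in row_labels) {
    row <- lst[[r]]
    if (is.null(row)) stopf("%s: missing row for '%s'", where, r)
    unknown <- setdiff(names(row), col_labels)
    if (length(unknown))
      stopf("%s, row '%s': unknown label '%s'", where, r, unknown[1])
    for (cn in col_labels) {
      val <- row[[cn]]
      if (is.null(val)) stopf("%s, row '%s': missing entry '%s'", where, r, cn)
      if (!is.numeric(val) || length(val) != 1 || !is.finite(val))
        stopf("%s, row '%s', entry '%s': malformed number", where, r, cn)
      m[r, cn] <- val
    }
    if (renormalize) {
      s <- sum(m[r, ])
      if (abs(s - 1) > HARD_ROW_TOL)
        stopf("%s, row '%s': probabilities sum to %.12g", where, r, s)
      if (abs(s - 1) > ROW_SUM_TOL) {
        note("note: %s, row '%s' summed to %.12g; renormalized", where, r, s)
        m[r, ] <- m[r, ] / s
      } else if (s != 1) {
        m[r, ] <- m[r, ] / s
      }
    }
  }
  m
}

named_prob_vector <- function(p, labels) {
  out <- as.list(p)
  names(out) <- labels
  out
}

prob_vector_from_named <- function(lst, labels, where) {
  unknown <- setdiff(names(lst), labels)
  if (length(unknown)) stopf("%s: unknown label '%s'", where, unknown[1])
  p <- vapply(labels, function(l) {
    val <- lst[[l]]
    if (is.null(val)) stopf("%s: missing entry '%s'", where, l)
    as.numeric(val)
  }, numeric(1))
  s <- sum(p)
  if (abs(s - 1) > HARD_ROW_TOL)
    stopf("%s: probabilities sum to %.12g", where, s)
  if (abs(s - 1) > ROW_SUM_TOL)
    note("note: %s summed to %.12g; renormalized", where, s)
  p / s
}

check_known_keys <- function(lst, allowed, where) {
  unknown <- setdiff(names(lst), allowed)
  if (length(unknown))
    stopf("%s: unknown key '%s'", where, unknown[1])
}

horizon_to_list <- function(h) {
  out <- list(kind = h$kind)
  if (!is.null(h$T)) out$T <- h$T
  if (!is.null(h$terminal_values)) out$terminal_values <- h$terminal_values
  if (isTRUE(h$terminal_decision)) out$terminal_decision <- TRUE
  out
}

horizon_from_list <- function(lst) {
  if (is.null(lst)) return(horizon_spec("infinite"))
  check_known_keys(lst, c("kind", "T", "terminal_values", "terminal_decision"),
                   "horizon")
  horizon_spec(lst$kind %||% "infinite", T = lst$T,
               terminal_values = unlist(lst$terminal_values),
               terminal_decision = isTRUE(lst$terminal_decision))
}

## per-problem-class serializers ------------------------------------------

problem_to_list <- function(problem) UseMethod("problem_to_list")

kernel_to_list <- function(kernel, states, actions) {
  out <- list()
  for (a in seq_along(actions))
    out[[actions[a]]] <- named_from_matrix(kernel[[a]], states, states)
  out
}

kernel_from_list <- function(lst, states, actions, where) {
  check_known_keys(lst, actions, where)
  lapply(actions, function(an) {
    sub <- lst[[an]]
    if (is.null(sub)) stopf("%s: missing kernel for action '%s'", where, an)
    matrix_from_named(sub, states, states,
                      sprintf("%s, action '%s'", where, an),
                      renormalize = TRUE)
  })
}

#' @export
problem_to_list.mdp_problem <- function(problem) {
  list(format_version = FORMAT_VERSION, class = "mdp",
       states = problem$states, actions = problem$actions,
       kernel = kernel_to_list(problem$kernel, problem$states, problem$actions),
       rewards = named_from_matrix(problem$rewards, problem$states,
                                   problem$actions),
       discount = problem$discount,
       horizon = horizon_to_list(problem$horizon))
}

#' @export
problem_to_list.pomdp_problem <- function(problem) {
  out <- problem_to_list.mdp_problem(problem)
  out$class <- "pomdp"
  out$observations <- problem$observations
  out$obs_model <- list()
  for (a in seq_along(problem$actions))
    out$obs_model[[problem$actions[a]]] <-
      named_from_matrix(problem$obs_model[[a]], problem$states,
                        problem$observations)
  out$initial_belief <- named_prob_vector(problem$initial_belief,
                                          problem$states)
  out
}

models_to_list <- function(models, states, actions) {
  lapply(seq_len(models$K), function(k)
    list(kernel = kernel_to_list(models$kernels[[k]], states, actions),
         rewards = named_from_matrix(models$rewards[[k]], states, actions)))
}

models_from_list <- function(lst, states, actions) {
  kernels <- list(); rewards <- list()
  for (k in seq_along(lst)) {
    check_known_keys(lst[[k]], c("kernel", "rewards"),
                     sprintf("model %d", k))
    kernels[[k]] <- kernel_from_list(lst[[k]]$kernel, states, actions,
                                     sprintf("model %d kernel", k))
    rewards[[k]] <- matrix_from_named(lst[[k]]$rewards, states, actions,
                                      sprintf("model %d rewards", k))
  }
  model_set(kernels, rewards)
}

#' @export
problem_to_list.adaptive_problem <- function(problem) {
  list(format_version = FORMAT_VERSION, class = "adaptive",
       states = problem$states, actions = problem$actions,
       models = models_to_list(problem$models, problem$states,
                               problem$actions),
       prior = named_prob_vector(problem$prior,
                                 paste0("model", seq_along(problem$prior))),
       discount = problem$discount,
       horizon = horizon_to_list(problem$horizon))
}

#' @export
problem_to_list.nonstationary_problem <- function(problem) {
  out <- problem_to_list.adaptive_problem(problem)
  out$class <- "nonstationary"
  mlab <- paste0("model", seq_len(problem$models$K))
  out$drift <- named_from_matrix(problem$drift, mlab, mlab)
  out
}

#' @export
problem_to_list.momdp_problem <- function(problem) {
  nA <- length(problem$actions)
  kernel <- list()
  obs <- list()
  rewards <- list()
  for (a in seq_len(nA)) {
    an <- problem$actions[a]
    ker <- problem$kernel[[a]]
    kl <- list()
    for (x in seq_along(problem$x_states)) {
      yl <- list()
      for (y in seq_along(problem$y_states)) {
        xl <- list()
        for (xn in seq_along(problem$x_states)) {
          row <- as.list(ker[x, y, xn, ])
          names(row) <- problem$y_states
          xl[[problem$x_states[xn]]] <- row
        }
        yl[[problem$y_states[y]]] <- xl
      }
      kl[[problem$x_states[x]]] <- yl
    }
    kernel[[an]] <- kl
    ol <- list()
    for (x in seq_along(problem$x_states)) {
      yl <- list()
      for (y in seq_along(problem$y_states)) {
        row <- as.list(problem$obs_model[[a]][x, y, ])
        names(row) <- problem$observations
        yl[[problem$y_states[y]]] <- row
      }
      ol[[problem$x_states[x]]] <- yl
    }
    obs[[an]] <- ol
  }
  for (x in seq_along(problem$x_states)) {
    yl <- list()
    for (y in seq_along(problem$y_states)) {
      row <- as.list(problem$rewards[x, y, ])
      names(row) <- problem$actions
      yl[[problem$y_states[y]]] <- row
    }
    rewards[[problem$x_states[x]]] <- yl
  }
  list(format_version = FORMAT_VERSION, class = "momdp",
       x_states = problem$x_states, y_states = problem$y_states,
       actions = problem$actions, kernel = kernel,
       observations = problem$observations, obs_model = obs,
       rewards = rewards, discount = problem$discount,
       initial_belief = named_prob_vector(problem$initial_belief,
                                          problem$y_states),
       horizon = horizon_to_list(problem$horizon))
}

#' Write a problem to a label-keyed JSON problem file
#'
#' Keys are emitted in a fixed canonical order, so identical problems
#' produce identical bytes.
#'
#' @param problem any problem class of this package.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_problem <- function(problem, path) {
  v <- validate_problem(problem)
  if (length(v)) stopf("refusing to write invalid problem:\n%s",
                       paste("-", v, collapse = "\n"))
  jsonlite::write_json(problem_to_list(problem), path, auto_unbox = TRUE,
                       digits = I(17), pretty = TRUE)
  invisible(path)
}

#' Read a problem file
#'
#' Reads and fully validates a JSON problem file written by
#' [write_problem()] (or authored by hand).  Unknown keys and labels are
#' rejected with their location; probability rows off by at most 1e-6 are
#' renormalized with a note to stderr.
#'
#' @param path file path.
#' @return the problem instance of the tagged class.
#' @export
read_problem <- function(path) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  cls <- raw$class %||% stopf("problem file lacks a class tag")
  states <- as.character(unlist(raw$states))
  actions <- as.character(unlist(raw$actions))
  problem <- switch(
    cls,
    mdp = {
      check_known_keys(raw, c("format_version", "class", "states", "actions",
                              "kernel", "rewards", "discount", "horizon"),
                       "mdp file")
      mdp_problem(states, actions,
                  kernel_from_list(raw$kernel, states, actions, "kernel"),
                  matrix_from_named(raw$rewards, states, actions, "rewards"),
                  as.numeric(raw$discount), horizon_from_list(raw$horizon))
    },
    pomdp = {
      check_known_keys(raw, c("format_version", "class", "states", "actions",
                              "kernel", "rewards", "discount", "horizon",
                              "observations", "obs_model", "initial_belief"),
                       "pomdp file")
      obs <- as.character(unlist(raw$observations))
      check_known_keys(raw$obs_model, actions, "obs_model")
      om <- lapply(actions, function(an)
        matrix_from_named(raw$obs_model[[an]], states, obs,
                          sprintf("obs_model, action '%s'", an),
                          renormalize = TRUE))
      pomdp_problem(states, actions,
                    kernel_from_list(raw$kernel, states, actions, "kernel"),
                    matrix_from_named(raw$rewards, states, actions, "rewards"),
                    as.numeric(raw$discount), obs, om,
                    prob_vector_from_named(raw$initial_belief, states,
                                           "initial_belief"),
                    horizon_from_list(raw$horizon))
    },
    adaptive = {
      check_known_keys(raw, c("format_version", "class", "states", "actions",
                              "models", "prior", "discount", "horizon"),
                       "adaptive file")
      models <- models_from_list(raw$models, states, actions)
      mlab <- paste0("model", seq_len(models$K))
      adaptive_problem(states, actions, models,
                       prob_vector_from_named(raw$prior, mlab, "prior"),
                       as.numeric(raw$discount),
                       horizon_from_list(raw$horizon))
    },
    nonstationary = {
      check_known_keys(raw, c("format_version", "class", "states", "actions",
                              "models", "prior", "drift", "discount",
                              "horizon"),
                       "nonstationary file")
      models <- models_from_list(raw$models, states, actions)
      mlab <- paste0("model", seq_len(models$K))
      nonstationary_problem(
        states, actions, models,
        prob_vector_from_named(raw$prior, mlab, "prior"),
        matrix_from_named(raw$drift, mlab, mlab, "drift",
                          renormalize = TRUE),
        as.numeric(raw$discount), horizon_from_list(raw$horizon))
    },
    momdp = {
      check_known_keys(raw, c("format_version", "class", "x_states",
                              "y_states", "actions", "kernel",
                              "observations", "obs_model", "rewards",
                              "discount", "initial_belief", "horizon"),
                       "momdp file")
      momdp_from_list(raw)
    },
    stopf("unknown problem class '%s'", cls))
  v <- validate_problem(problem)
  if (length(v)) stopf("problem file %s is invalid:\n%s", path,
                       paste("-", v, collapse = "\n"))
  problem
}

momdp_from_list <- function(raw) {
  xs <- as.character(unlist(raw$x_states))
  ys <- as.character(unlist(raw$y_states))
  actions <- as.character(unlist(raw$actions))
  obs <- as.character(unlist(raw$observations))
  nX <- length(xs); nY <- length(ys); nO <- length(obs)
  kernel <- list(); om <- list()
  check_known_keys(raw$kernel, actions, "kernel")
  check_known_keys(raw$obs_model, actions, "obs_model")
  for (a in seq_along(actions)) {
    an <- actions[a]
    ker <- array(NA_real_, c(nX, nY, nX, nY))
    kl <- raw$kernel[[an]]
    check_known_keys(kl, xs, sprintf("kernel, action '%s'", an))
    for (x in seq_len(nX)) {
      check_known_keys(kl[[xs[x]]], ys,
                       sprintf("kernel, action '%s', x '%s'", an, xs[x]))
      for (y in seq_len(nY)) {
        sub <- kl[[xs[x]]][[ys[y]]]
        check_known_keys(sub, xs, sprintf("kernel, action '%s', (%s,%s)",
                                          an, xs[x], ys[y]))
        for (xn in seq_len(nX)) {
          row <- sub[[xs[xn]]]
          check_known_keys(row, ys, sprintf(
            "kernel, action '%s', (%s,%s) -> %s", an, xs[x], ys[y], xs[xn]))
          for (yn in seq_len(nY))
            ker[x, y, xn, yn] <- as.numeric(
              row[[ys[yn]]] %||%
                stopf("kernel, action '%s': missing entry", an))
        }
        s <- sum(ker[x, y, , ])
        if (abs(s - 1) > HARD_ROW_TOL)
          stopf("kernel row (action '%s', %s, %s) sums to %.12g",
                an, xs[x], ys[y], s)
        if (s != 1) {
          if (abs(s - 1) > ROW_SUM_TOL)
            note("note: kernel row (action '%s', %s, %s) summed to %.12g; renormalized",
                 an, xs[x], ys[y], s)
          ker[x, y, , ] <- ker[x, y, , ] / s
        }
      }
    }
    kernel[[a]] <- ker
    f <- array(NA_real_, c(nX, nY, nO))
    ol <- raw$obs_model[[an]]
    for (x in seq_len(nX)) for (y in seq_len(nY)) {
      row <- ol[[xs[x]]][[ys[y]]]
      check_known_keys(row, obs, sprintf("obs_model, action '%s'", an))
      for (o in seq_len(nO))
        f[x, y, o] <- as.numeric(
          row[[obs[o]]] %||% stopf("obs_model, action '%s': missing entry", an))
      s <- sum(f[x, y, ])
      if (abs(s - 1) > HARD_ROW_TOL)
        stopf("obs_model row (action '%s', %s, %s) sums to %.12g",
              an, xs[x], ys[y], s)
      if (s != 1) f[x, y, ] <- f[x, y, ] / s
    }
    om[[a]] <- f
  }
  rew <- array(NA_real_, c(nX, nY, length(actions)))
  for (x in seq_len(nX)) for (y in seq_len(nY)) {
    row <- raw$rewards[[xs[x]]][[ys[y]]]
    check_known_keys(row, actions, "rewards")
    for (a in seq_along(actions))
      rew[x, y, a] <- as.numeric(
        row[[actions[a]]] %||% stopf("rewards: missing entry"))
  }
  momdp_problem(xs, ys, actions, kernel, obs, om, rew,
                as.numeric(raw$discount),
                prob_vector_from_named(raw$initial_belief, ys,
                                       "initial_belief"),
                horizon_from_list(raw$horizon))
}

## policy / value export ---------------------------------------------------

#' Tabulate a solved policy and value for export
#'
#' @param problem the problem the solution belongs to.
#' @param solution either the list returned by [value_iteration()] (MDP)
#'   or a `grid_solution` (belief-space solvers).
#' @return data frame with state labels, a `grid_point` column for
#'   belief-space solutions, the action label and the value.
#' @export
solution_table <- function(problem, solution) {
  if (inherits(solution, "grid_solution")) {
    nX <- nrow(solution$value)
    nG <- ncol(solution$value)
    data.frame(
      state = rep(rownames(solution$value), nG),
      grid_point = rep(apply(solution$grid$points, 1L, paste,
                             collapse = "/"), each = nX),
      action = solution$actions[as.integer(solution$policy)],
      value = as.numeric(solution$value),
      stringsAsFactors = FALSE)
  } else {
    data.frame(state = problem$states,
               action = problem$actions[solution$policy],
               value = solution$value, stringsAsFactors = FALSE)
  }
}

#' Export an alpha-vector set as JSON
#'
#' @param problem the POMDP the set belongs to.
#' @param alpha_set alpha-vector set.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_alpha_set <- function(problem, alpha_set, path) {
  out <- lapply(seq_len(ncol(alpha_set$alphas)), function(j)
    list(action = problem$actions[alpha_set$actions[j]],
         vector = named_prob_vector(alpha_set$alphas[, j], problem$states)))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = I(17),
                       pretty = TRUE)
  invisible(path)
}
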