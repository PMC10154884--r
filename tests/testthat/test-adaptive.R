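two_kernel_models <- function(p1, p2) {
  ## two single-action 2-state models with P_k(hi|lo) = pk
  model_set(list(list(rbind(c(1 - p1, p1), c(0.5, 0.5))),
                 list(rbind(c(1 - p2, p2), c(0.5, 0.5)))),
            rbind(c(1), c(1)))
}

test_that("model-state updating follows Bayes' rule", {
  ms <- two_kernel_models(0.8, 0.4)
  # direct arithmetic: (0.5*0.8, 0.5*0.4) / 0.6
  expect_equal(update_model_belief(c(0.5, 0.5), 1, 1, 2, ms),
               c(2 / 3, 1 / 3), tolerance = 1e-14)
  # degenerate prior is absorbing
  expect_equal(update_model_belief(c(1, 0), 1, 1, 2, ms), c(1, 0))
  # identical kernels: likelihood ratio 1, q unchanged
  ms_same <- two_kernel_models(0.6, 0.6)
  expect_equal(update_model_belief(c(0.3, 0.7), 1, 1, 1, ms_same),
               c(0.3, 0.7), tolerance = 1e-14)
  # impossible evidence errors, naming the transition
  ms0 <- two_kernel_models(0, 0)
  expect_error(update_model_belief(c(0.5, 0.5), 1, 1, 2, ms0),
               "impossible evidence")
})

test_that("model averaging of kernels and rewards is the stated mixture", {
  ap <- small_adaptive(seed = 17L, n_states = 3L)
  q <- c(0.35, 0.65)
  avg <- averaged_transition(q, ap$models)
  for (a in seq_along(ap$actions)) {
    manual <- q[1] * ap$models$kernels[[1]][[a]] +
      q[2] * ap$models$kernels[[2]][[a]]
    expect_equal(avg[[a]], manual, tolerance = 1e-14)
    expect_true(all(abs(rowSums(avg[[a]]) - 1) < 1e-12))
  }
  # degenerate q returns the model's own kernel
  expect_equal(averaged_transition(c(1, 0), ap$models)[[1]],
               ap$models$kernels[[1]][[1]])
  # weighted-mean reward: 0.25 * 0 + 0.75 * 4 = 3
  ms <- model_set(list(list(matrix(1)), list(matrix(1))),
                  list(matrix(0), matrix(4)))
  expect_equal(averaged_reward(c(0.25, 0.75), ms), matrix(3))
})

test_that("model weights form a martingale under the mixture law", {
  ap <- small_adaptive(seed = 23L, n_states = 3L)
  q <- c(0.4, 0.6)
  for (a in 1:2) for (x in 1:3) {
    lik <- sapply(ap$models$kernels, function(kr) kr[[a]][x, ])
    pmix <- drop(lik %*% q)
    expected_q <- Reduce(`+`, lapply(which(pmix > 0), function(xn)
      pmix[xn] * update_model_belief(q, x, a, xn, ap$models)))
    expect_equal(expected_q, q, tolerance = 1e-12)
  }
})

test_that("adaptive values collapse to known-model values at simplex corners", {
  ap <- small_adaptive(seed = 3L)
  sol <- solve_active_adaptive(ap, grid = 10, tol = 1e-10)
  corners <- consdp:::simplex_corners(sol$grid)
  for (k in 1:2) {
    mk <- value_iteration(consdp:::model_mdp(ap, k), tol = 1e-10)
    expect_lt(max(abs(sol$value[, corners[k]] - mk$value)), 1e-8)
  }
})

test_that("a single model collapses both solvers to plain value iteration", {
  cfg <- generator_config(seed = 5L, n_states = 2L, n_models = 1L)
  ap <- random_model_set(cfg, divergence = 0)
  base <- value_iteration(consdp:::model_mdp(ap, 1), tol = 1e-10)
  for (solver in list(solve_active_adaptive, solve_passive_adaptive)) {
    sol <- solver(ap, grid = 1, tol = 1e-10)
    expect_equal(drop(sol$value), base$value, tolerance = 1e-8,
                 ignore_attr = TRUE)
  }
})

test_that("identical models make passive and active agree everywhere", {
  ap <- small_adaptive(seed = 31L, divergence = 0)
  act <- solve_active_adaptive(ap, grid = 8, tol = 1e-10)
  pas <- solve_passive_adaptive(ap, grid = 8, tol = 1e-10)
  expect_lt(max(abs(act$value - pas$value)), 1e-8)
})

test_that("active value dominates the evaluated passive policy (value of information)", {
  ap <- small_adaptive(seed = 3L)
  grid <- simplex_grid(2, 10)
  act <- solve_active_adaptive(ap, grid = grid, tol = 1e-9)
  pas <- solve_passive_adaptive(ap, grid = grid, tol = 1e-9)
  realized <- evaluate_adaptive_policy(ap, pas)
  expect_true(all(act$value >= realized - 1e-6))
})

test_that("active value at corner-adjacent points matches a belief-tree oracle", {
  ap <- small_adaptive(seed = 3L)
  ap_fin <- ap
  ap_fin$horizon <- horizon_spec("finite", T = 6)
  grid <- simplex_grid(2, 50)
  sol <- solve_active_adaptive(ap_fin, grid = grid)
  for (g in c(1L, 2L, nrow(grid$points) - 1L, nrow(grid$points))) {
    q <- grid$points[g, ]
    for (x in 1:2) {
      oracle <- expectimax_tree(ap_fin, 6, x = x, q = q)
      expect_lt(abs(sol$value[x, g] - oracle), 0.02)
    }
  }
})

test_that("grid refinement behaves like a Cauchy sequence at shared points", {
  ap <- small_adaptive(seed = 3L)
  sols <- lapply(c(5, 10, 20), function(m)
    solve_active_adaptive(ap, grid = m, tol = 1e-9))
  ## points of the m=5 grid are shared by the m=10 and m=20 grids
  shared_q <- lapply(seq_len(6), function(i) sols[[1]]$grid$points[i, ])
  gaps <- sapply(1:2, function(lev) {
    max(sapply(shared_q, function(q) max(sapply(1:2, function(x)
      abs(grid_value_at(sols[[lev + 1]], x, q) -
            grid_value_at(sols[[lev]], x, q))))))
  })
  expect_lte(gaps[2], gaps[1] + 1e-9)
})

test_that("simulation is seed-reproducible and learns the true model", {
  ap <- small_adaptive(seed = 3L)
  sol <- solve_active_adaptive(ap, grid = 10, tol = 1e-8)
  s1 <- simulate_adaptive(ap, sol, true_model_index = 2L, horizon = 10,
                          n_reps = 5, seed = 99L)
  s2 <- simulate_adaptive(ap, sol, true_model_index = 2L, horizon = 10,
                          n_reps = 5, seed = 99L)
  expect_identical(s1, s2)
  for (r in 1:5) for (t in 1:10) expect_prob_vector(s1$q_path[r, t, ])

  # degenerate prior stays degenerate
  apd <- ap; apd$prior <- c(0, 1)
  sd <- simulate_adaptive(apd, sol, true_model_index = 2L, horizon = 5,
                          n_reps = 2, seed = 1L)
  expect_true(all(sd$q_path[, , 2] == 1))

  # distinguishable models: mean terminal weight on the true model
  # exceeds its prior by more than 3 standard errors
  s <- simulate_adaptive(ap, sol, true_model_index = 2L, horizon = 25,
                         n_reps = 200, seed = 7L)
  w <- s$q_path[, 26, 2]
  se <- sd(w) / sqrt(length(w))
  expect_gt(mean(w), ap$prior[2] + 3 * se)
})
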