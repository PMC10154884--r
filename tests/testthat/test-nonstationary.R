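test_that("drift prediction is the chain step on model weights", {
  drift <- rbind(c(0.9, 0.1), c(0.2, 0.8))
  expect_equal(predict_model_belief(c(0.5, 0.5), drift), c(0.55, 0.45),
               tolerance = 1e-14)
  # identity drift leaves q unchanged
  expect_equal(predict_model_belief(c(0.3, 0.7), diag(2)), c(0.3, 0.7))
  # absorbing drift forces the jump
  absorbing <- rbind(c(1, 0), c(1, 0))
  expect_equal(predict_model_belief(c(0.5, 0.5), absorbing), c(1, 0))
})

test_that("nonstationary updating is predict-then-correct", {
  p <- drifting_problem(seed = 3L)
  # identity drift collapses to the stationary Bayes update
  pid <- p; pid$drift <- diag(2)
  q <- c(0.4, 0.6)
  for (a in 1:2) for (x in 1:2) for (xn in 1:2)
    expect_equal(nonstationary_update(q, x, a, xn, pid),
                 update_model_belief(q, x, a, xn, p$models),
                 tolerance = 1e-14)

  # identical kernels: no correction, update equals pure prediction
  psame <- p
  psame$models$kernels[[2]] <- psame$models$kernels[[1]]
  expect_equal(nonstationary_update(q, 1, 1, 2, psame),
               predict_model_belief(q, p$drift), tolerance = 1e-14)

  # numeric case against brute-force enumeration of (y, y', x')
  qp <- predict_model_belief(q, p$drift)
  for (a in 1:2) for (x in 1:2) for (xn in 1:2) {
    joint <- sapply(1:2, function(yn)
      qp[yn] * p$models$kernels[[yn]][[a]][x, xn])
    expect_equal(nonstationary_update(q, x, a, xn, p),
                 joint / sum(joint), tolerance = 1e-13)
  }
})

test_that("iterated nonstationary filtering equals model-path enumeration", {
  p <- drifting_problem(seed = 23L)
  evidence <- list(list(x = 1L, a = 1L, x_next = 2L),
                   list(x = 2L, a = 2L, x_next = 2L),
                   list(x = 2L, a = 1L, x_next = 1L),
                   list(x = 1L, a = 2L, x_next = 1L))
  q <- p$prior
  for (s in evidence)
    q <- nonstationary_update(q, s$x, s$a, s$x_next, p)
  expect_equal(q, joint_filter_oracle(p, evidence), tolerance = 1e-12)
})

test_that("nonstationary filtering equals mixed filtering on the drift embedding", {
  p <- drifting_problem(seed = 3L)
  emb <- nonstationary_to_momdp(p)
  q <- c(0.25, 0.75)
  for (a in 1:2) for (x in 1:2) for (xn in 1:2)
    expect_equal(mixed_belief_update(x, q, a, xn, 1L, emb),
                 nonstationary_update(q, x, a, xn, p), tolerance = 1e-13)
})

test_that("identity drift reproduces the stationary adaptive solution", {
  p <- drifting_problem(seed = 3L, drift = diag(2))
  ap <- small_adaptive(seed = 3L)
  grid <- simplex_grid(2, 10)
  sn <- solve_nonstationary(p, grid = grid, tol = 1e-10)
  sa <- solve_active_adaptive(ap, grid = grid, tol = 1e-10)
  expect_lt(max(abs(sn$value - sa$value)), 1e-8)
})

test_that("a single model collapses the nonstationary solver to value iteration", {
  ap1 <- random_model_set(generator_config(seed = 2L, n_states = 2L,
                                           n_models = 1L), 0)
  p <- nonstationary_problem(ap1$states, ap1$actions, ap1$models,
                             1, matrix(1), ap1$discount)
  sol <- solve_nonstationary(p, grid = 1, tol = 1e-10)
  vi <- value_iteration(consdp:::model_mdp(ap1, 1), tol = 1e-10)
  expect_lt(max(abs(drop(sol$value) - vi$value)), 1e-8)
})

test_that("finite-horizon nonstationary values match belief-tree expectimax", {
  p <- drifting_problem(seed = 3L)
  p$horizon <- horizon_spec("finite", T = 5)
  grid <- simplex_grid(2, 50)
  sol <- solve_nonstationary(p, grid = grid)
  for (g in c(1L, 13L, 26L, 39L, 51L)) {
    q <- grid$points[g, ]
    for (x in 1:2)
      expect_lt(abs(sol$value[x, g] - expectimax_tree(p, 5, x = x, q = q)),
                0.03)
  }
})

test_that("period ordering is return, model drift, state transition", {
  # one-step oracle enumerating the paper's stated event sequence
  p <- drifting_problem(seed = 7L)
  p$horizon <- horizon_spec("finite", T = 1)
  sol <- solve_nonstationary(p, grid = 10)
  grid <- sol$grid
  for (g in seq_len(nrow(grid$points))) {
    q <- grid$points[g, ]
    qp <- predict_model_belief(q, p$drift)
    for (x in 1:2) {
      # immediate return under prior q; transition under drifted q'
      # (one stage, terminal value zero, so only the return matters)
      manual <- max(sapply(1:2, function(a)
        sum(q * sapply(1:2, function(k) p$models$rewards[[k]][x, a]))))
      expect_equal(sol$value[x, g], manual, tolerance = 1e-12,
                   ignore_attr = TRUE)
    }
  }
  # two stages: the continuation is weighted by P(x'|x,a,q'), not P(..|q)
  p2 <- drifting_problem(seed = 7L)
  p2$horizon <- horizon_spec("finite", T = 2)
  grid2 <- simplex_grid(2, 50)
  sol2 <- solve_nonstationary(p2, grid = grid2)
  g <- 26L
  q <- grid2$points[g, ]
  oracle <- expectimax_tree(p2, 2, x = 1, q = q)
  expect_lt(abs(sol2$value[1, g] - oracle), 0.02)
})

test_that("scenario sweeps tabulate policy disagreement", {
  p <- drifting_problem(seed = 3L)
  grid <- simplex_grid(2, 8)
  id <- drift_scenario("stationary", diag(2))
  deg <- drift_scenario("degrading", rbind(c(0.5, 0.5), c(0, 1)),
                        "productive regime decays fast")
  # identical scenarios produce an empty disagreement table
  sw_same <- scenario_sweep(p, list(id, id), grid = grid, tol = 1e-8)
  expect_equal(nrow(sw_same$disagreement), 0)
  # a single scenario equals a direct solve
  sw_one <- scenario_sweep(p, list(deg), grid = grid, tol = 1e-8)
  pd <- p; pd$drift <- deg$drift
  direct <- solve_nonstationary(pd, grid = grid, tol = 1e-8)
  expect_equal(sw_one$solutions[[1]]$value, direct$value)
  # the identity-drift column equals the stationary adaptive solution
  sw <- scenario_sweep(p, list(id, deg), grid = grid, tol = 1e-9)
  ap <- small_adaptive(seed = 3L)
  sa <- solve_active_adaptive(ap, grid = grid, tol = 1e-9)
  expect_lt(max(abs(sw$solutions$stationary$value - sa$value)), 1e-7)
  expect_true(all(c("state", "grid_point", "stationary", "degrading")
                  %in% names(sw$disagreement)))
})
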