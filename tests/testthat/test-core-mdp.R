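test_that("validation reports each violation with its location", {
  expect_length(validate_problem(tiny_mdp()), 0)

  bad <- tiny_mdp()
  bad$kernel$rest[1, ] <- c(0.4, 0.5)            # row sums to 0.9
  v <- validate_problem(bad)
  expect_match(v, "action 'rest', state 'low'", all = FALSE)

  lam1 <- tiny_mdp(discount = 1)
  expect_match(validate_problem(lam1), "finite horizon", all = FALSE)
  expect_length(validate_problem(tiny_mdp(discount = 1,
                                          horizon = horizon_spec("finite", T = 3))),
                0)
})

test_that("bellman backup reproduces the one-step optimality operator", {
  # single state, single action: no future term beyond lambda * 0
  p1 <- single_state_mdp(rewards = 1, discount = 0.9)
  b <- bellman_backup(0, p1)
  expect_equal(b$value, 1)
  expect_equal(b$policy, 1L)

  # lambda = 0 annihilates the future for any V
  p0 <- tiny_mdp(discount = 0)
  b0 <- bellman_backup(c(5, -3), p0)
  expect_equal(b0$value, apply(p0$rewards, 1, max), ignore_attr = TRUE)

  # seeded 2-state 2-action problem against a hand-rolled sum-product
  p <- random_mdp(generator_config(seed = 42L, n_states = 2L))
  V <- c(0.7, -1.3)
  manual <- sapply(1:2, function(x) {
    max(sapply(1:2, function(a)
      p$rewards[x, a] + p$discount *
        sum(sapply(1:2, function(xn) p$kernel[[a]][x, xn] * V[xn]))))
  })
  expect_equal(bellman_backup(V, p)$value, manual, tolerance = 1e-14)
})

test_that("value iteration hits closed forms and refuses lambda = 1", {
  p <- single_state_mdp(rewards = c(1, 2), discount = 0.5)
  sol <- value_iteration(p, tol = 1e-12)
  expect_equal(sol$value, 4, tolerance = 1e-10)    # R_max / (1 - lambda)
  expect_equal(sol$policy, 2L)

  # identical actions: single-action value, tie broken to lowest index
  p2 <- tiny_mdp()
  p2$kernel$harvest <- p2$kernel$rest
  p2$rewards[, 2] <- p2$rewards[, 1]
  sol2 <- value_iteration(p2, tol = 1e-10)
  expect_equal(sol2$value, policy_value(p2, c(1L, 1L)),
               tolerance = 1e-8, ignore_attr = TRUE)
  expect_equal(sol2$policy, c(1L, 1L))

  pl1 <- tiny_mdp(discount = 1)
  pl1$horizon <- horizon_spec("infinite")
  expect_error(value_iteration(pl1), "finite_horizon_solve")
})

test_that("value iteration matches exhaustive policy enumeration", {
  for (seed in c(5L, 6L, 7L)) {
    p <- random_mdp(generator_config(seed = seed, n_states = 3L,
                                     n_actions = 2L))
    vi <- value_iteration(p, tol = 1e-10)
    en <- enumerate_stationary_policies(p)
    expect_lt(max(abs(vi$value - en$value)), 1e-8)
  }
})

test_that("backward induction handles terminal cases and zero rewards", {
  # T = 1 with a terminal decision: terminal stage is max_a R(a|x)
  p <- tiny_mdp(horizon = horizon_spec("finite", T = 1,
                                       terminal_decision = TRUE))
  sol <- finite_horizon_solve(p)
  expect_equal(sol$value["t1", ], apply(p$rewards, 1, max),
               ignore_attr = TRUE)

  # T = 2, lambda = 1, deterministic chain: sum of the two stage rewards
  # along the forced path low -> high -> high
  chain <- mdp_problem(c("low", "high"), "go",
                       kernel = list(rbind(c(0, 1), c(0, 1))),
                       rewards = rbind(2, 5), discount = 1,
                       horizon = horizon_spec("finite", T = 2))
  solc <- finite_horizon_solve(chain)
  expect_equal(solc$value["t0", "low"], 2 + 5)

  # all rewards zero: every stage value 0, ties go to action 1
  z <- tiny_mdp(horizon = horizon_spec("finite", T = 3))
  z$rewards[] <- 0
  solz <- finite_horizon_solve(z)
  expect_true(all(solz$value == 0))
  expect_true(all(solz$policy[1:3, ] == 1L))

  expect_error(finite_horizon_solve(tiny_mdp()), "finite")
})

test_that("policy evaluation solves the linear system exactly", {
  p <- single_state_mdp(rewards = 1, discount = 0.9)
  expect_equal(policy_value(p, 1L), 10, tolerance = 1e-12)

  p0 <- tiny_mdp(discount = 0)
  expect_equal(policy_value(p0, c(2L, 1L)),
               c(p0$rewards[1, 2], p0$rewards[2, 1]),
               ignore_attr = TRUE)

  # truncated-series oracle on a 2-state problem
  p <- random_mdp(generator_config(seed = 9L, n_states = 2L))
  pol <- c(2L, 1L)
  P <- rbind(p$kernel[[2]][1, ], p$kernel[[1]][2, ])
  R <- c(p$rewards[1, 2], p$rewards[2, 1])
  V_series <- numeric(2)
  Pt <- diag(2)
  for (tau in 0:199) {
    V_series <- V_series + p$discount^tau * drop(Pt %*% R)
    Pt <- Pt %*% P
  }
  expect_lt(max(abs(policy_value(p, pol) - V_series)), 1e-8)

  expect_error(policy_value(tiny_mdp(discount = 1), c(1L, 1L)), "discount")
})

test_that("the backup operator is a contraction and monotone", {
  set.seed(100)
  p <- random_mdp(generator_config(seed = 13L, n_states = 3L))
  for (i in 1:20) {
    U <- rnorm(3, sd = 5)
    W <- rnorm(3, sd = 5)
    bu <- bellman_backup(U, p)$value
    bw <- bellman_backup(W, p)$value
    expect_lte(max(abs(bu - bw)), p$discount * max(abs(U - W)) + 1e-12)
    Wd <- U + abs(rnorm(3))                      # U <= Wd elementwise
    expect_true(all(bellman_backup(Wd, p)$value >= bu - 1e-12))
  }
})

test_that("the greedy policy from value iteration evaluates back to its value", {
  p <- random_mdp(generator_config(seed = 21L, n_states = 3L))
  tol <- 1e-9
  sol <- value_iteration(p, tol = tol)
  pv <- policy_value(p, sol$policy)
  expect_lt(max(abs(pv - sol$value)), tol / (1 - p$discount))
})
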