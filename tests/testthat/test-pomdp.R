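test_that("belief filtering follows predict-then-correct Bayes", {
  # numeric case: uniform prior, prediction (0.3, 0.7), likelihood (0.9, 0.2)
  p <- pomdp_problem(
    states = c("A", "B"), actions = "a",
    kernel = list(rbind(c(0.3, 0.7), c(0.3, 0.7))),
    rewards = rbind(0, 0), discount = 0.9,
    observations = c("pos", "neg"),
    obs_model = list(rbind(c(0.9, 0.1), c(0.2, 0.8))))
  b <- belief_update(c(0.5, 0.5), "a", "pos", p)
  expect_equal(b, c(27 / 41, 14 / 41), tolerance = 1e-14)
  marg <- observation_marginal(c(0.5, 0.5), "a", p)
  expect_equal(unname(marg["pos"]), 0.41, tolerance = 1e-14)
  expect_equal(sum(marg), 1, tolerance = 1e-14)

  # identity monitoring pins the belief on the observed state
  pid <- identity_obs_pomdp()
  b2 <- belief_update(c(0.5, 0.5), 1, 2, pid)
  expect_equal(b2, c(0, 1))

  # uninformative monitoring reduces to pure prediction
  pu <- two_state_pomdp()
  pu$obs_model <- list(matrix(0.5, 2, 2), matrix(0.5, 2, 2))
  b0 <- c(0.4, 0.6)
  expect_equal(belief_update(b0, 1, 1, pu),
               drop(b0 %*% pu$kernel[[1]]), tolerance = 1e-14)

  # impossible observation errors
  pz <- two_state_pomdp()
  pz$obs_model[[1]][, 1] <- 0
  pz$obs_model[[1]][, 2] <- 1
  expect_error(belief_update(c(0.5, 0.5), 1, 1, pz), "impossible evidence")
})

test_that("iterated filtering equals joint-distribution enumeration", {
  p <- two_state_pomdp()
  evidence <- list(list(a = 1L, o = 2L), list(a = 2L, o = 1L),
                   list(a = 1L, o = 1L), list(a = 2L, o = 2L))
  b <- p$initial_belief
  for (step in evidence)
    b <- belief_update(b, step$a, step$o, p)
  expect_equal(b, joint_filter_oracle(p, evidence), tolerance = 1e-12)
  # empty sequence returns the prior
  expect_equal(joint_filter_oracle(p, list()), p$initial_belief)
})

test_that("observation mixture reproduces the predicted state distribution", {
  # law of total probability: sum_o P(o|b,a) b'(.|o) = prediction
  p <- two_state_pomdp()
  b <- c(0.35, 0.65)
  for (a in 1:2) {
    marg <- observation_marginal(b, a, p)
    mix <- Reduce(`+`, lapply(which(marg > 0), function(o)
      marg[o] * belief_update(b, a, o, p)))
    expect_equal(unname(mix), drop(b %*% p$kernel[[a]]), tolerance = 1e-12)
  }
})

test_that("belief-averaged returns are inner products", {
  R <- rbind(c(0, 5), c(4, 1))
  expect_equal(expected_reward(c(1, 0), 2, R), 5)
  expect_equal(expected_reward(c(0.25, 0.75), 1, rbind(0, 4)), 3)
  expect_equal(expected_reward(c(0.3, 0.7), 1, matrix(2, 2, 2)), 2)
})

test_that("horizon-1 alpha vectors are the nondominated reward columns", {
  p <- two_state_pomdp()
  g1 <- solve_pomdp_exact(p, 1)[[1]]
  expect_equal(ncol(g1$alphas), 2)
  for (j in 1:2)
    expect_equal(g1$alphas[, j], p$rewards[, g1$actions[j]],
                 ignore_attr = TRUE)
})

test_that("identity monitoring collapses the POMDP to the MDP stage-by-stage", {
  base <- tiny_mdp(horizon = horizon_spec("finite", T = 4))
  p <- identity_obs_pomdp(tiny_mdp())
  sets <- solve_pomdp_exact(p, 4)
  fh <- finite_horizon_solve(base)
  for (h in 1:4) {
    corner_vals <- sapply(1:2, function(x)
      alpha_value(sets[[h]], diag(2)[x, ])$value)
    expect_lt(max(abs(corner_vals - fh$value[4 - h + 1, ])), 1e-10)
  }
})

test_that("exact alpha-vector values equal belief-tree expectimax", {
  p <- two_state_pomdp()
  sets <- solve_pomdp_exact(p, 3)
  test_beliefs <- seq(0, 1, length.out = 11)
  for (b1 in test_beliefs) {
    b <- c(b1, 1 - b1)
    expect_lt(abs(alpha_value(sets[[3]], b)$value -
                    expectimax_tree(p, 3, b = b)), 1e-10)
  }
  # the represented value function is convex on the belief simplex
  v <- function(b1) alpha_value(sets[[3]], c(b1, 1 - b1))$value
  set.seed(2)
  for (i in 1:20) {
    x <- runif(2)
    expect_lte(v(mean(x)), (v(x[1]) + v(x[2])) / 2 + 1e-12)
  }
})

test_that("summing over observations equals summing over reachable beliefs", {
  # regroup the one-step expectation by distinct updated beliefs
  p <- two_state_pomdp()
  sets <- solve_pomdp_exact(p, 3)
  V2 <- function(b) alpha_value(sets[[2]], b)$value
  b <- c(0.45, 0.55)
  for (a in 1:2) {
    marg <- observation_marginal(b, a, p)
    by_obs <- sum(sapply(which(marg > 0), function(o)
      marg[o] * V2(belief_update(b, a, o, p))))
    nb <- lapply(which(marg > 0), function(o) belief_update(b, a, o, p))
    key <- sapply(nb, function(x) paste(round(x, 10), collapse = "|"))
    probs <- tapply(marg[marg > 0], key, sum)
    uniq <- nb[!duplicated(key)]
    names(uniq) <- key[!duplicated(key)]
    by_belief <- sum(sapply(names(probs), function(k)
      probs[[k]] * V2(uniq[[k]])))
    expect_equal(by_obs, by_belief, tolerance = 1e-12)
  }
})

test_that("the exact solver refuses backups beyond its enumeration cap", {
  p <- two_state_pomdp()
  expect_error(solve_pomdp_exact(p, 3, cap = 3), "point_based")
})

test_that("point-based backup lower-bounds the optimum and recovers corners", {
  # identity observations, beliefs at corners: MDP values recovered
  pid <- identity_obs_pomdp()
  pb <- solve_pomdp_point_based(pid, diag(2), tol = 1e-10)
  vi <- value_iteration(tiny_mdp(), tol = 1e-10)
  for (x in 1:2)
    expect_lt(abs(alpha_value(pb, diag(2)[x, ])$value - vi$value[x]), 1e-6)

  # single-state problem: geometric series
  p1 <- pomdp_problem("s", c("a", "b"), rep(list(matrix(1)), 2),
                      matrix(c(1, 2), 1), 0.5, "o",
                      rep(list(matrix(1)), 2), initial_belief = 1)
  pb1 <- solve_pomdp_point_based(p1, matrix(1, 1, 1), tol = 1e-10)
  expect_equal(alpha_value(pb1, 1)$value, 4, tolerance = 1e-6)

  # lower-bound property: point-based value never exceeds an upper bound
  # on the optimal value (finite-horizon exact value plus discounting tail)
  p <- two_state_pomdp(discount = 0.6)
  set.seed(3)
  bel <- rbind(diag(2), c(0.5, 0.5),
               t(sapply(1:20, function(i) { u <- runif(1); c(u, 1 - u) })))
  pb <- solve_pomdp_point_based(p, bel, tol = 1e-9)
  h <- 8L
  sets <- solve_pomdp_exact(p, h)
  tail <- p$discount^h * max(abs(p$rewards)) / (1 - p$discount)
  for (i in seq_len(nrow(bel))) {
    vex <- alpha_value(sets[[h]], bel[i, ])$value
    vpb <- alpha_value(pb, bel[i, ])$value
    expect_lte(vpb, vex + tail + 1e-9)
    # and the approximation is good at the backed-up beliefs
    expect_gte(vpb, vex - 1e-9)
    expect_lt(vpb - vex, 0.05 * diff(range(p$rewards)) + tail)
  }
})

test_that("policy simulation is reproducible and consistent with values", {
  p <- identity_obs_pomdp()
  # zero rewards give zero returns
  pz <- p; pz$rewards[] <- 0
  alphaz <- list(alphas = matrix(0, 2, 1), actions = 1L)
  rz <- evaluate_pomdp_policy(pz, alphaz, horizon = 10, n_reps = 20,
                              seed = 4L)
  expect_true(all(rz$returns == 0))

  # identity observations with MDP-optimal alphas: mean return within
  # 3 SE of the MDP value at the (known) initial state
  vi <- value_iteration(tiny_mdp(), tol = 1e-10)
  alpha_greedy <- list(
    alphas = sapply(1:2, function(x) {
      a <- numeric(2); a[x] <- 1e6; a          # force action chosen at e_x
    }), actions = vi$policy)
  h <- truncation_horizon(0.9, max(abs(p$rewards)), eps = 1e-4)
  r1 <- evaluate_pomdp_policy(p, alpha_greedy, horizon = h, n_reps = 600,
                              seed = 11L)
  expect_lt(abs(r1$mean - sum(p$initial_belief * vi$value)),
            3 * r1$se + 1e-4)
  r2 <- evaluate_pomdp_policy(p, alpha_greedy, horizon = h, n_reps = 600,
                              seed = 11L)
  expect_identical(r1$returns, r2$returns)

  # any simulated policy stays below the optimal value (plus noise)
  expect_lt(r1$mean, sum(p$initial_belief * vi$value) + 3 * r1$se + 1e-4)
})
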