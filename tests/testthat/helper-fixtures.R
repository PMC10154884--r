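## Small fixture builders shared across the suite.  Everything is built
## in code; seeds make every fixture reproducible.

tiny_mdp <- function(discount = 0.9, horizon = horizon_spec("infinite")) {
  mdp_problem(
    states  = c("low", "high"),
    actions = c("rest", "harvest"),
    kernel  = list(rest    = rbind(c(0.4, 0.6), c(0.1, 0.9)),
                   harvest = rbind(c(0.9, 0.1), c(0.6, 0.4))),
    rewards = rbind(c(0, 1), c(0, 3)),
    discount = discount, horizon = horizon)
}

single_state_mdp <- function(rewards = c(1, 2), discount = 0.5) {
  mdp_problem(states = "only", actions = paste0("a", seq_along(rewards)),
              kernel = rep(list(matrix(1, 1, 1)), length(rewards)),
              rewards = matrix(rewards, 1), discount = discount)
}

two_state_pomdp <- function(discount = 0.9) {
  pomdp_problem(
    states = c("lo", "hi"), actions = c("u", "v"),
    kernel = list(rbind(c(0.7, 0.3), c(0.2, 0.8)),
                  rbind(c(0.9, 0.1), c(0.5, 0.5))),
    rewards = rbind(c(0, 0.2), c(1, 0.6)), discount = discount,
    observations = c("o1", "o2"),
    obs_model = list(rbind(c(0.8, 0.2), c(0.3, 0.7)),
                     rbind(c(0.6, 0.4), c(0.25, 0.75))),
    initial_belief = c(0.5, 0.5))
}

identity_obs_pomdp <- function(problem = tiny_mdp(),
                               initial_belief = c(1, 0)) {
  nX <- length(problem$states)
  pomdp_problem(problem$states, problem$actions, problem$kernel,
                problem$rewards, problem$discount,
                observations = paste0("see_", problem$states),
                obs_model = rep(list(diag(nX)), length(problem$actions)),
                initial_belief = initial_belief)
}

small_adaptive <- function(seed = 3L, n_states = 2L, divergence = 0.3,
                           discount = 0.9) {
  random_model_set(generator_config(seed = seed, n_states = n_states,
                                    n_actions = 2L, n_models = 2L,
                                    discount = discount),
                   divergence = divergence)
}

small_momdp <- function(seed = 11L, discount = 0.9) {
  ## 2 observable x 2 hidden x 2 actions x 2 observations, random but
  ## well formed
  set.seed(seed)
  nX <- 2L; nY <- 2L; nA <- 2L; nO <- 2L
  rand_simplex <- function(n) { g <- stats::rgamma(n, 1); g / sum(g) }
  kernel <- lapply(seq_len(nA), function(a) {
    ker <- array(0, c(nX, nY, nX, nY))
    for (x in 1:nX) for (y in 1:nY)
      ker[x, y, , ] <- matrix(rand_simplex(nX * nY), nX, nY)
    ker
  })
  obs <- lapply(seq_len(nA), function(a) {
    f <- array(0, c(nX, nY, nO))
    for (x in 1:nX) for (y in 1:nY) f[x, y, ] <- rand_simplex(nO)
    f
  })
  rewards <- array(stats::runif(nX * nY * nA), c(nX, nY, nA))
  momdp_problem(c("x1", "x2"), c("y1", "y2"), c("a1", "a2"), kernel,
                c("o1", "o2"), obs, rewards, discount,
                initial_belief = c(0.5, 0.5))
}

drifting_problem <- function(seed = 3L, discount = 0.9,
                             drift = rbind(c(0.9, 0.1), c(0.1, 0.9))) {
  ap <- small_adaptive(seed = seed, discount = discount)
  nonstationary_problem(ap$states, ap$actions, ap$models, ap$prior,
                        drift, ap$discount)
}

expect_prob_vector <- function(p, tol = 1e-12) {
  expect_true(all(p >= -tol))
  expect_equal(sum(p), 1, tolerance = tol)
}
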