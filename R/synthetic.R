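#' Configuration for the random problem generators
#'
#' @param seed integer seed; identical configurations generate identical
#'   problems.
#' @param n_states,n_actions,n_observations,n_models instance sizes.
#' @param concentration Dirichlet concentration of random kernel rows;
#'   large values give near-uniform rows, small values near-deterministic
#'   ones.
#' @param reward_range interval from which rewards are drawn uniformly.
#' @param discount per-step discount factor.
#' @return list of class `generator_config`.
#' @export
generator_config <- function(seed = 1L, n_states = 3L, n_actions = 2L,
                             n_observations = 2L, n_models = 2L,
                             concentration = 1, reward_range = c(0, 1),
                             discount = 0.9) {
  if (min(n_states, n_actions, n_observations, n_models) < 1L)
    stopf("sizes must be >= 1")
  if (concentration <= 0) stopf("concentration must be positive")
  structure(list(seed = as.integer(seed), n_states = as.integer(n_states),
                 n_actions = as.integer(n_actions),
                 n_observations = as.integer(n_observations),
                 n_models = as.integer(n_models),
                 concentration = concentration,
                 reward_range = reward_range, discount = discount),
            class = "generator_config")
}

## one Dirichlet(concentration) draw of length n
rdirichlet_row <- function(n, concentration) {
  g <- stats::rgamma(n, shape = concentration)
  if (sum(g) == 0) g <- rep(1, n)
  g / sum(g)
}

random_kernel <- function(n_states, n_actions, concentration) {
  lapply(seq_len(n_actions), function(a)
    t(vapply(seq_len(n_states),
             function(x) rdirichlet_row(n_states, concentration),
             numeric(n_states))))
}

#' Generate a random well-formed MDP
#'
#' Kernel rows are symmetric Dirichlet draws; rewards are uniform on
#' `reward_range`.  Construction guarantees [validate_problem()] passes;
#' identical seeds give identical problems.
#'
#' @param config a [generator_config()].
#' @return an [mdp_problem()].
#' @export
random_mdp <- function(config = generator_config()) {
  set.seed(config$seed)
  nX <- config$n_states; nA <- config$n_actions
  mdp_problem(
    states = paste0("s", seq_len(nX)),
    actions = paste0("a", seq_len(nA)),
    kernel = random_kernel(nX, nA, config$concentration),
    rewards = matrix(stats::runif(nX * nA, config$reward_range[1],
                                  config$reward_range[2]), nX, nA),
    discount = config$discount)
}

#' Generate a random adaptive problem with controlled model divergence
#'
#' `K` kernels are built as symmetric perturbations of one base kernel:
#' each row of each pair of kernels differs by a zero-sum direction
#' scaled so the row total-variation distance equals `divergence`
#' (clipped where the simplex boundary binds).  `divergence = 0` gives
#' identical models, so the model state never moves.
#'
#' @param config a [generator_config()].
#' @param divergence target per-row total-variation distance between
#'   models (nonnegative).
#' @param shared_rewards if `TRUE` (default) all models share one reward
#'   table.
#' @return an [adaptive_problem()] with uniform prior.
#' @export
random_model_set <- function(config = generator_config(), divergence = 0.2,
                             shared_rewards = TRUE) {
  if (divergence < 0) stopf("divergence must be nonnegative")
  set.seed(config$seed)
  nX <- config$n_states; nA <- config$n_actions; K <- config$n_models
  base <- random_kernel(nX, nA, config$concentration)
  ## one-sided offsets: model 1 keeps the base row, model K gets the
  ## full shift, intermediates interpolate
  offsets <- if (K == 1L) 0 else seq(0, 1, length.out = K)
  kernels <- lapply(seq_len(K), function(k) base)
  dv <- min(divergence, 1)
  for (a in seq_len(nA)) for (x in seq_len(nX)) {
    p <- base[[a]][x, ]
    if (dv == 0 || nX == 1L) next
    ## zero-sum direction with disjoint donor/recipient supports: remove
    ## mass proportionally from the high-probability half of the row, add
    ## it proportionally to the rest.  The half split keeps both sides'
    ## capacity >= 1/2, so the full shift is feasible for dv <= 1/2 and
    ## clipped otherwise; disjoint supports make
    ## TV(p + off_i * delta, p + off_j * delta) = |off_i - off_j| * dv.
    ord <- order(p, decreasing = TRUE)
    donors <- ord[seq_len(ceiling(nX / 2))]
    recip <- setdiff(seq_len(nX), donors)
    cap_d <- p[donors]
    cap_r <- 1 - p[recip]
    dv_row <- min(dv, sum(cap_d), sum(cap_r))
    delta <- numeric(nX)
    delta[donors] <- -dv_row * cap_d / sum(cap_d)
    delta[recip] <- dv_row * cap_r / sum(cap_r)
    for (k in seq_len(K))
      kernels[[k]][[a]][x, ] <- p + offsets[k] * delta
  }
  rewards <- matrix(stats::runif(nX * nA, config$reward_range[1],
                                 config$reward_range[2]), nX, nA)
  rew <- if (shared_rewards) rewards else
    lapply(seq_len(K), function(k)
      matrix(stats::runif(nX * nA, config$reward_range[1],
                          config$reward_range[2]), nX, nA))
  adaptive_problem(
    states = paste0("s", seq_len(nX)), actions = paste0("a", seq_len(nA)),
    models = model_set(kernels, rew), prior = rep(1 / K, K),
    discount = config$discount)
}

#' Configuration of the toy wildlife-harvest problem family
#'
#' A discrete population managed by harvest: abundance classes, per-model
#' per-class growth multipliers, per-action harvest fractions, a return
#' per unit harvested, and a monitoring confusion matrix for the
#' partially observed variant.  The default two models contrast a
#' productive and a degraded population; the default drift matrix lets the
#' productive regime degrade over time.
#'
#' @param abundance numeric abundance classes (ordered, distinct).
#' @param growth list with one per-class growth-multiplier vector per
#'   model.
#' @param harvest_fractions per-action fraction of the population removed.
#' @param return_per_unit return per unit of expected harvest.
#' @param confusion row-stochastic monitoring confusion matrix over
#'   abundance classes (default: 0.7 on the diagonal, rest split between
#'   neighbors).
#' @param drift row-stochastic model-transition matrix for the
#'   nonstationary variant.
#' @param discount per-step discount factor.
#' @param prior model prior.
#' @return list of class `harvest_config`.
#' @export
harvest_config <- function(abundance = c(0, 25, 50, 75, 100),
                           growth = list(productive = c(0, 1.6, 1.4, 1.2, 1.0),
                                         degraded   = c(0, 1.1, 1.0, 0.9, 0.8)),
                           harvest_fractions = c(none = 0, light = 0.1,
                                                 heavy = 0.4),
                           return_per_unit = 1,
                           confusion = NULL,
                           drift = NULL,
                           discount = 0.9,
                           prior = NULL) {
  n <- length(abundance)
  if (is.unsorted(abundance, strictly = TRUE))
    stopf("abundance classes must be strictly increasing")
  for (g in growth) {
    if (length(g) != n) stopf("each growth vector needs one entry per class")
    if (any(g < 0)) stopf("growth multipliers must be nonnegative")
  }
  if (any(harvest_fractions < 0 | harvest_fractions > 1))
    stopf("harvest fractions must lie in [0,1]")
  if (is.null(confusion)) {
    confusion <- matrix(0, n, n)
    for (i in seq_len(n)) {
      confusion[i, i] <- 0.7
      nb <- intersect(c(i - 1L, i + 1L), seq_len(n))
      confusion[i, nb] <- 0.3 / length(nb)
    }
  }
  if (!check_row_stochastic(confusion))
    stopf("confusion matrix is not row-stochastic")
  K <- length(growth)
  if (is.null(drift)) {
    ## default nonstationarity: the productive regime slowly degrades
    drift <- if (K == 2L) rbind(c(0.95, 0.05), c(0.02, 0.98)) else diag(K)
  }
  structure(list(abundance = abundance, growth = growth,
                 harvest_fractions = harvest_fractions,
                 return_per_unit = return_per_unit, confusion = confusion,
                 drift = as.matrix(drift), discount = discount,
                 prior = prior %||% rep(1 / K, K)),
            class = "harvest_config")
}

## split an expected abundance between the two nearest grid classes so the
## mean is preserved (clamped at the ends of the grid)
abundance_split <- function(value, abundance) {
  n <- length(abundance)
  p <- numeric(n)
  if (value <= abundance[1]) { p[1] <- 1; return(p) }
  if (value >= abundance[n]) { p[n] <- 1; return(p) }
  hi <- which(abundance >= value)[1]
  lo <- hi - 1L
  w <- (value - abundance[lo]) / (abundance[hi] - abundance[lo])
  p[lo] <- 1 - w
  p[hi] <- w
  p
}

harvest_kernel <- function(cfg, growth) {
  n <- length(cfg$abundance)
  lapply(cfg$harvest_fractions, function(h) {
    t(vapply(seq_len(n), function(i) {
      next_n <- growth[i] * cfg$abundance[i] * (1 - h)
      abundance_split(next_n, cfg$abundance)
    }, numeric(n)))
  })
}

harvest_rewards <- function(cfg) {
  n <- length(cfg$abundance)
  outer(cfg$abundance, cfg$harvest_fractions) * cfg$return_per_unit
}

#' Build the toy harvest problem family
#'
#' One biology, four uncertainty treatments: a known-model MDP (first
#' model taken as true), an adaptive problem over the rival growth
#' models, a partially observed variant of the known-model problem with
#' the monitoring confusion matrix, and a nonstationary variant in which
#' the governing growth model drifts.  Stripping the uncertainty layers
#' recovers the base MDP.
#'
#' @param config a [harvest_config()].
#' @return list with elements `mdp`, `adaptive`, `pomdp`,
#'   `nonstationary`.
#' @export
harvest_problem <- function(config = harvest_config()) {
  n <- length(config$abundance)
  states <- paste0("n", config$abundance)
  actions <- names(config$harvest_fractions) %||%
    paste0("h", config$harvest_fractions)
  rewards <- harvest_rewards(config)
  kernels <- lapply(config$growth, function(g) harvest_kernel(config, g))
  K <- length(kernels)
  base <- mdp_problem(states, actions, kernels[[1L]], rewards,
                      config$discount)
  adaptive <- adaptive_problem(states, actions,
                               model_set(unname(kernels), rewards),
                               config$prior, config$discount)
  pomdp <- pomdp_problem(states, actions, kernels[[1L]], rewards,
                         config$discount,
                         observations = paste0("obs_", states),
                         obs_model = rep(list(config$confusion), length(actions)),
                         initial_belief = rep(1 / n, n))
  nonstat <- nonstationary_problem(states, actions,
                                   model_set(unname(kernels), rewards),
                                   config$prior, config$drift,
                                   config$discount)
  list(mdp = base, adaptive = adaptive, pomdp = pomdp,
       nonstationary = nonstat)
}
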