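# Population metaheuristics under one contract: each optimizer minimises a
# user fitness over a box, keeps a greedy incumbent, respects bounds by
# clamping, and is bit-reproducible under a fixed seed (one generator per
# run, draws consumed in fixed agent-major order).
#
# The pelican and hippopotamus updates follow the canonical published
# formulations of those algorithms at default coefficients; the source
# material names only the behavioural phases, so the update equations here
# are reconstructions.

#' Optimizer configuration
#'
#' @param n_agents population size (>= 2).
#' @param n_iter number of iterations.
#' @param bounds 2-row matrix (`rbind(lower, upper)`) or list of
#'   `c(low, high)` per dimension; `low < high` everywhere.
#' @param seed integer seed.
#' @param inertia,cognitive,social PSO coefficients (constriction-
#'   equivalent defaults 0.729 / 1.49445 / 1.49445).
#' @return an `optimizer_config` list.
#' @export
optimizer_config <- function(n_agents = 30L, n_iter = 200L, bounds,
                             seed = 1L, inertia = 0.729,
                             cognitive = 1.49445, social = 1.49445) {
  if (is.list(bounds)) bounds <- do.call(cbind, bounds)
  bounds <- as.matrix(bounds)
  if (nrow(bounds) != 2) stop("bounds must have a lower and an upper row")
  if (any(bounds[1, ] >= bounds[2, ])) stop("bounds must satisfy low < high")
  if (n_agents < 2) stop("n_agents must be at least 2")
  structure(list(n_agents = as.integer(n_agents),
                 n_iter = as.integer(n_iter),
                 lower = bounds[1, ], upper = bounds[2, ],
                 seed = as.integer(seed),
                 inertia = inertia, cognitive = cognitive, social = social),
            class = "optimizer_config")
}

check_fitness <- function(f, x) {
  v <- f(x)
  if (!is.finite(v)) {
    stop("non-finite fitness at point (", paste(signif(x, 4), collapse = ", "),
         ")")
  }
  v
}

init_positions <- function(config) {
  d <- length(config$lower)
  t(replicate(config$n_agents,
              config$lower + stats::runif(d) * (config$upper - config$lower)))
}

clamp_bounds <- function(X, config) {
  X <- pmax(X, matrix(config$lower, nrow(X), ncol(X), byrow = TRUE))
  pmin(X, matrix(config$upper, nrow(X), ncol(X), byrow = TRUE))
}

#' Particle swarm optimisation
#'
#' Classic inertia-weight PSO: each particle's velocity blends its previous
#' velocity with pulls toward its personal best and the global best,
#' `v <- w v + c1 r1 (pbest - x) + c2 r2 (gbest - x)`; positions are
#' clamped to the bounds.  Returns the incumbent best.
#'
#' @param fitness function of a position vector, returning a finite scalar
#'   to minimise.
#' @param config an [optimizer_config()].
#' @return list with `best_x`, `best_f`, and `history` (incumbent best
#'   fitness per iteration, non-increasing).
#' @export
pso_optimize <- function(fitness, config) {
  set.seed(config$seed)
  d <- length(config$lower)
  X <- init_positions(config)
  V <- matrix(0, config$n_agents, d)
  f <- apply(X, 1, function(x) check_fitness(fitness, x))
  pbest <- X; pbest_f <- f
  g <- which.min(f)
  gbest <- X[g, ]; gbest_f <- f[g]
  history <- numeric(config$n_iter)
  for (t in seq_len(config$n_iter)) {
    r1 <- matrix(stats::runif(config$n_agents * d), config$n_agents, d)
    r2 <- matrix(stats::runif(config$n_agents * d), config$n_agents, d)
    V <- config$inertia * V +
      config$cognitive * r1 * (pbest - X) +
      config$social * r2 * sweep(X, 2, gbest, function(x, g_) g_ - x)
    X <- clamp_bounds(X + V, config)
    f <- apply(X, 1, function(x) check_fitness(fitness, x))
    improved <- f < pbest_f
    pbest[improved, ] <- X[improved, , drop = FALSE]
    pbest_f[improved] <- f[improved]
    g <- which.min(pbest_f)
    if (pbest_f[g] < gbest_f) {
      gbest <- pbest[g, ]; gbest_f <- pbest_f[g]
    }
    history[t] <- gbest_f
  }
  list(best_x = gbest, best_f = gbest_f, history = history)
}

#' Pelican optimisation
#'
#' Two phases per agent and iteration.  Moving toward prey: a randomly
#' chosen other agent serves as prey; the agent steps toward it when the
#' prey is fitter (`x + r (prey - I x)`, `I` in `{1, 2}`) and away
#' otherwise.  Winging over the water surface: a local perturbation with
#' radius `0.2 (1 - t/T)` of the box extent.  Both phases accept a move
#' only when it improves the agent (greedy acceptance), so the incumbent
#' history is non-increasing.
#'
#' @inheritParams pso_optimize
#' @return list with `best_x`, `best_f`, `history`.
#' @export
poa_optimize <- function(fitness, config) {
  set.seed(config$seed)
  d <- length(config$lower)
  span <- config$upper - config$lower
  X <- init_positions(config)
  f <- apply(X, 1, function(x) check_fitness(fitness, x))
  history <- numeric(config$n_iter)
  for (t in seq_len(config$n_iter)) {
    for (i in seq_len(config$n_agents)) {
      # phase 1: toward (or away from) prey
      j <- sample(setdiff(seq_len(config$n_agents), i), 1L)
      I <- sample(1:2, 1L)
      r <- stats::runif(d)
      cand <- if (f[j] < f[i]) X[i, ] + r * (X[j, ] - I * X[i, ])
              else X[i, ] + r * (X[i, ] - X[j, ])
      cand <- pmin(pmax(cand, config$lower), config$upper)
      fc <- check_fitness(fitness, cand)
      if (fc < f[i]) { X[i, ] <- cand; f[i] <- fc }
      # phase 2: winging -- shrinking local search
      radius <- 0.2 * (1 - t / config$n_iter)
      cand <- X[i, ] + radius * (2 * stats::runif(d) - 1) * span
      cand <- pmin(pmax(cand, config$lower), config$upper)
      fc <- check_fitness(fitness, cand)
      if (fc < f[i]) { X[i, ] <- cand; f[i] <- fc }
    }
    history[t] <- min(f)
  }
  b <- which.min(f)
  list(best_x = X[b, ], best_f = f[b], history = cummin(history))
}

#' Hippopotamus optimisation
#'
#' Three phases per agent and iteration: a position update toward the
#' dominant (best) agent blended with a herd-mean term; a defensive move
#' relative to a simulated predator position with a distance-scaled
#' factor; and a bounded random evasion whose radius shrinks with the
#' iteration.  Every phase uses greedy acceptance.
#'
#' @inheritParams pso_optimize
#' @return list with `best_x`, `best_f`, `history`.
#' @export
ho_optimize <- function(fitness, config) {
  set.seed(config$seed)
  d <- length(config$lower)
  span <- config$upper - config$lower
  X <- init_positions(config)
  f <- apply(X, 1, function(x) check_fitness(fitness, x))
  history <- numeric(config$n_iter)
  for (t in seq_len(config$n_iter)) {
    dominant <- X[which.min(f), ]
    herd_mean <- colMeans(X)
    for (i in seq_len(config$n_agents)) {
      # phase 1: toward the dominant animal with a herd-mean pull
      I <- sample(1:2, 1L)
      r1 <- stats::runif(d); r2 <- stats::runif(d)
      cand <- X[i, ] + r1 * (dominant - I * X[i, ]) +
        r2 * (herd_mean - X[i, ])
      cand <- pmin(pmax(cand, config$lower), config$upper)
      fc <- check_fitness(fitness, cand)
      if (fc < f[i]) { X[i, ] <- cand; f[i] <- fc }
      # phase 2: defence against a simulated predator
      predator <- config$lower + stats::runif(d) * span
      dist_p <- sqrt(sum((X[i, ] - predator)^2))
      r3 <- stats::runif(d)
      cand <- X[i, ] + r3 * (X[i, ] - predator) / (1 + dist_p)
      cand <- pmin(pmax(cand, config$lower), config$upper)
      fc <- check_fitness(fitness, cand)
      if (fc < f[i]) { X[i, ] <- cand; f[i] <- fc }
      # phase 3: evasion -- bounded escape shrinking with iteration
      radius <- (1 - t / config$n_iter) * 0.1
      cand <- X[i, ] + radius * (2 * stats::runif(d) - 1) * span
      cand <- pmin(pmax(cand, config$lower), config$upper)
      fc <- check_fitness(fitness, cand)
      if (fc < f[i]) { X[i, ] <- cand; f[i] <- fc }
    }
    history[t] <- min(f)
  }
  b <- which.min(f)
  list(best_x = X[b, ], best_f = f[b], history = cummin(history))
}

#' Tune rough-network weights with a metaheuristic
#'
#' The decision vector concatenates every layer's centre weights with
#' every half-width; the fitness is the mean cross-entropy of the network
#' on the training set plus a penalty `lambda_w * mean(|half-width|)`
#' discouraging vacuous intervals.  The returned network is rebuilt from
#' the best vector with `w_low <= w_up` enforced by construction
#' (half-widths pass through an absolute value).
#'
#' @param net a `rough_network`.
#' @param train_set list with `X` (feature matrix) and `y` (class labels
#'   matching `net$classes`).
#' @param optimizer_kind `"pso"`, `"poa"`, or `"ho"`.
#' @param config an [optimizer_config()]; its `bounds` entry is ignored
#'   and replaced by a box around the current parameters.
#' @param lambda_w interval-width penalty (default 0.01).
#' @param bound_width half-extent of the search box around each current
#'   parameter value (default 2).
#' @return the tuned `rough_network`.
#' @export
tune_rough_weights <- function(net, train_set, optimizer_kind = c("pso", "poa", "ho"),
                               config = NULL, lambda_w = 0.01,
                               bound_width = 2) {
  optimizer_kind <- match.arg(optimizer_kind)
  if (is.null(train_set$X) || nrow(train_set$X) == 0) {
    stop("empty train_set")
  }
  X <- as.matrix(train_set$X)
  y_idx <- match(train_set$y, net$classes)
  if (anyNA(y_idx)) stop("labels outside the network's class set")
  centre0 <- net_get_params(net)
  half0 <- net_get_halfwidths(net)
  theta0 <- c(centre0, half0)
  nc <- length(centre0)
  fitness <- function(theta) {
    cand <- net_set_params(net, theta[seq_len(nc)],
                           abs(theta[nc + seq_len(length(half0))]))
    net_cross_entropy(cand, X, y_idx) +
      lambda_w * mean(abs(theta[nc + seq_len(length(half0))]))
  }
  if (is.null(config)) config <- optimizer_config(bounds = rbind(0, 1))
  if (config$n_iter == 0) return(net)
  lower <- theta0 - bound_width
  upper <- theta0 + bound_width
  config$lower <- lower; config$upper <- upper
  opt <- switch(optimizer_kind,
                pso = pso_optimize(fitness, config),
                poa = poa_optimize(fitness, config),
                ho = ho_optimize(fitness, config))
  best <- if (opt$best_f <= fitness(theta0)) opt$best_x else theta0
  net_set_params(net, best[seq_len(nc)], abs(best[nc + seq_len(length(half0))]))
}
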