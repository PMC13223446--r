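test_that("conjugate gradients reproduces direct solves", {
  # trivial: zero right-hand side from a zero start
  r0 <- cg_solve(diag(3), rep(0, 3))
  expect_equal(r0$x, rep(0, 3))
  expect_equal(r0$iterations, 0)

  A <- matrix(c(4, 1, 1, 3), 2)
  s <- cg_solve(A, c(1, 2))
  expect_lte(s$iterations, 2)
  expect_lt(max(abs(s$x - solve(A, c(1, 2)))), 1e-10)

  expect_error(cg_solve(matrix(c(1, 2, 3, 4), 2), c(1, 1)), "symmetric")
  expect_error(cg_solve(diag(c(1, -1)), c(1, 1)),
               "non-negative definite")
})

test_that("CG terminates within n iterations on random SPD systems", {
  for (seed in 1:10) {
    sys <- random_spd_system(seed)
    s <- cg_solve(sys$A, sys$b, tol = 1e-10, max_iter = 5 * sys$n)
    expect_lte(s$iterations, sys$n)
    expect_lt(sqrt(sum((sys$b - sys$A %*% s$x)^2)), 1e-10)
  }
})

test_that("CG maintains the residual identity and A-conjugate directions", {
  set.seed(5)
  n <- 12
  M <- matrix(rnorm(n * n), n)
  A <- crossprod(M) + diag(n)
  b <- rnorm(n)
  # replay the recurrence, checking r_k = b - A x_k each step
  x <- numeric(n); r <- b; p <- r; rs <- sum(r^2)
  dirs <- list()
  for (k in 1:n) {
    if (sqrt(rs) <= 1e-10) break
    dirs[[k]] <- p
    Ap <- as.vector(A %*% p)
    alpha <- rs / sum(p * Ap)
    x <- x + alpha * p
    r <- r - alpha * Ap
    expect_lt(max(abs(r - (b - as.vector(A %*% x)))), 1e-8)
    rs_new <- sum(r^2)
    p <- r + (rs_new / rs) * p
    rs <- rs_new
  }
  # pairwise A-conjugacy of the stored directions
  for (i in seq_along(dirs)) {
    for (j in seq_len(i - 1)) {
      denom <- sqrt(sum(dirs[[i]] * (A %*% dirs[[i]]))) *
        sqrt(sum(dirs[[j]] * (A %*% dirs[[j]])))
      expect_lt(abs(sum(dirs[[i]] * (A %*% dirs[[j]]))) / denom, 1e-6)
    }
  }
  # and the package solver agrees with the replay
  s <- cg_solve(A, b, tol = 1e-10)
  expect_lt(max(abs(s$x - x)), 1e-8)
})

test_that("LM recovers exact linear data and runs its damping schedule", {
  xs <- 0:3; ys <- 2 * xs + 1
  fit <- lm_fit(function(beta) ys - (beta[1] * xs + beta[2]),
                function(beta) cbind(xs, 1),
                c(0, 0))
  expect_lt(max(abs(fit$beta - c(2, 1))), 1e-8)
  # normal-equations oracle for the same model
  Xd <- cbind(xs, 1)
  expect_lt(max(abs(fit$beta - solve(crossprod(Xd), crossprod(Xd, ys)))),
            1e-8)
  expect_true(all(diff(fit$history) <= 0))

  # zero residual at the start: unchanged
  z <- lm_fit(function(beta) numeric(4), function(beta) cbind(xs, 1),
              c(5, 5))
  expect_equal(z$beta, c(5, 5))

  expect_error(lm_fit(identity, identity, 1, lambda0 = 0), "positive")
  expect_error(lm_fit(identity, identity, 1, factor = 1), "exceed")
})

test_that("the damping factor moves by exactly the factor on accept/reject", {
  # one accepted step from a quadratic residual: lambda drops by factor
  xs <- 0:3; ys <- 2 * xs + 1
  fit <- lm_fit(function(beta) ys - (beta[1] * xs + beta[2]),
                function(beta) cbind(xs, 1),
                c(0, 0), lambda0 = 1e-3, factor = 10, max_iter = 1)
  expect_equal(fit$lambda, 1e-4)
  # a residual that can never improve: every proposal rejected, lambda
  # escalates by the factor each time until the trainer gives up
  stuck <- lm_fit(function(beta) 1, function(beta) matrix(1, 1, 1),
                  0, lambda0 = 1, factor = 10, max_iter = 5)
  expect_equal(stuck$beta, 0)
})

test_that("LM agrees with an independent damped-least-squares solver", {
  # nonlinear model y = a exp(b x): cross-check the full damped iteration
  # against minpack.lm on the same residuals
  set.seed(4)
  xs <- seq(0, 2, length.out = 15)
  ys <- 1.7 * exp(0.8 * xs) + rnorm(15, 0, 0.02)
  resid_fn <- function(beta) ys - beta[1] * exp(beta[2] * xs)
  jac_fn <- function(beta) cbind(exp(beta[2] * xs),
                                 beta[1] * xs * exp(beta[2] * xs))
  fit <- lm_fit(resid_fn, jac_fn, c(1, 0.1))
  ref <- minpack.lm::nls.lm(c(1, 0.1), fn = resid_fn)
  expect_lt(max(abs(fit$beta - ref$par)), 1e-6)
})

test_that("LM with vanishing damping matches ordinary least squares", {
  set.seed(8)
  xs <- seq(0, 1, length.out = 12)
  ys <- 3 * xs - 0.5 + rnorm(12, 0, 0.05)
  fit <- lm_fit(function(beta) ys - (beta[1] * xs + beta[2]),
                function(beta) cbind(xs, 1),
                c(0, 0), lambda0 = 1e-8)
  ols <- stats::lm.fit(cbind(xs, 1), ys)$coefficients
  expect_lt(max(abs(fit$beta - ols)), 1e-6)
})

test_that("reduced-memory LM reaches the closed-form quadratic minimum", {
  set.seed(3)
  M <- matrix(rnorm(100), 10)
  A <- crossprod(M) + diag(10)
  b <- rnorm(10)
  loss <- function(x) 0.5 * sum(x * (A %*% x)) - sum(b * x)
  grad <- function(x) as.vector(A %*% x) - b
  xstar <- solve(A, b)
  fit <- rmlm_fit(loss, grad, rep(0, 10), m = 5)
  expect_lt(loss(fit$beta) - loss(xstar), 1e-8)
  expect_true(all(diff(fit$history) <= 0))
  expect_lte(fit$memory_size, 5)

  # gradient zero at the start: no iterations
  z <- rmlm_fit(loss, grad, xstar, m = 5)
  expect_equal(z$iterations, 0)
  expect_error(rmlm_fit(function(x) NaN, grad, rep(0, 10)), "non-finite")
  expect_error(rmlm_fit(loss, grad, rep(0, 10), m = 0), "at least 1")
})

test_that("full-memory RMLM tracks a quasi-Newton reference on quadratics", {
  set.seed(11)
  M <- matrix(rnorm(36), 6)
  A <- crossprod(M) + diag(6)
  b <- rnorm(6)
  loss <- function(x) 0.5 * sum(x * (A %*% x)) - sum(b * x)
  grad <- function(x) as.vector(A %*% x) - b
  fit <- rmlm_fit(loss, grad, rep(0, 6), m = 10)
  ref <- stats::optim(rep(0, 6), loss, grad, method = "BFGS",
                      control = list(reltol = 1e-14))
  expect_lt(abs(loss(fit$beta) - ref$value), 1e-6)
})

test_that("stage-classifier training descends and fits separable clusters", {
  set.seed(1)
  centres <- list(c(0.2, 0.2), c(0.5, 0.8), c(0.8, 0.3))
  X <- do.call(rbind, lapply(centres, function(ctr) {
    cbind(rnorm(30, ctr[1], 0.05), rnorm(30, ctr[2], 0.05))
  }))
  y <- rep(stage_levels(), each = 30)
  ds <- decision_system(data.frame(f1 = round(X[, 1] * 6),
                                   f2 = round(X[, 2] * 6)), y)
  net <- init_rough_weights(ds, c("f1", "f2"), c(2, 8, 3), seed = 1,
                            classes = stage_levels())

  expect_error(train_stage_classifier(net, list(X = X, y = rep("nope", 90))),
               "outside the class set")
  unchanged <- train_stage_classifier(net, list(X = X, y = y), "rmlm",
                                      max_iter = 0)
  expect_identical(unchanged$net, net)

  for (kind in c("rmlm", "lm", "cg")) {
    fit <- train_stage_classifier(net, list(X = X, y = y), kind,
                                  max_iter = if (kind == "lm") 25 else 100)
    expect_true(all(diff(fit$history) <= 1e-10))
    if (kind == "rmlm") {
      preds <- vapply(seq_len(nrow(X)),
                      function(i) predict_stage(fit$net, X[i, ]), "")
      expect_gte(mean(preds == y), 0.95)
    }
  }
})
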