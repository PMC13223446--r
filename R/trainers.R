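# Training functions: conjugate gradients for symmetric non-negative-
# definite linear systems, damped Levenberg-Marquardt for nonlinear least
# squares, and a reduced-memory variant built on the limited-memory
# two-loop recursion, plus the stage-classifier training loop that wires
# them to the rough network's midpoint weights.

#' Conjugate-gradient linear solver
#'
#' Solves `A x = b` for symmetric non-negative-definite `A` by the
#' classical recurrence: residual `r0 = b - A x0`, first direction
#' `p0 = r0`, then per iteration the step `alpha = (r'r)/(p'Ap)`, solution
#' and residual updates, and the new direction `p <- r + beta p` with
#' `beta = (r_new'r_new)/(r'r)`, until the residual norm drops to `tol` or
#' `max_iter` is reached.  In exact arithmetic the method terminates in at
#' most `n` iterations.
#'
#' @param A symmetric matrix (checked to `1e-10` relative asymmetry).
#' @param b right-hand side vector.
#' @param x0 starting point (default zero).
#' @param tol residual-norm stopping tolerance (default `1e-10`).
#' @param max_iter iteration cap (default `length(b)`).
#' @return list with `x` and `iterations`.
#' @export
cg_solve <- function(A, b, x0 = NULL, tol = 1e-10, max_iter = length(b)) {
  A <- as.matrix(A)
  if (tol <= 0) stop("tol must be positive")
  asym <- max(abs(A - t(A)))
  if (asym > 1e-10 * max(1, max(abs(A)))) stop("A is not symmetric")
  if (is.null(x0)) x0 <- numeric(length(b))
  x <- x0
  r <- b - as.vector(A %*% x)
  p <- r
  rs <- sum(r^2)
  k <- 0L
  while (sqrt(rs) > tol && k < max_iter) {
    Ap <- as.vector(A %*% p)
    pAp <- sum(p * Ap)
    if (pAp <= 0) {
      stop("A is not non-negative definite along the search direction")
    }
    alpha <- rs / pAp
    x <- x + alpha * p
    r <- r - alpha * Ap
    rs_new <- sum(r^2)
    p <- r + (rs_new / rs) * p
    rs <- rs_new
    k <- k + 1L
  }
  list(x = x, iterations = k)
}

#' Levenberg-Marquardt nonlinear least squares
#'
#' Minimises `sum(residual_fn(beta)^2)`.  Each step solves the damped
#' normal equations `(J'J + lambda I) delta = J' r` and proposes
#' `beta + delta`; a step that reduces the error is accepted and `lambda`
#' is divided by `factor` (larger, Gauss-Newton-like steps), a step that
#' increases it is rejected and `lambda` is multiplied by `factor`
#' (gradient-descent-like retreat) before retrying.
#'
#' @param residual_fn function of `beta` returning the residual vector
#'   (data minus model).
#' @param jacobian_fn function of `beta` returning the Jacobian of the
#'   MODEL with respect to `beta` (n_residuals x n_params), so that the
#'   linearised residual is `r - J delta`.
#' @param beta0 starting parameter vector.
#' @param lambda0 initial damping factor (> 0, default `1e-3`).
#' @param factor damping multiplier (> 1, default 10).
#' @param tol stopping tolerance on the step norm and gradient norm
#'   (default `1e-8`).
#' @param max_iter accepted-step cap (default 500).
#' @return list with `beta`, `history` (sum of squared residuals after
#'   each accepted step, starting with the initial error), `lambda`,
#'   `iterations`.
#' @export
lm_fit <- function(residual_fn, jacobian_fn, beta0, lambda0 = 1e-3,
                   factor = 10, tol = 1e-8, max_iter = 500L) {
  if (lambda0 <= 0) stop("lambda0 must be positive")
  if (factor <= 1) stop("factor must exceed 1")
  beta <- beta0
  lambda <- lambda0
  r <- residual_fn(beta)
  err <- sum(r^2)
  history <- err
  it <- 0L
  while (it < max_iter) {
    J <- jacobian_fn(beta)
    g <- as.vector(crossprod(J, r))
    if (sqrt(sum(g^2)) <= tol) break
    accepted <- FALSE
    escal <- 0L
    while (!accepted) {
      H <- crossprod(J) + diag(lambda, length(beta))
      delta <- tryCatch(solve(H, g), error = function(e) NULL)
      if (is.null(delta)) {
        escal <- escal + 1L
        if (escal > 50L) stop("damped normal equations singular after 50 escalations")
        lambda <- lambda * factor
        next
      }
      cand <- beta + delta
      rc <- residual_fn(cand)
      errc <- sum(rc^2)
      if (errc < err) {
        beta <- cand; r <- rc; err <- errc
        lambda <- lambda / factor
        accepted <- TRUE
      } else {
        escal <- escal + 1L
        if (escal > 50L) {
          # no descent at any damping: treat as converged
          return(list(beta = beta, history = history, lambda = lambda,
                      iterations = it))
        }
        lambda <- lambda * factor
      }
    }
    it <- it + 1L
    history <- c(history, err)
    if (sqrt(sum(delta^2)) <= tol) break
  }
  list(beta = beta, history = history, lambda = lambda, iterations = it)
}

# limited-memory two-loop recursion: returns H*g approximating
# (inverse Hessian) %*% g from stored (s, y) pairs
two_loop_direction <- function(g, mem) {
  q <- g
  m <- length(mem$s)
  if (m == 0) return(g)
  alpha <- numeric(m)
  rho <- vapply(seq_len(m), function(i) 1 / sum(mem$y[[i]] * mem$s[[i]]),
                numeric(1))
  for (i in rev(seq_len(m))) {
    alpha[i] <- rho[i] * sum(mem$s[[i]] * q)
    q <- q - alpha[i] * mem$y[[i]]
  }
  s_last <- mem$s[[m]]; y_last <- mem$y[[m]]
  q <- q * sum(s_last * y_last) / sum(y_last * y_last)
  for (i in seq_len(m)) {
    beta_i <- rho[i] * sum(mem$y[[i]] * q)
    q <- q + (alpha[i] - beta_i) * mem$s[[i]]
  }
  q
}

#' Reduced-memory Levenberg-Marquardt (limited-memory quasi-Newton)
#'
#' Memory-efficient training for problems where the full Jacobian or
#' Hessian is too large to hold: the search direction comes from the
#' limited-memory two-loop recursion over at most `m` stored
#' (parameter-change, gradient-change) pairs, the step length from
#' backtracking under the Armijo sufficient-decrease rule, and the memory
#' is renewed after every accepted step (oldest pair evicted beyond `m`).
#'
#' @param loss_fn scalar loss function of `beta`.
#' @param grad_fn gradient function of `beta`.
#' @param beta0 starting parameter vector.
#' @param m memory capacity (>= 1, default 5).
#' @param tol stopping tolerance on the gradient norm and step norm
#'   (default `1e-8`).
#' @param max_iter iteration cap (default 500).
#' @param c_armijo sufficient-decrease constant (default `1e-4`).
#' @return list with `beta`, `history` (loss after each accepted step,
#'   starting with the initial loss), `iterations`, `memory_size`.
#' @export
rmlm_fit <- function(loss_fn, grad_fn, beta0, m = 5L, tol = 1e-8,
                     max_iter = 500L, c_armijo = 1e-4) {
  if (m < 1) stop("memory capacity m must be at least 1")
  beta <- beta0
  loss <- loss_fn(beta)
  g <- grad_fn(beta)
  if (!is.finite(loss) || any(!is.finite(g))) {
    stop("non-finite loss or gradient at the starting point")
  }
  history <- loss
  mem <- list(s = list(), y = list())
  it <- 0L
  while (it < max_iter && sqrt(sum(g^2)) > tol) {
    dir <- -two_loop_direction(g, mem)
    slope <- sum(g * dir)
    if (slope >= 0) { dir <- -g; slope <- -sum(g^2) }
    step <- 1
    accepted <- FALSE
    for (bt in 1:50) {
      cand <- beta + step * dir
      lc <- loss_fn(cand)
      if (!is.finite(lc)) { step <- step / 2; next }
      if (lc <= loss + c_armijo * step * slope) { accepted <- TRUE; break }
      step <- step / 2
    }
    if (!accepted) break
    g_new <- grad_fn(cand)
    if (any(!is.finite(g_new))) stop("non-finite gradient during optimisation")
    s_k <- cand - beta
    y_k <- g_new - g
    if (sum(s_k * y_k) > 1e-12) {       # curvature condition
      mem$s <- c(mem$s, list(s_k))
      mem$y <- c(mem$y, list(y_k))
      if (length(mem$s) > m) {          # evict oldest
        mem$s <- mem$s[-1]; mem$y <- mem$y[-1]
      }
    }
    beta <- cand; loss <- lc; g <- g_new
    it <- it + 1L
    history <- c(history, loss)
    if (sqrt(sum(s_k^2)) <= tol) break
  }
  list(beta = beta, history = history, iterations = it,
       memory_size = length(mem$s))
}

# ---- stage-classifier wiring -------------------------------------------

# Loss and gradient of the rough network with respect to its CENTRE
# parameters theta, half-widths frozen at the network's current values.
# The forward pass is the genuine rough one (lower and upper sigmoid
# branches averaged between layers), so training optimises exactly the
# function the network evaluates; the softmax cross-entropy sits on top of
# the final layer's midpoints.
midpoint_loss_grad <- function(net, theta, X, y_idx) {
  sizes <- net$layer_sizes
  nl <- length(sizes) - 1L
  Ws <- vector("list", nl); bs <- vector("list", nl)
  Hw <- vector("list", nl); hb <- vector("list", nl)
  off <- 0L
  for (l in seq_len(nl)) {
    ly <- net$layers[[l]]
    nw <- sizes[l + 1L] * sizes[l]
    Ws[[l]] <- matrix(theta[off + seq_len(nw)], sizes[l + 1L], sizes[l])
    Hw[[l]] <- (ly$w_up - ly$w_low) / 2
    off <- off + nw
    bs[[l]] <- theta[off + seq_len(sizes[l + 1L])]
    hb[[l]] <- (ly$b_up - ly$b_low) / 2
    off <- off + sizes[l + 1L]
  }
  n <- nrow(X)
  A <- list(t(X))                       # activations, d x n
  Sl <- vector("list", nl); Su <- vector("list", nl)
  for (l in seq_len(nl)) {
    if (l < nl) {
      Zl <- (Ws[[l]] - Hw[[l]]) %*% A[[l]] + (bs[[l]] - hb[[l]])
      Zu <- (Ws[[l]] + Hw[[l]]) %*% A[[l]] + (bs[[l]] + hb[[l]])
      Sl[[l]] <- sigmoid(Zl); Su[[l]] <- sigmoid(Zu)
      A[[l + 1L]] <- (Sl[[l]] + Su[[l]]) / 2
    } else {
      # output layer: midpoint of the pre-activation interval = centre
      # response; unbounded logits under the softmax
      A[[l + 1L]] <- Ws[[l]] %*% A[[l]] + bs[[l]]
    }
  }
  P <- t(row_softmax(t(A[[nl + 1L]])))  # k x n
  eps <- 1e-12
  losses <- -log(pmax(P[cbind(y_idx, seq_len(n))], eps))
  Y <- matrix(0, nrow(P), n)
  Y[cbind(y_idx, seq_len(n))] <- 1
  dA <- P - Y                           # dL/d(logits)
  grads <- vector("list", nl)
  for (l in rev(seq_len(nl))) {
    if (l < nl) {
      dZl <- dA * Sl[[l]] * (1 - Sl[[l]]) / 2
      dZu <- dA * Su[[l]] * (1 - Su[[l]]) / 2
      dZ <- dZl + dZu
      dA_prev <- t(Ws[[l]] - Hw[[l]]) %*% dZl + t(Ws[[l]] + Hw[[l]]) %*% dZu
    } else {
      dZ <- dA
      dA_prev <- t(Ws[[l]]) %*% dZ
    }
    grads[[l]] <- list(W = dZ %*% t(A[[l]]) / n, b = rowMeans(dZ))
    if (l > 1L) dA <- dA_prev
  }
  grad <- unlist(lapply(seq_len(nl), function(l) {
    c(grads[[l]]$W, grads[[l]]$b)
  }))
  list(loss = mean(losses), grad = grad, losses = losses)
}

# numerical per-sample jacobian of sqrt(per-sample CE) residuals; small
# nets only (used by the LM trainer)
ce_residual_jacobian <- function(net, theta, X, y_idx, h = 1e-6) {
  r0 <- sqrt(pmax(midpoint_loss_grad(net, theta, X, y_idx)$losses, 1e-12))
  J <- matrix(0, length(r0), length(theta))
  for (j in seq_along(theta)) {
    tp <- theta; tp[j] <- tp[j] + h
    rp <- sqrt(pmax(midpoint_loss_grad(net, tp, X, y_idx)$losses, 1e-12))
    J[, j] <- (rp - r0) / h
  }
  J
}

#' Train the stage classifier
#'
#' Optimises the midpoint weights of a rough network against softmax
#' cross-entropy, with the interval half-widths frozen.  `"lm"` runs
#' Levenberg-Marquardt on the per-sample sqrt-cross-entropy residuals;
#' `"rmlm"` runs the reduced-memory quasi-Newton trainer on the mean
#' cross-entropy; `"cg"` performs Gauss-Newton steps on the FINAL layer
#' only (earlier layers frozen), each step solved by [cg_solve()] on the
#' damped normal equations -- the conjugate-gradient method is a linear
#' solver, so this is the natural way for it to train a nonlinear
#' classifier.
#'
#' @param net a `rough_network`.
#' @param train_set list with `X` (feature matrix) and `y` (labels in
#'   `net$classes`).
#' @param trainer_kind `"cg"`, `"lm"`, or `"rmlm"`.
#' @param max_iter iteration cap (default 100).
#' @param tol convergence tolerance (default `1e-8`).
#' @return list with the trained `net` and the loss `history` over
#'   accepted steps (non-increasing).
#' @export
train_stage_classifier <- function(net, train_set,
                                   trainer_kind = c("rmlm", "lm", "cg"),
                                   max_iter = 100L, tol = 1e-8) {
  trainer_kind <- match.arg(trainer_kind)
  X <- as.matrix(train_set$X)
  y_idx <- match(train_set$y, net$classes)
  if (anyNA(y_idx)) {
    stop("labels outside the class set: ",
         paste(unique(train_set$y[is.na(y_idx)]), collapse = ", "))
  }
  half <- net_get_halfwidths(net)
  theta0 <- net_get_params(net)
  if (max_iter == 0) return(list(net = net, history = numeric(0)))

  if (trainer_kind == "rmlm") {
    fit <- rmlm_fit(
      loss_fn = function(th) midpoint_loss_grad(net, th, X, y_idx)$loss,
      grad_fn = function(th) midpoint_loss_grad(net, th, X, y_idx)$grad,
      beta0 = theta0, m = 5L, tol = tol, max_iter = max_iter)
    theta <- fit$beta; history <- fit$history
  } else if (trainer_kind == "lm") {
    fit <- lm_fit(
      residual_fn = function(th) {
        sqrt(pmax(midpoint_loss_grad(net, th, X, y_idx)$losses, 1e-12))
      },
      jacobian_fn = function(th) -ce_residual_jacobian(net, th, X, y_idx),
      beta0 = theta0, tol = tol, max_iter = max_iter)
    theta <- fit$beta; history <- fit$history / nrow(X)
  } else {
    # cg: Gauss-Newton on the output layer, earlier layers frozen
    sizes <- net$layer_sizes
    nl <- length(sizes) - 1L
    n_out <- sizes[nl + 1L] * sizes[nl] + sizes[nl + 1L]
    head_idx <- seq(length(theta0) - n_out + 1L, length(theta0))
    theta <- theta0
    history <- midpoint_loss_grad(net, theta, X, y_idx)$loss
    for (k in seq_len(max_iter)) {
      J <- ce_residual_jacobian(net, theta, X, y_idx)[, head_idx, drop = FALSE]
      r <- sqrt(pmax(midpoint_loss_grad(net, theta, X, y_idx)$losses, 1e-12))
      g <- as.vector(crossprod(J, r))
      if (sqrt(sum(g^2)) <= tol) break
      H <- crossprod(J) + diag(1e-6, length(head_idx))
      delta <- cg_solve(H, -g, tol = 1e-10, max_iter = 5L * length(g))$x
      cand <- theta
      cand[head_idx] <- cand[head_idx] + delta
      new_loss <- midpoint_loss_grad(net, cand, X, y_idx)$loss
      # halve the step until it descends
      step_ok <- new_loss < history[length(history)]
      step <- 1
      while (!step_ok && step > 1e-6) {
        step <- step / 2
        cand[head_idx] <- theta[head_idx] + step * delta
        new_loss <- midpoint_loss_grad(net, cand, X, y_idx)$loss
        step_ok <- new_loss < history[length(history)]
      }
      if (!step_ok) break
      theta <- cand
      history <- c(history, new_loss)
      if (sqrt(sum((step * delta)^2)) <= tol) break
    }
  }
  list(net = net_set_params(net, theta, half), history = history)
}
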