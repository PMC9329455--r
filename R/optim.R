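# Full-batch trainers. Both work on a flat parameter vector through
# fn(par) / gr(par) closures, so they can be exercised on any smooth
# objective, not just the network loss. One "iteration" here is one
# epoch of training (full-batch update attempt).

#' Scaled conjugate gradient minimization
#'
#' Moller's scaled conjugate gradient: conjugate-direction updates with a
#' scalar second-order estimate obtained by a finite perturbation of size
#' `sigma` along the search direction, and Levenberg-style damping
#' `lambda` raised on unsuccessful steps and lowered on very successful
#' ones. The direction restarts to steepest descent every
#' `length(par)` iterations.
#'
#' @param par Numeric start vector.
#' @param fn Objective function of `par`.
#' @param gr Gradient function of `par`.
#' @param max_iter Iteration cap.
#' @param grad_tol Stop when the gradient norm falls to or below this
#'   (checked before each iteration, so a stationary start returns
#'   immediately with `par` unchanged).
#' @param sigma Perturbation scale for the second-order estimate.
#' @param lambda0 Initial damping.
#' @param callback Optional `function(iter, par, value, grad_norm)`
#'   called after every iteration; returning `TRUE` stops training
#'   (stop reason `"callback"`).
#' @return A list: `par`, `value`, `iterations`, and `stop` (one of
#'   `"grad_tol"`, `"max_iter"`, `"callback"`).
#' @references Moller, M. F. (1993) A scaled conjugate gradient
#'   algorithm for fast supervised learning. Neural Networks 6, 525-533.
#' @export
scg_optimize <- function(par, fn, gr, max_iter = 2000L, grad_tol = 1e-6,
                         sigma = 5e-5, lambda0 = 5e-7, callback = NULL) {
  P <- length(par)
  w <- par
  E <- fn(w)
  r <- -gr(w)
  p <- r
  lambda <- lambda0
  lambda_bar <- 0
  success <- TRUE
  delta <- 0
  iter <- 0L
  stop_reason <- "max_iter"

  repeat {
    gnorm <- sqrt(sum(r^2))
    if (gnorm <= grad_tol) { stop_reason <- "grad_tol"; break }
    if (iter >= max_iter) { stop_reason <- "max_iter"; break }
    iter <- iter + 1L

    pnorm2 <- sum(p^2)
    if (success) {
      # second-order information along p by finite perturbation
      sigma_k <- sigma / sqrt(pnorm2)
      s <- (gr(w + sigma_k * p) - (-r)) / sigma_k
      delta <- sum(p * s)
    }
    delta <- delta + (lambda - lambda_bar) * pnorm2
    if (delta <= 0) { # make the Hessian estimate positive definite
      lambda_bar <- 2 * (lambda - delta / pnorm2)
      delta <- -delta + lambda * pnorm2
      lambda <- lambda_bar
    }
    mu <- sum(p * r)
    alpha <- mu / delta
    E_new <- fn(w + alpha * p)
    Delta <- 2 * delta * (E - E_new) / mu^2

    if (is.finite(Delta) && Delta >= 0) { # successful step
      w <- w + alpha * p
      E <- E_new
      if (!is.finite(E)) {
        stop_domain(sprintf("non-finite loss encountered at epoch %d", iter))
      }
      r_new <- -gr(w)
      lambda_bar <- 0
      success <- TRUE
      if (iter %% P == 0L) {
        p <- r_new # periodic restart to steepest descent
      } else {
        beta <- (sum(r_new^2) - sum(r_new * r)) / mu
        p <- r_new + beta * p
      }
      r <- r_new
      if (Delta >= 0.75) lambda <- lambda / 4
    } else {
      lambda_bar <- lambda
      success <- FALSE
    }
    if (!is.finite(Delta) || Delta < 0.25) {
      lambda <- lambda + delta * (1 - Delta) / pnorm2
      if (!is.finite(lambda)) lambda <- lambda0
    }

    if (!is.null(callback) &&
        isTRUE(callback(iter, w, E, sqrt(sum(r^2))))) {
      stop_reason <- "callback"
      break
    }
  }
  list(par = w, value = E, iterations = iter, stop = stop_reason)
}

#' One Rprop update
#'
#' The sign-based resilient-backpropagation rule (iRprop- variant):
#' each parameter keeps its own step size, grown by `eta_plus` (capped
#' at `delta_max`) when the gradient keeps its sign, shrunk by
#' `eta_minus` with the pending update skipped when the sign flips.
#' Gradient magnitude never enters the update.
#'
#' @param par Current parameter vector.
#' @param grad Gradient at `par`.
#' @param state A list with `step` (per-parameter step sizes) and
#'   `grad_prev`; create the initial state with `rprop_state()`.
#' @param eta_plus,eta_minus Step growth/shrink factors
#'   (`eta_minus < 1 < eta_plus`).
#' @param delta_max Step-size cap.
#' @return A list with the updated `par` and `state`.
#' @examples
#' # minimizing w^2 from w = 1 with defaults: w -> 0.93 -> 0.846
#' st <- rprop_state(1)
#' s1 <- rprop_step(1, 2 * 1, st)
#' s2 <- rprop_step(s1$par, 2 * s1$par, s1$state)
#' c(s1$par, s2$par)
#' @references Riedmiller, M. and Braun, H. (1993) A direct adaptive
#'   method for faster backpropagation learning: the RPROP algorithm.
#'   IEEE ICNN, 586-591.
#' @export
rprop_step <- function(par, grad, state, eta_plus = 1.2, eta_minus = 0.5,
                       delta_max = 50) {
  if (!(eta_minus < 1 && 1 < eta_plus)) {
    stop_domain("need eta_minus < 1 < eta_plus")
  }
  s <- grad * state$grad_prev
  state$step <- ifelse(s > 0, pmin(state$step * eta_plus, delta_max),
                       ifelse(s < 0, state$step * eta_minus, state$step))
  grad <- ifelse(s < 0, 0, grad) # iRprop-: skip update after a sign flip
  par <- par - sign(grad) * state$step
  state$grad_prev <- grad
  list(par = par, state = state)
}

#' @rdname rprop_step
#' @param n Number of parameters.
#' @param delta0 Initial per-parameter step size.
#' @export
rprop_state <- function(n, delta0 = 0.07) {
  list(step = rep(delta0, n), grad_prev = numeric(n))
}

#' Full-batch Rprop minimization
#'
#' Iterates [rprop_step()] until the gradient norm, the iteration cap,
#' or the callback stops it. Same interface as [scg_optimize()].
#'
#' @inheritParams scg_optimize
#' @param delta0 Initial step size for every parameter.
#' @param eta_plus,eta_minus,delta_max See [rprop_step()].
#' @return A list: `par`, `value`, `iterations`, `stop`.
#' @export
rprop_optimize <- function(par, fn, gr, max_iter = 2000L, grad_tol = 1e-6,
                           eta_plus = 1.2, eta_minus = 0.5, delta0 = 0.07,
                           delta_max = 50, callback = NULL) {
  state <- rprop_state(length(par), delta0)
  iter <- 0L
  stop_reason <- "max_iter"
  repeat {
    g <- gr(par)
    gnorm <- sqrt(sum(g^2))
    if (gnorm <= grad_tol) { stop_reason <- "grad_tol"; break }
    if (iter >= max_iter) { stop_reason <- "max_iter"; break }
    iter <- iter + 1L
    upd <- rprop_step(par, g, state, eta_plus, eta_minus, delta_max)
    par <- upd$par
    state <- upd$state
    value <- fn(par)
    if (!is.finite(value)) {
      stop_domain(sprintf("non-finite loss encountered at epoch %d", iter))
    }
    if (!is.null(callback) && isTRUE(callback(iter, par, value, gnorm))) {
      stop_reason <- "callback"
      break
    }
  }
  list(par = par, value = fn(par), iterations = iter, stop = stop_reason)
}
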