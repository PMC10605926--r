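# Centralized sparse-SVM oracle.
#
# The constrained soft-margin program (slack variables zeta_i, margin
# constraints l_i(phi_i' theta + theta0) >= 1 - zeta_i) is a convex QP. No
# QP solver ships with this environment, so the oracle solves the program
# exactly through its Lagrange dual, which for psi > 0 is smooth and concave:
#
#   max_{alpha in [0,1]^n, l' alpha = 0}
#       sum(alpha) - ||soft(Phi' (alpha * l), rho)||^2 / (2 psi)
#
# (the theta-minimisation has the closed form theta(v) = soft(v, rho) / psi,
# v = Phi'(alpha * l); the bias multiplier yields the equality constraint).
# The dual is maximised by accelerated projected gradient (FISTA with
# adaptive restart); the primal classifier is recovered from theta(alpha)
# plus an exact 1-D scan for the bias, and optimality is certified by the
# duality gap rather than assumed. This route shares no code path with the
# decentralised cPDS iteration, so the two can check each other.

spectral_norm <- function(M, iters = 100L, tol = 1e-10) {
  if (length(M) == 0L) return(0)
  v <- rep(1 / sqrt(ncol(M)), ncol(M))
  s_old <- 0
  for (k in seq_len(iters)) {
    w <- drop(crossprod(M, M %*% v))
    s <- sqrt(sum(w^2))
    if (s == 0) return(0)
    v <- w / s
    if (abs(sqrt(s) - s_old) < tol * max(1, sqrt(s))) break
    s_old <- sqrt(s)
  }
  sqrt(s)
}

# projection onto {alpha in [0,1]^n : l' alpha = 0} by bisection on the
# multiplier of the equality constraint
project_dual <- function(z, l) {
  s_of <- function(lam) sum(l * pmin(pmax(z - lam * l, 0), 1))
  lo <- -(max(abs(z)) + 2)
  hi <- max(abs(z)) + 2
  for (k in seq_len(90L)) {
    mid <- (lo + hi) / 2
    if (s_of(mid) > 0) lo <- mid else hi <- mid
  }
  lam <- (lo + hi) / 2
  pmin(pmax(z - lam * l, 0), 1)
}

# exact minimiser over the bias of sum_i max(0, 1 - l_i (m_i + b)): the
# objective is convex piecewise linear with kinks at b_i = l_i - m_i and
# nonnegative outer slopes, so the minimum is attained at a kink
optimal_bias <- function(margins_wo_bias, l) {
  b_cand <- unique(l - margins_wo_bias)
  f <- vapply(b_cand, function(b) sum(pmax(0, 1 - l * (margins_wo_bias + b))), 0)
  b_cand[which.min(f)]
}

#' Exact centralized sparse-SVM solver (QP oracle)
#'
#' Solves the centralized objective `sum(hinge) + 0.5*psi*||theta||^2 +
#' rho*||theta||_1` to certified precision via its smooth concave dual (see
#' the source header), and is used throughout the package as the reference
#' the federated solvers are measured against. Requires `psi > 0` (the dual
#' construction needs strong convexity in `theta`).
#'
#' @param data an [svm_dataset()].
#' @param hp an [hyperparams()] with `psi > 0`.
#' @param tol stop when the duality gap is below `tol * max(1, |objective|)`.
#' @param max_iter iteration cap for the accelerated dual ascent.
#' @return an object of class `oracle_solution`: list with `classifier`,
#'   `objective_value`, `solver_status` (`"optimal"`), `duality_gap`,
#'   `dual_objective` and `iterations`.
#' @export
solve_centralized_qp <- function(data, hp, tol = 1e-9, max_iter = 200000L) {
  stopifnot(inherits(data, "svm_dataset"), inherits(hp, "svm_hyperparams"))
  if (hp$psi <= 0) {
    stop_("the centralized oracle requires psi > 0 (got psi = %g)", hp$psi)
  }
  X <- data$features
  l <- data$labels
  n <- nrow(X)
  psi <- hp$psi
  rho <- hp$rho

  theta_of <- function(alpha) soft_threshold(drop(crossprod(X, alpha * l)), rho) / psi
  dual_of <- function(alpha, theta) sum(alpha) - 0.5 * psi * sum(theta^2)
  grad_f <- function(theta) l * (drop(X %*% theta)) - 1  # gradient of -dual

  L <- max(spectral_norm(X)^2 / psi, .Machine$double.eps)
  alpha <- numeric(n)
  y <- alpha
  t_acc <- 1
  g_old <- -Inf
  best <- NULL
  check_every <- 25L
  iter_done <- max_iter

  for (k in seq_len(max_iter)) {
    theta_y <- theta_of(y)
    alpha_new <- project_dual(y - grad_f(theta_y) / L, l)
    g_new <- dual_of(alpha_new, theta_of(alpha_new))
    if (g_new < g_old) {        # adaptive restart of the momentum
      t_acc <- 1
      y <- alpha
      theta_y <- theta_of(y)
      alpha_new <- project_dual(y - grad_f(theta_y) / L, l)
      g_new <- dual_of(alpha_new, theta_of(alpha_new))
    }
    t_new <- (1 + sqrt(1 + 4 * t_acc^2)) / 2
    y <- alpha_new + ((t_acc - 1) / t_new) * (alpha_new - alpha)
    alpha <- alpha_new
    t_acc <- t_new
    g_old <- g_new

    if (k %% check_every == 0L || k == max_iter) {
      theta <- theta_of(alpha)
      m0 <- drop(X %*% theta)
      theta0 <- optimal_bias(m0, l)
      clf <- svm_classifier(theta, theta0, data$feature_names)
      primal <- svm_objective(clf, data, hp)
      gap <- primal - g_new
      if (is.null(best) || primal < best$objective_value) {
        best <- list(classifier = clf, objective_value = primal,
                     duality_gap = gap, dual_objective = g_new)
      }
      if (best$duality_gap <= tol * max(1, abs(best$objective_value))) {
        iter_done <- k
        break
      }
    }
  }
  if (is.null(best) ||
      best$duality_gap > tol * max(1, abs(best$objective_value))) {
    stop_("oracle did not converge: duality gap %.3g after %d iterations",
          if (is.null(best)) NA_real_ else best$duality_gap, max_iter)
  }
  structure(c(best, list(solver_status = "optimal", iterations = iter_done)),
            class = "oracle_solution")
}

#' @export
print.oracle_solution <- function(x, ...) {
  cat(sprintf("<oracle_solution> objective %.8g (gap %.2e, %d iterations)\n",
              x$objective_value, x$duality_gap, x$iterations))
  invisible(x)
}
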