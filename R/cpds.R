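# Cluster primal-dual splitting (cPDS) over a Metropolis-weighted graph.
#
# Each agent j holds a data shard and the local objective
#   G_j(x_j) = 0.5 psi_j ||theta_j||^2 + rho_j ||theta_j||_1   (bias free)
#   F_j(y_j) = sum_i max(0, 1 - y_ji),   y_j = Gamma_j A_j x_j
# with x_j = (theta_j, theta_j0) and A_j the signed margin operator, under
# the consensus constraint x_1 = ... = x_m. The solver is a Condat-Vu /
# Chambolle-Pock primal-dual splitting on the product space: one dual block
# u_j per agent for the hinge term, and a consensus dual (kept locally as
# nu_j, the image of the multiplier under the consensus operator I - W) for
# the constraint. One synchronous round per agent:
#
#   u_j  <- prox_{hinge*}(u_j + sigma Gamma_j A_j xt_j)      (per-sample step)
#   nu_j <- nu_j + sigma_c (xt_j - sum_h w_jh xt_h)          (Metropolis mixing)
#   x_j  <- prox_reg(x_j - tau (Gamma_j A_j)' u_j - tau nu_j)
#   xt_j <- 2 x_j - x_j_old                                  (extrapolation)
#
# Only the extrapolated primal xt_j travels over edges; both dual blocks stay
# local, so one round costs 2|E| model-vector messages. Because the columns
# of (I - W) sum to zero on a doubly stochastic W, the accumulated nu_j sum
# to zero across agents and the fixed points are exactly the saddle points of
# the *global* consensus problem -- plain "mix then prox" diffusion (without
# nu) stalls at an O(tau) biased fixed point instead. Convergence requires
#   tau * (sigma * L^2 + sigma_c * ||I - W||) <= 1,  L = max_j ||Gamma_j A_j||.

#' Per-agent problem description
#'
#' Bundles one agent's data shard with its penalty coefficients and optional
#' positive per-sample scalings `gamma` (folded into the margin operator;
#' defaults to 1).
#'
#' @param data the agent's [svm_dataset()].
#' @param hp per-agent [hyperparams()] (already scaled; see [agent_problems()]).
#' @param gamma optional positive vector of per-sample weights.
#' @return an object of class `agent_problem`.
#' @export
agent_problem <- function(data, hp, gamma = NULL) {
  stopifnot(inherits(data, "svm_dataset"), inherits(hp, "svm_hyperparams"))
  n <- n_samples(data)
  if (n < 1L) stop_("an agent needs at least one sample")
  if (is.null(gamma)) gamma <- rep(1, n)
  if (length(gamma) != n || any(gamma <= 0)) {
    stop_("gamma must be a positive vector of length %d", n)
  }
  structure(list(data = data, hp = hp, gamma = as.numeric(gamma),
                 K = gamma * margin_operator(data)),
            class = "agent_problem")
}

#' Build the per-agent problems of a federated run
#'
#' Splits global penalties across agents as `psi_j = psi / m`,
#' `rho_j = rho / m`, so that at consensus the sum of local objectives equals
#' the centralized objective with the global `hp`.
#'
#' @param partition an [partition_agents()] result, or a list of
#'   [svm_dataset()]s.
#' @param hp global [hyperparams()].
#' @return list of [agent_problem()]s.
#' @export
agent_problems <- function(partition, hp) {
  parts <- if (inherits(partition, "agent_partition")) partition$parts else partition
  m <- length(parts)
  hp_j <- hyperparams(hp$psi / m, hp$rho / m)
  lapply(parts, agent_problem, hp = hp_j)
}

#' Solver configuration for cPDS
#'
#' Step sizes left `NULL` are filled at [cpds_init()] from the problem scale
#' `L = max_j ||Gamma_j A_j||_2` (power iteration, 100 steps, tol 1e-10):
#' `tau = 1/L`, `sigma = 0.5 / (tau L^2)`, `consensus_sigma =
#' 0.45 / (tau ||I - W||)`, which satisfies the contraction contract
#' `tau * (sigma L^2 + consensus_sigma ||I - W||) <= 1` with margin and the
#' hinge-block rule `tau * sigma * L^2 <= 1` required at construction.
#'
#' @param tau primal step (> 0) or `NULL` for the default.
#' @param sigma hinge dual step (> 0) or `NULL`.
#' @param consensus_sigma consensus dual step (>= 0) or `NULL`.
#' @param max_rounds communication-round cap.
#' @param tol_consensus stop threshold on the consensus residual.
#' @param tol_objective stop threshold on the relative objective change of
#'   the averaged model over the last 10 recorded points.
#' @param record_every record the trace every this many rounds.
#' @param seed seed reserved for randomised initialisation (the default
#'   initialisation is deterministic zero).
#' @return an object of class `cpds_config`.
#' @export
solver_config <- function(tau = NULL, sigma = NULL, consensus_sigma = NULL,
                          max_rounds = 1000, tol_consensus = 1e-8,
                          tol_objective = 1e-10, record_every = 10, seed = 1) {
  structure(list(tau = tau, sigma = sigma, consensus_sigma = consensus_sigma,
                 max_rounds = check_count(max_rounds, "max_rounds"),
                 tol_consensus = check_scalar(tol_consensus, "tol_consensus", lower = 0),
                 tol_objective = check_scalar(tol_objective, "tol_objective", lower = 0),
                 record_every = check_count(record_every, "record_every"),
                 seed = check_count(seed, "seed", min = 0L)),
            class = "cpds_config")
}

#' Initialise the cPDS solver state
#'
#' Verifies dimensions and the step-size contract (erroring with the violated
#' bound), and returns the round-0 state: all primal, extrapolated and dual
#' iterates at zero.
#'
#' @param problems list of [agent_problem()]s, one per graph vertex.
#' @param graph a [metropolis_weights()]-completed `comm_graph`.
#' @param config a [solver_config()].
#' @param test_data optional [svm_dataset()]; when given, test accuracy of the
#'   averaged model is recorded along the trace.
#' @return an object of class `cpds_state`.
#' @export
cpds_init <- function(problems, graph, config = solver_config(), test_data = NULL) {
  stopifnot(inherits(graph, "comm_graph"), inherits(config, "cpds_config"))
  if (!all(vapply(problems, inherits, TRUE, "agent_problem"))) {
    stop_("`problems` must be a list of agent_problem objects")
  }
  m <- length(problems)
  if (m != graph$m) stop_("%d problems but the graph has %d agents", m, graph$m)
  if (is.null(graph$weights)) stop_("graph weights unset; call metropolis_weights() first")
  d <- n_features(problems[[1]]$data)
  if (!all(vapply(problems, function(p) n_features(p$data), 1L) == d)) {
    stop_("all agents must share the feature dimension")
  }

  L <- max(vapply(problems, function(p) spectral_norm(p$K), 0))
  W <- graph$weights
  B2 <- if (m == 1L) 0 else max(abs(eigen(diag(m) - W, symmetric = TRUE,
                                           only.values = TRUE)$values))
  tau <- if (is.null(config$tau)) 1 / L else check_scalar(config$tau, "tau", 0, open_lower = TRUE)
  # budget split between the two dual blocks: consensus enforcement gets the
  # larger share on multi-agent graphs (it is what limits the final
  # disagreement); a single agent has no consensus block and the hinge dual
  # takes the whole budget
  single <- B2 < 1e-14
  sigma <- if (is.null(config$sigma)) (if (single) 0.9 else 0.25) / (tau * L^2)
           else check_scalar(config$sigma, "sigma", 0, open_lower = TRUE)
  consensus_sigma <- if (is.null(config$consensus_sigma)) {
    if (single) 0 else 0.7 / (tau * B2)
  } else check_scalar(config$consensus_sigma, "consensus_sigma", 0)

  if (tau * sigma * L^2 > 1 + 1e-12) {
    stop_("step rule violated: tau * sigma * L^2 = %.4g > 1 (L = %.4g)",
          tau * sigma * L^2, L)
  }
  if (tau * (sigma * L^2 + consensus_sigma * B2) > 1 + 1e-12) {
    stop_("step rule violated: tau * (sigma L^2 + consensus_sigma ||I-W||) = %.4g > 1",
          tau * (sigma * L^2 + consensus_sigma * B2))
  }

  config$tau <- tau; config$sigma <- sigma; config$consensus_sigma <- consensus_sigma
  hp_global <- hyperparams(sum(vapply(problems, function(p) p$hp$psi, 0)),
                           sum(vapply(problems, function(p) p$hp$rho, 0)))
  state <- structure(list(
    problems = problems, graph = graph, config = config,
    m = m, d = d, L = L, B2 = B2,
    hp_global = hp_global,
    neighbours = lapply(seq_len(m), function(j) {
      setdiff(which(graph$weights[, j] > 0), j)
    }),
    X = matrix(0, d + 1, m), Xt = matrix(0, d + 1, m), Nu = matrix(0, d + 1, m),
    U = lapply(problems, function(p) numeric(n_samples(p$data))),
    round = 0L,
    messages_per_round = 2L * nrow(graph$edges),
    vector_length = d + 1L,
    log = comm_log(),
    test_data = test_data,
    trace = list()
  ), class = "cpds_state")
  state$trace[[1]] <- trace_row(state)
  state
}

# network average, written as deviations from agent 1 so that bitwise-equal
# agent states average to themselves exactly
network_average <- function(X) {
  drop(X[, 1] + rowMeans(X - X[, 1]))
}

average_classifier <- function(state) {
  xbar <- network_average(state$X)
  svm_classifier(xbar[-(state$d + 1L)], xbar[state$d + 1L],
                 state$problems[[1]]$data$feature_names)
}

union_objective <- function(state, clf) {
  sum(vapply(state$problems, function(p) sum(hinge_losses(clf, p$data)), 0)) +
    0.5 * state$hp_global$psi * sum(clf$theta^2) +
    state$hp_global$rho * sum(abs(clf$theta))
}

trace_row <- function(state) {
  clf <- average_classifier(state)
  row <- list(round = state$round,
              objective = union_objective(state, clf),
              consensus_residual = consensus_residual(state),
              cumulative_messages = state$log$messages,
              cumulative_bytes = state$log$bytes)
  row$test_accuracy <- if (!is.null(state$test_data)) {
    predict_accuracy(clf, state$test_data)$accuracy
  } else NA_real_
  row
}

#' Maximum consensus disagreement
#'
#' `max_j || x_j - xbar ||_2`, the residual of the consensus constraint at
#' the current primal iterates.
#'
#' @param state a `cpds_state`.
#' @return nonnegative scalar.
#' @export
consensus_residual <- function(state) {
  stopifnot(inherits(state, "cpds_state"))
  xbar <- network_average(state$X)
  sqrt(max(colSums((state$X - xbar)^2)))
}

#' One synchronous cPDS round
#'
#' Runs the dual, consensus and primal updates for every agent in parallel
#' (see the iteration laid out in the package source and vignette), advances
#' the round counter, updates the communication log (`2|E|` model-vector
#' messages per round), and appends a trace record every `record_every`
#' rounds. Each agent reads only its graph neighbours' extrapolated primals.
#'
#' @param state a `cpds_state`.
#' @return the updated `cpds_state`.
#' @export
cpds_step <- function(state) {
  stopifnot(inherits(state, "cpds_state"))
  cfg <- state$config
  if (state$round >= cfg$max_rounds) stop_("max_rounds (%d) already reached", cfg$max_rounds)
  W <- state$graph$weights
  X_old <- state$X

  # (a) hinge dual, per agent, using the extrapolated primal
  for (j in seq_len(state$m)) {
    p <- state$problems[[j]]
    v <- state$U[[j]] + cfg$sigma * drop(p$K %*% state$Xt[, j])
    state$U[[j]] <- prox_hinge_conjugate(v, cfg$sigma * p$gamma)
  }

  # (b) consensus dual: Metropolis-weighted disagreement with the neighbours,
  # accumulated locally. Written as sum_h w_jh (xt_j - xt_h) -- equal to
  # xt_j - sum_h w_jh xt_h because the rows of W sum to one -- so agents in
  # bitwise consensus accumulate an exact zero and only neighbour columns
  # (w_jh > 0) are ever read.
  if (state$m > 1L && cfg$consensus_sigma > 0) {
    for (j in seq_len(state$m)) {
      nb <- state$neighbours[[j]]
      if (length(nb)) {
        delta <- (state$Xt[, j] - state$Xt[, nb, drop = FALSE]) %*% W[nb, j]
        state$Nu[, j] <- state$Nu[, j] + cfg$consensus_sigma * drop(delta)
      }
    }
  }

  # (c) primal prox step against both dual blocks
  for (j in seq_len(state$m)) {
    p <- state$problems[[j]]
    u <- X_old[, j] - cfg$tau * drop(crossprod(p$K, state$U[[j]])) -
      cfg$tau * state$Nu[, j]
    xj <- prox_regularizer(u, cfg$tau, p$hp)
    if (!all(is.finite(xj))) {
      stop_("non-finite iterate for agent %d at round %d", j, state$round + 1L)
    }
    state$X[, j] <- xj
  }

  # (d) extrapolation
  state$Xt <- 2 * state$X - X_old
  state$round <- state$round + 1L
  state$log <- record_round(state$log, state$messages_per_round, state$vector_length)

  if (state$round %% cfg$record_every == 0L || state$round == cfg$max_rounds) {
    state$trace[[length(state$trace) + 1L]] <- trace_row(state)
  }
  state
}

#' Run cPDS to convergence
#'
#' Iterates [cpds_step()] until `max_rounds`, or earlier once the consensus
#' residual drops below `tol_consensus` *and* the relative objective change
#' of the averaged model across the last 10 recorded trace points falls
#' below `tol_objective`. The returned model is the network average
#' `xbar = mean_j x_j` split into `(theta, theta0)`.
#'
#' @inheritParams cpds_init
#' @return an object of class `cpds_fit`: list with `classifier`, `state`,
#'   `objective` (averaged-model objective at the final round), and `rounds`.
#' @export
cpds_solve <- function(problems, graph, config = solver_config(), test_data = NULL) {
  state <- cpds_init(problems, graph, config, test_data = test_data)
  cfg <- state$config
  while (state$round < cfg$max_rounds) {
    state <- cpds_step(state)
    if (state$round %% cfg$record_every == 0L && length(state$trace) >= 11L) {
      tr <- state$trace
      last <- tr[[length(tr)]]
      prev <- tr[[length(tr) - 10L]]
      rel <- abs(last$objective - prev$objective) / max(1e-12, abs(last$objective))
      if (last$consensus_residual <= cfg$tol_consensus && rel <= cfg$tol_objective) break
    }
  }
  clf <- average_classifier(state)
  structure(list(classifier = clf, state = state,
                 objective = union_objective(state, clf),
                 rounds = state$round),
            class = "cpds_fit")
}

#' @export
print.cpds_fit <- function(x, ...) {
  cat(sprintf("<cpds_fit> %d rounds, objective %.6g, consensus residual %.3g\n",
              x$rounds, x$objective, consensus_residual(x$state)))
  invisible(x)
}

#' Extract the solver trace
#'
#' One row per recorded round with columns `round`, `objective`,
#' `consensus_residual`, `cumulative_messages`, `cumulative_bytes` and
#' `test_accuracy` (NA when no test set was supplied).
#'
#' @param x a `cpds_state` or `cpds_fit`.
#' @return a `data.frame`.
#' @export
cpds_trace <- function(x) {
  state <- if (inherits(x, "cpds_fit")) x$state else x
  stopifnot(inherits(state, "cpds_state"))
  do.call(rbind, lapply(state$trace, function(r) as.data.frame(r)))
}

#' Write a solver trace as CSV
#'
#' @param trace a data.frame from [cpds_trace()] (or the FedAvg equivalent).
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(trace, path) {
  data.table::fwrite(data.table::as.data.table(trace), path)
  invisible(path)
}
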