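# FedAvg-style comparator ("Fed-SVM"): rounds of local proximal-subgradient
# training on each agent's shard followed by server-side sample-weighted
# model averaging. This is a baseline, not an oracle: with heterogeneous
# shards it exhibits the usual client drift and need not reach the
# centralized optimum.

# sample-share-weighted average, computed as deviations from the first
# column so that identical local models average to themselves bitwise
weighted_average <- function(X, w) {
  drop(X[, 1] + (X - X[, 1]) %*% w)
}

# one agent's local training pass: full-batch proximal subgradient on the
# agent's local objective (hinge over its shard plus the global penalties
# scaled by its sample share, so the shards sum to the centralized
# objective), step 1/(psi_loc t) (1/sqrt(t) when psi = 0), t continuing
# across rounds
fedavg_local_update <- function(x, data, hp, epochs, t0) {
  d <- n_features(data)
  A <- margin_operator(data)
  t_local <- t0
  for (e in seq_len(epochs)) {
    t_local <- t_local + 1
    eta <- if (hp$psi > 0) 1 / (hp$psi * t_local) else 1 / sqrt(t_local)
    margins <- drop(A %*% x)
    active <- margins < 1
    g <- -unname(colSums(A[active, , drop = FALSE]))
    g[-(d + 1)] <- g[-(d + 1)] + hp$psi * x[-(d + 1)]
    x <- x - eta * g
    x[-(d + 1)] <- soft_threshold(x[-(d + 1)], eta * hp$rho)
  }
  x
}

#' FedAvg baseline for the sparse SVM
#'
#' Per round, every agent starts from the current global model and runs
#' `local_epochs` full-batch proximal-subgradient steps on its local
#' objective (hinge over its own shard plus the global penalties scaled by
#' its sample share `n_j / n`, so the local objectives sum to the
#' centralized one): a subgradient step on hinge + ridge followed by
#' soft-thresholding for the L1 term, with the classical decaying step
#' `eta_t = 1 / (psi_loc * t)` (or `1 / sqrt(t)` when `psi = 0`), `t`
#' counting local steps across the whole run. The server then averages the
#' returned models weighted by `n_j`; agents holding identical shards
#' produce identical updates, so the average equals any one agent's local
#' training result bitwise. With `rounds = 0` the zero classifier is
#' returned. The procedure is deterministic (full-batch); `seed` is kept
#' for interface stability.
#'
#' @param partition an [partition_agents()] result or list of datasets.
#' @param hp global [hyperparams()].
#' @param rounds number of communication rounds (`>= 0`).
#' @param local_epochs local steps per round (`>= 1`).
#' @param seed unused by the deterministic full-batch variant.
#' @param test_data optional test [svm_dataset()] for the trace.
#' @param record_every trace recording stride.
#' @return an object of class `fedavg_fit`: list with `classifier`, `trace`
#'   (same schema as [cpds_trace()]), `log` (a [comm_log()]) and `rounds`.
#' @export
fedavg_svm <- function(partition, hp, rounds = 100, local_epochs = 5,
                       seed = 1, test_data = NULL, record_every = 10) {
  parts <- if (inherits(partition, "agent_partition")) partition$parts else partition
  stopifnot(inherits(hp, "svm_hyperparams"))
  rounds <- check_count(rounds, "rounds", min = 0L)
  local_epochs <- check_count(local_epochs, "local_epochs")
  m <- length(parts)
  if (m < 1L) stop_("degenerate partition: no agents")
  n_j <- vapply(parts, n_samples, 1L)
  if (any(n_j < 1L)) stop_("degenerate partition: empty agent shard")
  n <- sum(n_j)
  d <- n_features(parts[[1]])
  feature_names <- parts[[1]]$feature_names

  union_obj <- function(clf) {
    sum(vapply(parts, function(p) sum(hinge_losses(clf, p)), 0)) +
      0.5 * hp$psi * sum(clf$theta^2) + hp$rho * sum(abs(clf$theta))
  }

  x_global <- numeric(d + 1)          # (theta, theta0)
  log <- comm_log()
  t_step <- 0
  trace <- list()
  record <- function(round, X_local) {
    clf <- svm_classifier(x_global[-(d + 1)], x_global[d + 1], feature_names)
    drift <- if (is.null(X_local)) 0 else {
      xbar <- rowMeans(X_local)
      sqrt(max(colSums((X_local - xbar)^2)))
    }
    list(round = round, objective = union_obj(clf), consensus_residual = drift,
         cumulative_messages = log$messages, cumulative_bytes = log$bytes,
         test_accuracy = if (!is.null(test_data)) predict_accuracy(clf, test_data)$accuracy else NA_real_)
  }
  trace[[1]] <- record(0L, NULL)

  for (r in seq_len(rounds)) {
    X_local <- matrix(0, d + 1, m)
    for (j in seq_len(m)) {
      hp_j <- hyperparams(hp$psi * n_j[j] / n, hp$rho * n_j[j] / n)
      X_local[, j] <- fedavg_local_update(x_global, parts[[j]], hp_j,
                                          local_epochs, t_step)
    }
    t_step <- t_step + local_epochs
    x_global <- weighted_average(X_local, n_j / n)
    log <- record_round(log, 2L * m, d + 1L)   # upload + download per client
    if (r %% record_every == 0L || r == rounds) {
      trace[[length(trace) + 1L]] <- record(r, X_local)
    }
  }

  clf <- svm_classifier(x_global[-(d + 1)], x_global[d + 1], feature_names)
  structure(list(classifier = clf,
                 trace = do.call(rbind, lapply(trace, as.data.frame)),
                 log = log, rounds = rounds),
            class = "fedavg_fit")
}

#' @export
print.fedavg_fit <- function(x, ...) {
  cat(sprintf("<fedavg_fit> %d rounds, final objective %.6g\n",
              x$rounds, utils::tail(x$trace$objective, 1)))
  invisible(x)
}
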