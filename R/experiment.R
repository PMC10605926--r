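# End-to-end benchmark harness: accuracy vs rounds / volume, utility vs
# cost, for cPDS against the centralized oracle, a FedAvg comparator, and
# purely local training.
#
# Cost axes are conventions (documented, since no standard exists):
# "compute" cost is cumulative local gradient/prox evaluations x 1e-4
# (cPDS: 2 per agent per round; FedAvg: local_epochs per agent per round;
# oracle/local: solver iterations), "transmission" cost is cumulative
# messages x 1e-3. Accuracy is reported in percent.

#' Experiment configuration
#'
#' @param cohort a [cohort_spec()] describing the synthetic cohort.
#' @param m number of data-holding client agents.
#' @param topology graph kind for [build_topology()].
#' @param topology_p edge probability (erdos_renyi only).
#' @param partition_mode `"iid"` or `"label_skew"`.
#' @param skew_alpha Dirichlet concentration for label skew.
#' @param test_fraction held-out fraction for accuracy scoring.
#' @param hp global [hyperparams()].
#' @param checkpoints strictly increasing round counts at which accuracy is
#'   recorded.
#' @param local_epochs FedAvg local steps per round.
#' @param methods subset of `c("cpds", "fedavg", "local", "oracle")`.
#' @param utility_kappa nonnegative cost weight in the utility
#'   `accuracy_percent - kappa * cost`.
#' @param cost_kind `"transmission"` or `"compute"`.
#' @param record_every trace stride; must divide every checkpoint.
#' @param seed seed for the partition and split (the cohort uses its own).
#' @return an object of class `experiment_config`.
#' @export
experiment_config <- function(cohort = cohort_spec(),
                              m = 5,
                              topology = "star",
                              topology_p = NULL,
                              partition_mode = "label_skew",
                              skew_alpha = 0.5,
                              test_fraction = 0.25,
                              hp = hyperparams(1, 0.1),
                              checkpoints = seq(100L, 1000L, by = 100L),
                              local_epochs = 5,
                              methods = c("cpds", "fedavg", "local", "oracle"),
                              utility_kappa = 1,
                              cost_kind = c("transmission", "compute"),
                              record_every = 10,
                              seed = 1) {
  stopifnot(inherits(cohort, "cohort_spec"), inherits(hp, "svm_hyperparams"))
  if (length(methods) < 1L) stop_("at least one method is required")
  methods <- match.arg(methods, c("cpds", "fedavg", "local", "oracle"),
                       several.ok = TRUE)
  checkpoints <- as.integer(checkpoints)
  if (length(checkpoints) < 1L || any(diff(checkpoints) <= 0) || any(checkpoints < 1L)) {
    stop_("checkpoints must be strictly increasing positive integers")
  }
  record_every <- check_count(record_every, "record_every")
  if (any(checkpoints %% record_every != 0L)) {
    stop_("every checkpoint must be a multiple of record_every (%d)", record_every)
  }
  structure(list(cohort = cohort, m = check_count(m, "m"),
                 topology = topology, topology_p = topology_p,
                 partition_mode = partition_mode,
                 skew_alpha = check_scalar(skew_alpha, "skew_alpha", 0, open_lower = TRUE),
                 test_fraction = test_fraction, hp = hp,
                 checkpoints = checkpoints,
                 local_epochs = check_count(local_epochs, "local_epochs"),
                 methods = methods,
                 utility_kappa = check_scalar(utility_kappa, "utility_kappa", 0),
                 cost_kind = match.arg(cost_kind),
                 record_every = record_every,
                 seed = check_count(seed, "seed", min = 0L)),
            class = "experiment_config")
}

#' Utility of an accuracy/cost operating point
#'
#' The linear trade-off `accuracy_percent - kappa * cost`; `kappa = 0`
#' reduces utility to accuracy.
#'
#' @param accuracy_percent accuracy in `[0, 100]`.
#' @param cost nonnegative cost.
#' @param kappa nonnegative cost weight.
#' @return scalar utility.
#' @export
utility <- function(accuracy_percent, cost, kappa) {
  if (any(accuracy_percent < 0 | accuracy_percent > 100)) {
    stop_("accuracy must be in [0, 100]")
  }
  if (any(cost < 0) || any(kappa < 0)) stop_("cost and kappa must be nonnegative")
  accuracy_percent - kappa * cost
}

cost_of <- function(kind, messages, evals) {
  if (kind == "transmission") messages * 1e-3 else evals * 1e-4
}

#' Run a full benchmark experiment
#'
#' Generates the cohort, makes a stratified train/test split, partitions the
#' training rows across `m` agents, and runs every requested method,
#' recording test accuracy (percent), cumulative communication volume, cost
#' and utility at each checkpoint. The oracle and local baselines have no
#' rounds axis: their rows repeat the converged accuracy with `round = 0`
#' and zero transmission. Deterministic given the config (all seeds
#' explicit).
#'
#' @param config an [experiment_config()].
#' @return a `data.frame` of class `metrics_table` with columns `method`,
#'   `round`, `gigabytes`, `accuracy_percent`, `cost`, `utility`; the fitted
#'   models are attached as the `"fits"` attribute.
#' @export
run_experiment <- function(config) {
  stopifnot(inherits(config, "experiment_config"))
  stage <- function(what, expr) {
    tryCatch(expr, error = function(e) {
      stop_("experiment stage `%s` failed: %s", what, conditionMessage(e))
    })
  }
  cohort <- stage("generate", generate_cohort(config$cohort))
  split <- stage("split", train_test_split(cohort, config$test_fraction,
                                           seed = derive_seed(config$seed, 1L)))
  part <- stage("partition", partition_agents(split$train, config$m,
                                              mode = config$partition_mode,
                                              skew_alpha = config$skew_alpha,
                                              seed = derive_seed(config$seed, 2L)))
  graph <- stage("graph", metropolis_weights(
    build_topology(config$topology, config$m, p = config$topology_p,
                   seed = derive_seed(config$seed, 3L))))

  cps <- config$checkpoints
  max_rounds <- max(cps)
  kappa <- config$utility_kappa
  rows <- list()
  fits <- list()
  add_rows <- function(method, round, gigabytes, acc, evals, messages) {
    cost <- cost_of(config$cost_kind, messages, evals)
    rows[[length(rows) + 1L]] <<- data.frame(
      method = method, round = round, gigabytes = gigabytes,
      accuracy_percent = 100 * acc, cost = cost,
      utility = utility(100 * acc, cost, kappa))
  }

  for (method in config$methods) {
    if (method == "cpds") {
      fit <- stage("cpds", cpds_solve(
        agent_problems(part, config$hp), graph,
        solver_config(max_rounds = max_rounds, tol_consensus = 0,
                      tol_objective = 0, record_every = config$record_every),
        test_data = split$test))
      fits$cpds <- fit
      tr <- cpds_trace(fit)
      for (cp in cps) {
        r <- tr[tr$round == cp, ]
        add_rows("cpds", cp, r$cumulative_bytes / 2^30, r$test_accuracy,
                 evals = 2 * config$m * cp, messages = r$cumulative_messages)
      }
    } else if (method == "fedavg") {
      fit <- stage("fedavg", fedavg_svm(part, config$hp, rounds = max_rounds,
                                        local_epochs = config$local_epochs,
                                        seed = derive_seed(config$seed, 4L),
                                        test_data = split$test,
                                        record_every = config$record_every))
      fits$fedavg <- fit
      tr <- fit$trace
      for (cp in cps) {
        r <- tr[tr$round == cp, ]
        add_rows("fedavg", cp, r$cumulative_bytes / 2^30, r$test_accuracy,
                 evals = config$m * config$local_epochs * cp,
                 messages = r$cumulative_messages)
      }
    } else if (method == "oracle") {
      sol <- stage("oracle", solve_centralized_qp(split$train, config$hp))
      fits$oracle <- sol
      acc <- predict_accuracy(sol$classifier, split$test)$accuracy
      for (cp in cps) add_rows("oracle", 0L, 0, acc, evals = sol$iterations, messages = 0)
    } else if (method == "local") {
      sols <- stage("local", lapply(part$parts, solve_centralized_qp, hp = config$hp))
      w <- vapply(part$parts, n_samples, 1L)
      w <- w / sum(w)
      theta <- Reduce(`+`, Map(function(s, wi) wi * s$classifier$theta, sols, w))
      theta0 <- sum(vapply(sols, function(s) s$classifier$theta0, 0) * w)
      clf <- svm_classifier(theta, theta0, split$train$feature_names)
      fits$local <- clf
      acc <- predict_accuracy(clf, split$test)$accuracy
      evals <- sum(vapply(sols, function(s) s$iterations, 0L))
      for (cp in cps) add_rows("local", 0L, 0, acc, evals = evals, messages = 0)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "fits") <- fits
  class(out) <- c("metrics_table", class(out))
  out
}

#' Write / read a metrics table as CSV
#'
#' Fixed column order `method, round, gigabytes, accuracy_percent, cost,
#' utility`; values round-trip losslessly to well past 10 significant
#' digits, and a write-read-write cycle is byte-identical.
#'
#' @param table a `metrics_table` (or compatible data.frame).
#' @param path file path.
#' @return `write_metrics` returns `path` invisibly; `read_metrics` a
#'   `metrics_table`.
#' @export
write_metrics <- function(table, path) {
  cols <- c("method", "round", "gigabytes", "accuracy_percent", "cost", "utility")
  if (nrow(table) == 0L) {
    writeLines(paste(cols, collapse = ","), path)
    return(invisible(path))
  }
  missing_cols <- setdiff(cols, names(table))
  if (length(missing_cols)) stop_("missing columns: %s", paste(missing_cols, collapse = ", "))
  data.table::fwrite(data.table::as.data.table(table)[, cols, with = FALSE], path)
  invisible(path)
}

#' @rdname write_metrics
#' @export
read_metrics <- function(path) {
  out <- data.table::fread(path, data.table = FALSE)
  class(out) <- c("metrics_table", class(out))
  out
}

#' Read an experiment configuration from JSON
#'
#' The JSON mirrors the [experiment_config()] fields; `cohort` is a nested
#' object mirroring [cohort_spec()] fields and `hp` holds `psi`/`rho`.
#' Absent fields keep their defaults. An optional top-level `seed` override
#' reseeds both the cohort and the experiment.
#'
#' @param path JSON file path.
#' @param seed optional seed overriding the file's seeds.
#' @return an [experiment_config()].
#' @export
read_experiment_config <- function(path, seed = NULL) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  cohort_args <- if (!is.null(raw$cohort)) raw$cohort else list()
  hp <- if (!is.null(raw$hp)) hyperparams(raw$hp$psi, raw$hp$rho) else hyperparams(1, 0.1)
  args <- raw[setdiff(names(raw), c("cohort", "hp"))]
  if (!is.null(seed)) {
    cohort_args$seed <- seed
    args$seed <- seed
  }
  args$cohort <- do.call(cohort_spec, cohort_args)
  args$hp <- hp
  do.call(experiment_config, args)
}
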