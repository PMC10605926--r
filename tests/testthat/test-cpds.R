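small_problem <- function(dat, hp = hyperparams(1, 0.1), m = 3,
                          topo = "complete", mode = "iid", seed = 2) {
  part <- partition_agents(dat, m, mode, seed = seed)
  list(problems = agent_problems(part, hp),
       graph = metropolis_weights(build_topology(topo, m)))
}

test_that("initialisation starts from zero and enforces the step rule", {
  dat <- make_instance(n = 60, seed = 14)
  sp <- small_problem(dat)
  st <- cpds_init(sp$problems, sp$graph)
  expect_equal(st$round, 0L)
  expect_equal(consensus_residual(st), 0)
  expect_true(all(st$X == 0) && all(st$Xt == 0))
  expect_true(all(vapply(st$U, function(u) all(u == 0), TRUE)))

  # tau * sigma * L^2 = 1.5 must be rejected, naming the bound
  L <- st$L
  bad <- solver_config(tau = 1 / L, sigma = 1.5 * L)
  expect_error(cpds_init(sp$problems, sp$graph, bad), "step rule")

  expect_error(cpds_init(sp$problems, metropolis_weights(build_topology("ring", 4))),
               "agents")
  expect_error(cpds_init(sp$problems, build_topology("complete", 3)), "weights")
})

test_that("identical shards stay in exact consensus at every round", {
  dat <- make_instance(n = 50, seed = 15)
  probs <- agent_problems(list(dat, dat, dat), hyperparams(1, 0.1))
  g <- metropolis_weights(build_topology("complete", 3))
  st <- cpds_init(probs, g, solver_config(max_rounds = 120))
  for (k in 1:120) {
    st <- cpds_step(st)
    expect_identical(st$X[, 1], st$X[, 2])
    expect_identical(st$X[, 1], st$X[, 3])
    expect_identical(consensus_residual(st), 0)
  }
})

test_that("dual iterates live in [-1, 0] and huge rho zeroes the weights", {
  dat <- make_instance(n = 60, seed = 16)
  sp <- small_problem(dat, hp = hyperparams(1, 1e6), m = 4, topo = "ring")
  st <- cpds_init(sp$problems, sp$graph, solver_config(max_rounds = 50))
  for (k in 1:50) {
    st <- cpds_step(st)
    for (u in st$U) expect_true(all(u >= -1 & u <= 0))
  }
  expect_true(all(st$X[1:10, ] == 0))   # soft threshold kills every weight
})

test_that("an agent's update only reads its neighbours' states", {
  dat <- make_instance(n = 80, seed = 17)
  sp <- small_problem(dat, m = 4, topo = "ring")
  st <- cpds_init(sp$problems, sp$graph, solver_config(max_rounds = 1000))
  for (k in 1:5) st <- cpds_step(st)

  # ring 1-2-3-4-1: agent 3 is not a neighbour of agent 1
  W <- sp$graph$weights
  expect_equal(W[1, 3], 0)
  perturbed <- st
  perturbed$X[, 3] <- perturbed$X[, 3] + 10
  perturbed$Xt[, 3] <- perturbed$Xt[, 3] + 10
  perturbed$U[[3]] <- pmax(perturbed$U[[3]] - 0.5, -1)
  a <- cpds_step(st)
  b <- cpds_step(perturbed)
  expect_identical(a$X[, 1], b$X[, 1])
  expect_identical(a$U[[1]], b$U[[1]])
  expect_identical(a$Nu[, 1], b$Nu[, 1])
  # ...but a neighbour's state does propagate
  expect_false(identical(a$X[, 2], b$X[, 2]))
})

test_that("cPDS matches the centralized oracle (single and multi-agent)", {
  dat <- generate_cohort(cohort_spec(40, 3, 2, sparsity = 2, label_noise = 0.05,
                                     seed = 1))
  hp <- hyperparams(1, 0.1)
  oracle <- solve_centralized_qp(dat, hp)

  f1 <- cpds_solve(agent_problems(list(dat), hp),
                   metropolis_weights(build_topology("complete", 1)),
                   solver_config(max_rounds = 5000, tol_consensus = 1e-8,
                                 tol_objective = 1e-12))
  expect_lte(abs(f1$objective - oracle$objective_value) / oracle$objective_value,
             1e-3)

  part <- partition_agents(dat, 4, "iid", seed = 3)
  f4 <- cpds_solve(agent_problems(part, hp),
                   metropolis_weights(build_topology("path", 4)),
                   solver_config(max_rounds = 5000, tol_consensus = 1e-7,
                                 tol_objective = 1e-11))
  expect_lte(abs(f4$objective - oracle$objective_value) / oracle$objective_value,
             1e-3)
  expect_lte(consensus_residual(f4$state), 1e-4)
})

test_that("complete and ring topologies reach the same optimum", {
  dat <- make_instance(n = 90, seed = 18)
  hp <- hyperparams(1, 0.2)
  cfg <- solver_config(max_rounds = 4000, tol_consensus = 1e-7,
                       tol_objective = 1e-11)
  part <- partition_agents(dat, 4, "iid", seed = 4)
  obj <- vapply(c("complete", "ring"), function(topo) {
    cpds_solve(agent_problems(part, hp),
               metropolis_weights(build_topology(topo, 4)), cfg)$objective
  }, 0)
  expect_lte(abs(diff(obj)) / obj[1], 1e-3)
})

test_that("separable cohorts are fit to perfect training accuracy", {
  sep <- make_separable(n = 240, seed = 41)
  sp <- list(problems = agent_problems(partition_agents(sep, 4, "iid", seed = 5),
                                       hyperparams(0.01, 0.001)),
             graph = metropolis_weights(build_topology("complete", 4)))
  fit <- cpds_solve(sp$problems, sp$graph,
                    solver_config(max_rounds = 5000, tol_consensus = 1e-8,
                                  tol_objective = 1e-12))
  expect_equal(predict_accuracy(fit$classifier, sep)$accuracy, 1.0)
})

test_that("consensus residual trends downward over a long run", {
  dat <- make_instance(n = 100, seed = 19)
  sp <- small_problem(dat, m = 4, topo = "ring", seed = 8)
  fit <- cpds_solve(sp$problems, sp$graph,
                    solver_config(max_rounds = 1000, tol_consensus = 0,
                                  tol_objective = 0, record_every = 10))
  tr <- cpds_trace(fit)
  early <- stats::median(tr$consensus_residual[tr$round <= 100 & tr$round > 0])
  late <- stats::median(tr$consensus_residual[tr$round >= 900])
  expect_lt(late, early)
  # two agents at +v / -v have residual ||v||
  st <- cpds_init(agent_problems(partition_agents(dat, 2, "iid", seed = 1),
                                 hyperparams(1, 0.1)),
                  metropolis_weights(build_topology("complete", 2)))
  v <- c(rnorm(10), 0.5)
  st$X[, 1] <- v; st$X[, 2] <- -v
  expect_equal(consensus_residual(st), sqrt(sum(v^2)))
})

test_that("solver state errors are informative", {
  dat <- make_instance(n = 30, seed = 20)
  sp <- small_problem(dat, m = 2)
  st <- cpds_init(sp$problems, sp$graph, solver_config(max_rounds = 1))
  st <- cpds_step(st)
  expect_error(cpds_step(st), "max_rounds")
})

test_that("trace output carries accounting and objective columns", {
  dat <- make_instance(n = 60, seed = 22)
  split <- train_test_split(dat, 0.25, seed = 1)
  part <- partition_agents(split$train, 3, "iid", seed = 2)
  g <- metropolis_weights(build_topology("ring", 3))
  fit <- cpds_solve(agent_problems(part, hyperparams(1, 0.1)), g,
                    solver_config(max_rounds = 100, tol_consensus = 0,
                                  tol_objective = 0, record_every = 10),
                    test_data = split$test)
  tr <- cpds_trace(fit)
  expect_named(tr, c("round", "objective", "consensus_residual",
                     "cumulative_messages", "cumulative_bytes", "test_accuracy"))
  # 2|E| messages of (d+1) doubles per round
  expect_equal(tr$cumulative_messages, tr$round * 2 * 3)
  expect_equal(tr$cumulative_bytes, tr$cumulative_messages * 11 * 8)
  expect_lt(utils::tail(tr$objective, 1), tr$objective[1])
  path <- withr::local_tempfile(fileext = ".csv")
  write_trace_csv(tr, path)
  expect_equal(nrow(utils::read.csv(path)), nrow(tr))
})
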