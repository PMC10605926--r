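test_that("hinge losses and objective match hand evaluations", {
  # zero classifier: every hinge is exactly 1, objective is n
  dat <- make_instance(n = 25, seed = 2)
  zero <- svm_classifier(numeric(10), 0)
  expect_equal(hinge_losses(zero, dat), rep(1, 25))
  expect_equal(svm_objective(zero, dat, hyperparams(3, 7)), 25)

  # single-sample hand cases
  one <- function(phi, lab) svm_dataset(matrix(phi, 1), lab)
  clf <- svm_classifier(c(1, 0), 0)
  expect_equal(hinge_losses(clf, one(c(2, 0), 1)), 0)       # margin 2, correct
  expect_equal(hinge_losses(clf, one(c(0.5, 0), -1)), 1.5)  # wrong side by 0.5

  # theta=(1,-2), theta0=0.5, psi=2, rho=1, sample l=+1, phi=(0,0):
  # hinge 0.5 + ridge 5 + L1 3 = 8.5
  clf2 <- svm_classifier(c(1, -2), 0.5)
  expect_equal(svm_objective(clf2, one(c(0, 0), 1), hyperparams(2, 1)), 8.5)

  # psi = rho = 0 reduces to the hinge sum
  rc <- random_classifier(10, 3)
  expect_equal(svm_objective(rc, dat, hyperparams(0, 0)),
               sum(hinge_losses(rc, dat)))
  expect_error(hinge_losses(svm_classifier(1:3, 0), dat), "features")
})

test_that("objective is convex and nonnegative", {
  dat <- make_instance(n = 30, seed = 4)
  hp <- hyperparams(0.7, 0.4)
  set.seed(11)
  for (k in 1:100) {
    a <- svm_classifier(rnorm(10, sd = 2), rnorm(1))
    b <- svm_classifier(rnorm(10, sd = 2), rnorm(1))
    for (lam in c(0.25, 0.5, 0.75)) {
      mix <- svm_classifier(lam * a$theta + (1 - lam) * b$theta,
                            lam * a$theta0 + (1 - lam) * b$theta0)
      expect_lte(svm_objective(mix, dat, hp),
                 lam * svm_objective(a, dat, hp) +
                   (1 - lam) * svm_objective(b, dat, hp) + 1e-9)
    }
  }
})

test_that("c/eps parameterisation converts and shares its minimiser", {
  hp <- hyperparams_from_c_eps(2, 1)
  expect_equal(hp$psi, 0.5)
  expect_equal(hp$rho, 0.5)
  expect_equal(unclass(hyperparams_from_c_eps(1, 0))[c("psi", "rho")],
               list(psi = 1, rho = 0))
  expect_error(hyperparams_from_c_eps(0, 1), "c")

  # dual route: the constrained form with integer c equals the penalty form
  # on data with every sample duplicated c times
  dat <- make_instance(n = 20, n_cont = 4, n_bin = 2, seed = 13)
  c_val <- 2; eps <- 0.4
  dup <- svm_dataset(dat$features[rep(1:20, c_val), ],
                     dat$labels[rep(1:20, c_val)])
  sol_dup <- solve_centralized_qp(dup, hyperparams(1, eps), tol = 1e-10)
  sol_conv <- solve_centralized_qp(dat, hyperparams_from_c_eps(c_val, eps),
                                   tol = 1e-10)
  expect_equal(sol_conv$classifier$theta, sol_dup$classifier$theta,
               tolerance = 1e-5)
  expect_equal(sol_conv$classifier$theta0, sol_dup$classifier$theta0,
               tolerance = 1e-5)
})

test_that("prediction uses the sign(0) = +1 tie rule and complements flip", {
  dat <- make_instance(n = 40, seed = 6)
  zero <- svm_classifier(numeric(10), 0)
  pred <- predict_accuracy(zero, dat)
  expect_true(all(pred$labels == 1))
  expect_equal(pred$accuracy, mean(dat$labels == 1))
  # flipping every label complements the accuracy
  rc <- random_classifier(10, 7)
  flipped <- svm_dataset(dat$features, -dat$labels)
  expect_equal(predict_accuracy(rc, dat)$accuracy +
                 predict_accuracy(rc, flipped)$accuracy, 1)
  expect_error(predict_accuracy(rc, svm_dataset(matrix(0, 0, 10), numeric(0))),
               "empty")
})

test_that("prox operators match brute-force 1-D minimisation", {
  # frozen closed-form cases
  expect_equal(prox_regularizer(c(3, 0), 1, hyperparams(0, 1))[1], 2)
  expect_equal(prox_regularizer(c(0.5, 0), 1, hyperparams(0, 1))[1], 0)
  expect_equal(prox_regularizer(c(3, 0), 1, hyperparams(1, 1))[1], 1)
  expect_equal(prox_hinge_conjugate(0.5, 0.2), 0)
  expect_equal(prox_hinge_conjugate(-2, 0.1), -1)
  # bias slot passes through untouched
  expect_equal(prox_regularizer(c(5, -4), 2, hyperparams(3, 3))[2], -4)

  set.seed(20)
  # h*(u) = u on [-1, 0], +Inf elsewhere: prox = argmin over the box
  num_prox_hc <- function(v, sig) {
    stats::optimize(function(u) sig * u + 0.5 * (u - v)^2,
                    lower = -1, upper = 0, tol = 1e-12)$minimum
  }
  for (k in 1:60) {
    v <- rnorm(1, sd = 3)
    tau <- runif(1, 0.05, 4)
    hp <- hyperparams(runif(1, 0, 3), runif(1, 0, 3))
    f_reg <- function(u) hp$rho * abs(u) + 0.5 * hp$psi * u^2
    expect_lt(abs(prox_regularizer(c(v, 0), tau, hp)[1] -
                    num_prox(f_reg, v, tau)), 1e-7)
    sig <- runif(1, 0.05, 4)
    expect_lt(abs(prox_hinge_conjugate(v, sig) - num_prox_hc(v, sig)), 1e-7)
  }
})

test_that("Moreau identity ties the hinge prox to its conjugate", {
  set.seed(21)
  hinge <- function(y) max(0, 1 - y)
  for (k in 1:100) {
    v <- rnorm(1, sd = 3)
    sig <- runif(1, 0.05, 4)
    prox_h <- num_prox(hinge, v / sig, 1 / sig)
    expect_lt(abs(prox_hinge_conjugate(v, sig) + sig * prox_h - v), 1e-6)
  }
})

test_that("prox_regularizer is nonexpansive", {
  set.seed(22)
  hp <- hyperparams(0.8, 1.3)
  for (k in 1:50) {
    u <- rnorm(6, sd = 4); v <- rnorm(6, sd = 4)
    expect_lte(sqrt(sum((prox_regularizer(u, 0.7, hp) -
                           prox_regularizer(v, 0.7, hp))^2)),
               sqrt(sum((u - v)^2)) + 1e-12)
  }
})

test_that("margin operator encodes signed margins", {
  one <- svm_dataset(matrix(c(1, 2), 1), 1)
  expect_equal(margin_operator(one), matrix(c(1, 2, 1), 1),
               ignore_attr = TRUE)
  expect_equal(margin_operator(svm_dataset(matrix(c(1, 2), 1), -1)),
               matrix(c(-1, -2, -1), 1), ignore_attr = TRUE)

  # hinge through the operator equals hinge_losses
  dat <- make_instance(n = 35, seed = 9)
  A <- margin_operator(dat)
  for (s in 1:5) {
    clf <- random_classifier(10, s)
    expect_equal(sum(pmax(0, 1 - drop(A %*% c(clf$theta, clf$theta0)))),
                 sum(hinge_losses(clf, dat)), tolerance = 1e-12)
  }

  # margin-1 separable cohort: true rule clears margin 1 everywhere
  sep <- make_separable(n = 200, seed = 43)
  gt <- sep$ground_truth
  margins <- drop(margin_operator(sep) %*% c(gt$theta, gt$theta0))
  expect_true(all(margins >= 1 - 1e-9))
})

test_that("classifier JSON round-trips", {
  clf <- svm_classifier(c(0.25, -1.75, 0), 0.5, c("age", "bmi", "dx_1"))
  path <- withr::local_tempfile(fileext = ".json")
  write_classifier_json(clf, path)
  expect_equal(read_classifier_json(path), clf)
})
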