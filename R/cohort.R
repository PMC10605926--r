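# Synthetic EHR-like cohorts with a known sparse generating rule.
#
# The generator stands in for undisclosed hospital EHR data: a block of
# continuous features (age-, BMI-, vitals-like; standard normal, i.e. already
# scaled) and a block of 0/1 indicator features (diagnosis / medication
# history; Bernoulli with per-feature prevalence drawn uniformly from
# 0.05-0.5, mimicking the sparsity of coded diagnoses). Labels come from a
# sparse linear rule with independent label flips, so support recovery and
# accuracy can both be scored against a known truth.

continuous_name_pool <- c("age", "bmi", "height", "weight", "sbp", "dbp",
                          "heart_rate", "glucose", "cholesterol", "creatinine")

#' Specification of a synthetic EHR-like cohort
#'
#' @param n_samples number of patients.
#' @param n_continuous number of continuous (vitals-like) features.
#' @param n_binary number of 0/1 indicator (diagnosis-like) features.
#' @param sparsity number of nonzero entries of the ground-truth weight
#'   vector; at most `n_continuous + n_binary`.
#' @param signal_scale magnitude of each nonzero true weight.
#' @param label_noise probability in `[0, 0.5)` of flipping a generated label.
#' @param positive_fraction target pre-noise class balance in `(0, 1)`.
#' @param seed integer RNG seed; the generated cohort is a pure function of
#'   this spec.
#' @return an object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_samples = 1000, n_continuous = 10, n_binary = 10,
                        sparsity = 5, signal_scale = 1, label_noise = 0.05,
                        positive_fraction = 0.35, seed = 1) {
  spec <- list(
    n_samples = check_count(n_samples, "n_samples"),
    n_continuous = check_count(n_continuous, "n_continuous"),
    n_binary = check_count(n_binary, "n_binary"),
    sparsity = check_count(sparsity, "sparsity"),
    signal_scale = check_scalar(signal_scale, "signal_scale", lower = 0, open_lower = TRUE),
    label_noise = check_scalar(label_noise, "label_noise", lower = 0, upper = 0.5,
                               open_upper = TRUE),
    positive_fraction = check_scalar(positive_fraction, "positive_fraction",
                                     lower = 0, upper = 1,
                                     open_lower = TRUE, open_upper = TRUE),
    seed = check_count(seed, "seed", min = 0L)
  )
  if (spec$sparsity > spec$n_continuous + spec$n_binary) {
    stop_("sparsity (%d) exceeds the number of features (%d)",
          spec$sparsity, spec$n_continuous + spec$n_binary)
  }
  class(spec) <- "cohort_spec"
  spec
}

#' Generate a synthetic cohort
#'
#' Draws features, a sparse ground-truth rule `theta*` (exactly `sparsity`
#' nonzeros at positions sampled without replacement across both feature
#' blocks, magnitudes `+/- signal_scale`), tunes the true bias `theta0*` by
#' bisection (100 steps) so the pre-noise positive fraction lands within 0.02
#' of `positive_fraction`, then flips each label independently with
#' probability `label_noise`. The `ground_truth` element records `theta*`,
#' `theta0*`, the support, and the pre-noise labels.
#'
#' @param spec a [cohort_spec()].
#' @return an [svm_dataset()] with `ground_truth` attached.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  with_seed(spec$seed, {
    n <- spec$n_samples
    d <- spec$n_continuous + spec$n_binary
    Xc <- matrix(stats::rnorm(n * spec$n_continuous), n, spec$n_continuous)
    prevalence <- stats::runif(spec$n_binary, 0.05, 0.5)
    Xb <- matrix(stats::rbinom(n * spec$n_binary, 1L,
                               rep(prevalence, each = n)),
                 n, spec$n_binary)
    X <- cbind(Xc, Xb)
    cn <- c(continuous_name_pool, paste0("cont_", seq_len(max(0, spec$n_continuous - length(continuous_name_pool)))))
    feature_names <- c(cn[seq_len(spec$n_continuous)], paste0("dx_", seq_len(spec$n_binary)))

    support <- sort(sample.int(d, spec$sparsity))
    theta <- numeric(d)
    theta[support] <- spec$signal_scale * sample(c(-1, 1), spec$sparsity, replace = TRUE)

    z <- drop(X %*% theta)
    theta0 <- tune_bias_bisection(z, spec$positive_fraction)
    clean <- ifelse(z + theta0 >= 0, 1, -1)
    flips <- stats::runif(n) < spec$label_noise
    labels <- ifelse(flips, -clean, clean)

    svm_dataset(X, labels, feature_names,
                ground_truth = list(theta = theta, theta0 = theta0,
                                    support = support, clean_labels = clean))
  })
}

# bisection on the empirical CDF of the raw scores; fraction(theta0) is a
# nondecreasing step function, so 100 halvings pin theta0 to ~1e-28 of the
# initial bracket and any residual miss is pure label discreteness
tune_bias_bisection <- function(z, target, tol = 0.02, steps = 100L) {
  frac <- function(b) mean(z + b >= 0)
  lo <- -max(abs(z)) - 1
  hi <- max(abs(z)) + 1
  for (k in seq_len(steps)) {
    mid <- (lo + hi) / 2
    if (frac(mid) < target) lo <- mid else hi <- mid
  }
  b <- hi
  achieved <- frac(b)
  if (abs(achieved - target) > tol) {
    stop_("bias bisection failed: achieved positive fraction %.4f vs target %.4f",
          achieved, target)
  }
  b
}

#' Partition a dataset across agents
#'
#' `iid` shuffles rows and deals them into `m` near-equal contiguous parts
#' (sizes differ by at most 1). `label_skew` draws, for each class, a
#' Dirichlet(`skew_alpha`) allocation over agents and assigns that class's
#' samples multinomially -- the standard non-IID protocol; small
#' `skew_alpha` concentrates each class on few agents. If the draw leaves an
#' agent empty, one row is moved from the largest part so every agent holds
#' at least one sample. The union of parts is exactly the parent rows.
#'
#' @param data an [svm_dataset()].
#' @param m number of agents, `1 <= m <= n`.
#' @param mode `"iid"` or `"label_skew"`.
#' @param skew_alpha positive Dirichlet concentration (label_skew only).
#' @param seed RNG seed.
#' @return an object of class `agent_partition`: list with `parts` (a list of
#'   `m` datasets), `mode`, `skew_alpha`, and `indices` (row indices of each
#'   part in the parent).
#' @export
partition_agents <- function(data, m, mode = c("iid", "label_skew"),
                             skew_alpha = 0.5, seed = 1) {
  stopifnot(inherits(data, "svm_dataset"))
  mode <- match.arg(mode)
  m <- check_count(m, "m")
  n <- n_samples(data)
  if (m > n) stop_("cannot partition %d samples across %d agents", n, m)
  idx_parts <- with_seed(seed, {
    if (mode == "iid") {
      ord <- sample.int(n)
      sizes <- rep(n %/% m, m)
      extra <- n %% m
      if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
      unname(split(ord, rep(seq_len(m), times = sizes)))
    } else {
      skew_alpha <- check_scalar(skew_alpha, "skew_alpha", lower = 0, open_lower = TRUE)
      parts <- replicate(m, integer(0), simplify = FALSE)
      for (cls in c(-1, 1)) {
        rows <- which(data$labels == cls)
        if (!length(rows)) next
        rows <- rows[sample.int(length(rows))]
        g <- stats::rgamma(m, shape = skew_alpha)
        if (sum(g) == 0) g <- rep(1, m)
        assign_to <- sample.int(m, length(rows), replace = TRUE, prob = g / sum(g))
        for (j in seq_len(m)) parts[[j]] <- c(parts[[j]], rows[assign_to == j])
      }
      # repair empty agents deterministically from the largest part
      repeat {
        empty <- which(lengths(parts) == 0L)
        if (!length(empty)) break
        donor <- which.max(lengths(parts))
        parts[[empty[1]]] <- parts[[donor]][1]
        parts[[donor]] <- parts[[donor]][-1]
      }
      parts
    }
  })
  structure(list(parts = lapply(idx_parts, function(i) dataset_subset(data, i)),
                 indices = idx_parts, mode = mode,
                 skew_alpha = if (mode == "label_skew") skew_alpha else NA_real_),
            class = "agent_partition")
}

#' @export
print.agent_partition <- function(x, ...) {
  cat(sprintf("<agent_partition> %d agents (%s), sizes: %s\n",
              length(x$parts), x$mode,
              paste(vapply(x$parts, n_samples, 1L), collapse = ", ")))
  invisible(x)
}

#' Stratified train/test split
#'
#' Splits rows into disjoint, exhaustive train and test sets, stratified by
#' label (per-class test counts by largest-remainder rounding of
#' `test_fraction`), with the within-class order shuffled under `seed`.
#'
#' @param data an [svm_dataset()].
#' @param test_fraction fraction in `(0, 1)` assigned to the test set.
#' @param seed RNG seed.
#' @return list with elements `train` and `test`, both [svm_dataset()]s.
#' @export
train_test_split <- function(data, test_fraction, seed = 1) {
  stopifnot(inherits(data, "svm_dataset"))
  test_fraction <- check_scalar(test_fraction, "test_fraction", lower = 0, upper = 1,
                                open_lower = TRUE, open_upper = TRUE)
  n <- n_samples(data)
  n_test <- round(test_fraction * n)
  if (n_test < 1 || n - n_test < 1) {
    stop_("degenerate split: %d test / %d train samples", n_test, n - n_test)
  }
  with_seed(seed, {
    classes <- sort(unique(data$labels))
    quota <- vapply(classes, function(cl) test_fraction * sum(data$labels == cl), 0)
    take <- floor(quota)
    rem <- n_test - sum(take)
    if (rem > 0) {
      extra <- order(quota - take, decreasing = TRUE)[seq_len(rem)]
      take[extra] <- take[extra] + 1
    }
    test_idx <- integer(0)
    for (k in seq_along(classes)) {
      rows <- which(data$labels == classes[k])
      rows <- rows[sample.int(length(rows))]
      test_idx <- c(test_idx, rows[seq_len(take[k])])
    }
    test_idx <- sort(test_idx)
    list(train = dataset_subset(data, setdiff(seq_len(n), test_idx)),
         test = dataset_subset(data, test_idx))
  })
}
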