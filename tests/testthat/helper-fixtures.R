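# Shared fixtures, all generated in code (no stored data).

# small labelled instance with mixed feature blocks
make_instance <- function(n = 120, n_cont = 6, n_bin = 4, sparsity = 3,
                          label_noise = 0.05, positive_fraction = 0.4,
                          seed = 21) {
  generate_cohort(cohort_spec(n, n_cont, n_bin, sparsity = sparsity,
                              label_noise = label_noise,
                              positive_fraction = positive_fraction,
                              seed = seed))
}

# noiseless cohort filtered to a guaranteed margin around the true rule,
# then rescaled so every signed margin is >= 1
make_separable <- function(n = 300, n_cont = 10, n_bin = 5, sparsity = 5,
                           margin = 0.5, seed = 41) {
  big <- generate_cohort(cohort_spec(4 * n, n_cont, n_bin, sparsity = sparsity,
                                     signal_scale = 2, label_noise = 0,
                                     positive_fraction = 0.4, seed = seed))
  gt <- big$ground_truth
  z <- drop(big$features %*% gt$theta) + gt$theta0
  keep <- which(abs(z) >= margin)
  stopifnot(length(keep) >= n)
  keep <- keep[seq_len(n)]
  out <- svm_dataset(big$features[keep, , drop = FALSE], big$labels[keep],
                     big$feature_names,
                     ground_truth = list(theta = gt$theta / margin,
                                         theta0 = gt$theta0 / margin,
                                         support = gt$support))
  out
}

# brute-force 1-D proximal map by numerical minimisation (independent of the
# closed forms under test)
num_prox <- function(f, v, tau = 1) {
  half <- abs(v) + 10
  stats::optimize(function(u) tau * f(u) + 0.5 * (u - v)^2,
                  lower = v - half, upper = v + half, tol = 1e-12)$minimum
}

# multiset equality of dataset rows (features + label)
rows_signature <- function(data) {
  sort(apply(cbind(data$features, data$labels), 1, paste, collapse = "|"))
}

random_classifier <- function(d, seed) {
  set.seed(seed)
  svm_classifier(stats::rnorm(d), stats::rnorm(1))
}
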