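# Sparse soft-margin SVM: objective, predictions, and the proximal operators
# used by the splitting solvers.
#
# The model is the linear classifier sign(phi' theta + theta0) fitted by
#
#   min_{theta, theta0}  sum_i max(0, 1 - l_i (phi_i' theta + theta0))
#                        + 0.5 * psi * ||theta||_2^2 + rho * ||theta||_1
#
# The bias theta0 is never penalised.

#' Linear SVM classifier
#'
#' @param theta numeric weight vector (length `d`).
#' @param theta0 numeric bias scalar.
#' @param feature_names optional names for `theta`.
#' @return an object of class `svm_classifier`.
#' @export
svm_classifier <- function(theta, theta0, feature_names = NULL) {
  theta <- as.numeric(theta)
  if (!all(is.finite(theta)) || !is.finite(theta0)) stop_("classifier entries must be finite")
  if (!is.null(feature_names)) names(theta) <- feature_names
  structure(list(theta = theta, theta0 = as.numeric(theta0)),
            class = "svm_classifier")
}

#' @export
print.svm_classifier <- function(x, ...) {
  nz <- sum(abs(x$theta) > 1e-8)
  cat(sprintf("<svm_classifier> d = %d (%d nonzero), theta0 = %.4g\n",
              length(x$theta), nz, x$theta0))
  invisible(x)
}

#' Penalty hyperparameters for the sparse SVM
#'
#' `psi` is the ridge coefficient, `rho` the L1 (sparsity) coefficient.
#' `hyperparams_from_c_eps` converts from the constrained soft-margin
#' parameterisation `0.5||theta||^2 + c * sum(slacks) + eps * ||theta||_1`:
#' dividing that objective by `c` gives the penalty form with `psi = 1/c`,
#' `rho = eps/c`, so both share the same minimiser.
#'
#' @param psi nonnegative ridge coefficient.
#' @param rho nonnegative L1 coefficient.
#' @return an object of class `svm_hyperparams`.
#' @export
hyperparams <- function(psi, rho) {
  psi <- check_scalar(psi, "psi", lower = 0)
  rho <- check_scalar(rho, "rho", lower = 0)
  structure(list(psi = psi, rho = rho), class = "svm_hyperparams")
}

#' @rdname hyperparams
#' @param c positive slack-penalty coefficient of the constrained form.
#' @param eps nonnegative L1 coefficient of the constrained form.
#' @export
hyperparams_from_c_eps <- function(c, eps) {
  c <- check_scalar(c, "c", lower = 0, open_lower = TRUE)
  eps <- check_scalar(eps, "eps", lower = 0)
  hyperparams(psi = 1 / c, rho = eps / c)
}

margins_of <- function(clf, data) {
  if (length(clf$theta) != n_features(data)) {
    stop_("classifier has %d weights but data has %d features",
          length(clf$theta), n_features(data))
  }
  drop(data$features %*% clf$theta) + clf$theta0
}

#' Per-sample hinge losses
#'
#' Returns `max(0, 1 - l_i * (phi_i' theta + theta0))` for every sample.
#'
#' @param clf an [svm_classifier()].
#' @param data an [svm_dataset()].
#' @return nonnegative numeric vector of length `n`.
#' @export
hinge_losses <- function(clf, data) {
  pmax(0, 1 - data$labels * margins_of(clf, data))
}

#' Sparse-SVM objective value
#'
#' `sum(hinge) + 0.5 * psi * ||theta||_2^2 + rho * ||theta||_1`; the bias is
#' not penalised.
#'
#' @inheritParams hinge_losses
#' @param hp an [hyperparams()] object.
#' @return nonnegative scalar.
#' @export
svm_objective <- function(clf, data, hp) {
  stopifnot(inherits(hp, "svm_hyperparams"))
  sum(hinge_losses(clf, data)) +
    0.5 * hp$psi * sum(clf$theta^2) + hp$rho * sum(abs(clf$theta))
}

#' Predict labels and accuracy
#'
#' Predicted label is `sign(phi' theta + theta0)` with the deterministic tie
#' rule `sign(0) = +1`.
#'
#' @inheritParams hinge_losses
#' @return list with `labels` (a `-1`/`+1` vector) and `accuracy` in `[0, 1]`.
#' @export
predict_accuracy <- function(clf, data) {
  if (n_samples(data) == 0L) stop_("cannot predict on an empty dataset")
  pred <- ifelse(margins_of(clf, data) >= 0, 1, -1)
  list(labels = pred, accuracy = mean(pred == data$labels))
}

#' @export
predict.svm_classifier <- function(object, newdata, ...) {
  ifelse(margins_of(object, newdata) >= 0, 1, -1)
}

soft_threshold <- function(x, t) sign(x) * pmax(abs(x) - t, 0)

#' Proximal operator of the elastic-net regulariser (bias unpenalised)
#'
#' For a stacked vector `u = (weights, bias)` returns the prox of
#' `tau * (rho * ||.||_1 + 0.5 * psi * ||.||_2^2)` applied to the weight
#' coordinates -- the closed form `soft(u, tau * rho) / (1 + tau * psi)` --
#' while the final (bias) coordinate passes through unchanged.
#'
#' @param u numeric vector whose last entry is the bias slot.
#' @param tau positive step size.
#' @param hp an [hyperparams()] object.
#' @return numeric vector of the same length.
#' @export
prox_regularizer <- function(u, tau, hp) {
  tau <- check_scalar(tau, "tau", lower = 0, open_lower = TRUE)
  stopifnot(inherits(hp, "svm_hyperparams"))
  p <- length(u)
  out <- u
  w <- u[-p]
  out[-p] <- soft_threshold(w, tau * hp$rho) / (1 + tau * hp$psi)
  out
}

#' Proximal operator of the hinge-loss convex conjugate
#'
#' The conjugate of `h(y) = max(0, 1 - y)` is `h*(u) = u` on `[-1, 0]` and
#' `+Inf` elsewhere, so `prox_{sigma h*}(v) = clip(v - sigma, -1, 0)`.
#' `sigma` may be a vector (per-coordinate step), as used when per-sample
#' scalings are folded into the dual update.
#'
#' @param v numeric vector.
#' @param sigma positive step size, scalar or vector recycled against `v`.
#' @return numeric vector with entries in `[-1, 0]`.
#' @export
prox_hinge_conjugate <- function(v, sigma) {
  if (any(sigma <= 0)) stop_("`sigma` must be positive")
  pmin(pmax(v - sigma, -1), 0)
}

#' Signed margin operator
#'
#' The `n x (d+1)` matrix `A` with row `i` equal to `l_i * [phi_i', 1]`, so
#' that `A %*% c(theta, theta0)` gives the margins `l_i (phi_i' theta +
#' theta0)`. This is the linear operator the splitting solver dualises.
#'
#' @param data an [svm_dataset()].
#' @return numeric matrix with `n` rows and `d + 1` columns.
#' @export
margin_operator <- function(data) {
  if (n_samples(data) == 0L) stop_("empty dataset")
  data$labels * cbind(data$features, 1, deparse.level = 0)
}

#' Serialise a classifier to JSON
#'
#' @param clf an [svm_classifier()].
#' @param path file path.
#' @return `write_classifier_json` returns `path` invisibly;
#'   `read_classifier_json` returns an [svm_classifier()].
#' @export
write_classifier_json <- function(clf, path) {
  stopifnot(inherits(clf, "svm_classifier"))
  obj <- list(theta = unname(clf$theta), theta0 = clf$theta0,
              feature_names = names(clf$theta))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_classifier_json
#' @export
read_classifier_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  svm_classifier(obj$theta, obj$theta0, feature_names = obj$feature_names)
}
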