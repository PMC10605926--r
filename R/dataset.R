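#' Construct a labelled classification dataset
#'
#' Bundles an `n x d` numeric feature matrix with a length-`n` label vector in
#' `{-1, +1}`, the common currency of every solver in the package. Rows are
#' patients (samples), columns are features.
#'
#' @param features numeric matrix, one row per sample; no missing values.
#' @param labels numeric vector of `-1`/`+1` labels, length `nrow(features)`.
#' @param feature_names optional character vector of column names; defaults to
#'   existing column names or `f1..fd`.
#' @param ground_truth optional list with elements `theta`, `theta0` and
#'   `support` describing the generating linear rule (kept by the synthetic
#'   cohort generator so support-recovery can be scored).
#' @return an object of class `svm_dataset`: a list with elements `features`,
#'   `labels`, `feature_names` and (optionally) `ground_truth`.
#' @seealso [generate_cohort()], [read_dataset_csv()]
#' @export
svm_dataset <- function(features, labels, feature_names = NULL, ground_truth = NULL) {
  features <- as.matrix(features)
  storage.mode(features) <- "double"
  labels <- as.numeric(labels)
  if (nrow(features) != length(labels)) {
    stop_("features has %d rows but labels has length %d", nrow(features), length(labels))
  }
  if (anyNA(features) || anyNA(labels)) stop_("missing values are not allowed")
  if (!all(labels %in% c(-1, 1))) stop_("labels must all be -1 or +1")
  if (is.null(feature_names)) {
    feature_names <- colnames(features)
    if (is.null(feature_names)) feature_names <- paste0("f", seq_len(ncol(features)))
  }
  if (length(feature_names) != ncol(features)) {
    stop_("feature_names has length %d but there are %d columns",
          length(feature_names), ncol(features))
  }
  colnames(features) <- feature_names
  out <- list(features = features, labels = labels,
              feature_names = as.character(feature_names))
  if (!is.null(ground_truth)) out$ground_truth <- ground_truth
  class(out) <- "svm_dataset"
  out
}

#' @export
print.svm_dataset <- function(x, ...) {
  cat(sprintf("<svm_dataset> %d samples x %d features; positive fraction %.3f\n",
              nrow(x$features), ncol(x$features), mean(x$labels == 1)))
  if (!is.null(x$ground_truth)) {
    cat(sprintf("  ground truth: %d nonzero weights\n", length(x$ground_truth$support)))
  }
  invisible(x)
}

n_samples <- function(data) nrow(data$features)
n_features <- function(data) ncol(data$features)

dataset_subset <- function(data, idx) {
  svm_dataset(data$features[idx, , drop = FALSE], data$labels[idx],
              data$feature_names, data$ground_truth)
}

#' Write / read a dataset as CSV
#'
#' The on-disk format is a plain UTF-8 CSV with a header row: one column per
#' feature followed by a final `label` column holding `-1`/`1`. Floats are
#' written with 15 significant digits so a write/read cycle round-trips to
#' well beyond 12 significant digits; labels round-trip exactly.
#'
#' @param data an [svm_dataset()].
#' @param path file path.
#' @return `write_dataset_csv` returns `path` invisibly; `read_dataset_csv`
#'   returns an [svm_dataset()].
#' @export
write_dataset_csv <- function(data, path) {
  stopifnot(inherits(data, "svm_dataset"))
  df <- data.table::as.data.table(data$features)
  df[["label"]] <- as.integer(data$labels)
  data.table::fwrite(df, path)
  invisible(path)
}

#' @rdname write_dataset_csv
#' @export
read_dataset_csv <- function(path) {
  df <- data.table::fread(path, data.table = FALSE)
  if (!("label" %in% names(df))) stop_("no `label` column in %s", path)
  lab <- df[["label"]]
  feats <- as.matrix(df[, setdiff(names(df), "label"), drop = FALSE])
  svm_dataset(feats, lab)
}
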