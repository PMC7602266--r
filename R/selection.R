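# Permutation feature importance over the ten window features.

# Stratified train/test split of trial indices by label.
stratified_split <- function(labels, train_fraction = 0.8) {
  idx <- split(seq_along(labels), labels)
  train <- unlist(lapply(idx, function(i) {
    n_train <- max(1L, floor(length(i) * train_fraction))
    if (length(i) > 1L) sample(i, n_train) else i
  }), use.names = FALSE)
  sort(train)
}

#' Permutation feature importance
#'
#' Trains a classifier on a stratified 80/20 split of the trials (all
#' features present), then measures, for each feature, the drop in held-out
#' accuracy when that feature's values are shuffled across the held-out
#' trials -- jointly over all channels and windows of a trial, so temporal
#' structure within a trial is preserved. The shuffle is repeated
#' `n_repeats` times and accuracies averaged. Importance is
#' `baseline - mean(permuted)` exactly; a feature the labels do not depend on
#' has importance near zero, and permuting a constant feature changes
#' nothing.
#'
#' @param series_list List of `feature_series` (one per trial) containing the
#'   features to score; all trials must share window/channel/feature dims.
#' @param classifier_factory Function `sequence_dataset -> emg_classifier`;
#'   defaults to the deterministic centroid classifier.
#' @param n_repeats Number of shuffles per feature (default 10).
#' @param seed Seed controlling the split and the shuffles; the report is
#'   bit-reproducible given the seed.
#' @param train_fraction Fraction of trials (per motion) used for training.
#' @return An `importance_report`: `baseline_accuracy`, named
#'   `permuted_accuracy` and `importance` vectors, the per-repeat accuracy
#'   matrix `repeat_accuracy` (repeats x features), `features`, `n_repeats`,
#'   `seed`.
#' @export
permutation_importance <- function(series_list,
                                   classifier_factory = function(ds) train_classifier(ds, "centroid"),
                                   n_repeats = 10L, seed = 1L,
                                   train_fraction = 0.8) {
  labels <- vapply(series_list, `[[`, character(1), "motion_label")
  if (length(unique(labels)) < 2L) {
    stop("permutation importance requires at least two classes", call. = FALSE)
  }
  feats <- series_list[[1]]$feature_set
  with_seed(seed, {
    train_idx <- stratified_split(labels, train_fraction)
    test_idx <- setdiff(seq_along(series_list), train_idx)
    if (length(test_idx) == 0L) {
      stop("no held-out trials; lower train_fraction", call. = FALSE)
    }
    classifier <- classifier_factory(build_sequences(series_list[train_idx]))
    test_series <- series_list[test_idx]
    test_ds <- build_sequences(test_series)
    baseline <- evaluate_classifier(classifier, test_ds)$overall
    repeat_acc <- vapply(feats, function(f) {
      vapply(seq_len(n_repeats), function(r) {
        perm <- sample(length(test_series))
        shuffled <- lapply(seq_along(test_series), function(i) {
          s <- test_series[[i]]
          s$values[, , f] <- test_series[[perm[i]]]$values[, , f]
          s
        })
        evaluate_classifier(classifier, build_sequences(shuffled))$overall
      }, numeric(1))
    }, numeric(n_repeats))
    repeat_acc <- matrix(repeat_acc, nrow = n_repeats,
                         dimnames = list(NULL, feats))
    permuted <- colMeans(repeat_acc)
    structure(
      list(baseline_accuracy = baseline,
           features = feats,
           permuted_accuracy = permuted,
           importance = baseline - permuted,
           repeat_accuracy = repeat_acc,
           n_repeats = as.integer(n_repeats),
           seed = as.integer(seed)),
      class = "importance_report"
    )
  })
}

#' @export
print.importance_report <- function(x, ...) {
  cat(sprintf("<importance_report> baseline accuracy %.3f, %d repeats\n",
              x$baseline_accuracy, x$n_repeats))
  print(importance_table(x))
  invisible(x)
}

#' Importance report as a table
#'
#' @param report An `importance_report`.
#' @return data.frame with columns feature, permuted_accuracy, importance.
#' @export
importance_table <- function(report) {
  data.frame(feature = report$features,
             permuted_accuracy = unname(report$permuted_accuracy[report$features]),
             importance = unname(report$importance[report$features]),
             stringsAsFactors = FALSE)
}

#' Select the top-k features by importance
#'
#' Orders features by importance (descending); ties are broken by the
#' canonical [feature_names()] order for determinism.
#'
#' @param report An `importance_report` (or any list with `features` and
#'   `importance` fields).
#' @param k Number of features to keep, `1 <= k <= length(features)`.
#' @return Character vector of `k` feature names, importance-sorted.
#' @export
select_features <- function(report, k) {
  k <- as.integer(k)
  feats <- report$features
  if (k < 1L) stop("k must be >= 1", call. = FALSE)
  if (k > length(feats)) {
    stop(sprintf("k = %d exceeds the %d available features", k, length(feats)),
         call. = FALSE)
  }
  imp <- report$importance[feats]
  canon <- match(feats, feature_names())
  ord <- order(-imp, canon)
  feats[ord][seq_len(k)]
}
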