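make_separable_ds <- function(n_per_class = 20, T_len = 3, D = 8, sep = 3,
                              classes = c("A", "B", "C"), seed = 3) {
  withr::with_seed(seed, {
    seqs <- list(); labels <- character(0)
    for (k in seq_along(classes)) {
      mu <- rep(0, D); mu[k] <- sep
      for (i in seq_len(n_per_class)) {
        seqs[[length(seqs) + 1]] <-
          matrix(rnorm(T_len * D, mean = rep(mu, each = T_len), sd = 0.5),
                 T_len, D)
        labels <- c(labels, classes[k])
      }
    }
    sequence_dataset(seqs, labels)
  })
}

test_that("LSTM gradients match finite differences", {
  ds <- make_separable_ds(n_per_class = 3, T_len = 2, D = 3, seed = 9)
  classes <- sort(unique(ds$labels))
  arr <- emgsign:::stack_sequences(ds)
  onehot <- outer(ds$labels, classes, `==`) * 1
  H <- 4
  set.seed(10)
  weights <- list(
    Wx = matrix(rnorm(3 * 4 * H, sd = 0.3), 3, 4 * H),
    Wh = matrix(rnorm(H * 4 * H, sd = 0.3), H, 4 * H),
    b = matrix(rnorm(4 * H, sd = 0.1), 1, 4 * H),
    Wy = matrix(rnorm(H * 3, sd = 0.3), H, 3),
    by = matrix(0, 1, 3)
  )
  fwd <- emgsign:::lstm_forward(weights, arr, H)
  grads <- emgsign:::lstm_backward(weights, arr, fwd, onehot, H)
  loss_at <- function(w) {
    f <- emgsign:::lstm_forward(w, arr, H)
    emgsign:::lstm_loss(f$probs, onehot)
  }
  eps <- 1e-6
  for (nm in names(weights)) {
    idx <- cbind(sample(nrow(weights[[nm]]), 3, replace = TRUE),
                 sample(ncol(weights[[nm]]), 3, replace = TRUE))
    for (r in seq_len(nrow(idx))) {
      wp <- weights; wm <- weights
      wp[[nm]][idx[r, 1], idx[r, 2]] <- wp[[nm]][idx[r, 1], idx[r, 2]] + eps
      wm[[nm]][idx[r, 1], idx[r, 2]] <- wm[[nm]][idx[r, 1], idx[r, 2]] - eps
      fd <- (loss_at(wp) - loss_at(wm)) / (2 * eps)
      an <- grads[[nm]][idx[r, 1], idx[r, 2]]
      expect_equal(an, fd, tolerance = 1e-4)
    }
  }
})

test_that("LSTM training separates separable sequence classes", {
  ds <- make_separable_ds()
  cl <- train_classifier(ds, "lstm", train_config())
  expect_gte(evaluate_classifier(cl, ds)$overall, 0.95)
  # loss trends downward
  expect_lt(utils::tail(cl$loss_history, 1), cl$loss_history[1])
  # determinism: same seed, identical final weights
  cl2 <- train_classifier(ds, "lstm", train_config())
  expect_identical(cl$weights, cl2$weights)
})

test_that("classifiers reject single-class training data", {
  ds <- sequence_dataset(lapply(1:4, function(i) matrix(rnorm(6), 2, 3)),
                         rep("A", 4))
  expect_error(train_classifier(ds, "centroid"), "two classes")
  expect_error(train_classifier(ds, "lstm"), "two classes")
})

subset_dataset_for_test <- function(ds, idx) {
  sequence_dataset(ds$sequences[idx], ds$labels[idx], ds$subjects[idx])
}

test_that("prediction scores normalize and follow sample order", {
  ds <- make_separable_ds(n_per_class = 10, seed = 4)
  for (kind in c("centroid", "lstm")) {
    cfg <- train_config(learning_rate = 0.01, iterations = 50, hidden_size = 8)
    cl <- train_classifier(ds, kind, cfg)
    pred <- predict_classifier(cl, ds)
    expect_equal(rowSums(pred$scores), rep(1, length(ds$sequences)),
                 tolerance = 1e-10)
    perm <- sample(length(ds$sequences))
    pred_p <- predict_classifier(cl, subset_dataset_for_test(ds, perm))
    expect_identical(pred_p$labels, pred$labels[perm])
  }
})

test_that("evaluation results reconcile counts and accuracies", {
  ds <- make_separable_ds(n_per_class = 15, sep = 5, seed = 6)
  cl <- train_classifier(ds, "centroid")
  ev <- evaluate_classifier(cl, ds)
  expect_equal(rowSums(ev$confusion), table(ds$labels)[rownames(ev$confusion)],
               ignore_attr = TRUE)
  expect_equal(ev$overall, sum(diag(ev$confusion)) / ev$n)
  # perfect separation gives an identity-structured confusion matrix
  expect_equal(ev$overall, 1)
  expect_true(all(ev$confusion[upper.tri(ev$confusion)] == 0))
  expect_equal(unname(ev$per_motion), rep(1, 3))
})

test_that("sequence construction flattens channels x features", {
  set.seed(8)
  feats <- c("RMS", "LOG", "AAC", "PSR", "MNP", "MDF")
  mk <- function(nw) structure(
    list(subject_id = "S01", motion_label = "M1", trial_index = 0L,
         values = array(rnorm(nw * 8 * 6), c(nw, 8, 6),
                        dimnames = list(NULL, NULL, feats)),
         feature_set = feats),
    class = "feature_series"
  )
  ds <- build_sequences(list(mk(3), mk(3)))
  expect_equal(ds$n_dims, 48)
  expect_equal(nrow(ds$sequences[[1]]), 3)
  ds1 <- build_sequences(list(mk(1)))
  expect_equal(nrow(ds1$sequences[[1]]), 1)
  # channel index varies fastest along the flattened axis
  fs <- mk(2)
  ds2 <- build_sequences(list(fs))
  expect_equal(ds2$sequences[[1]][2, 8 + 3], unname(fs$values[2, 3, "LOG"]))
  expect_error(
    sequence_dataset(list(matrix(0, 2, 3), matrix(0, 2, 4)), c("A", "B")),
    "same number of dimensions"
  )
})

test_that("label-shuffled data scores at chance level", {
  ds <- make_separable_ds(n_per_class = 30, seed = 12)
  shuffled <- withr::with_seed(99, sequence_dataset(
    ds$sequences, sample(ds$labels), ds$subjects
  ))
  cl <- train_classifier(shuffled, "centroid")
  ev <- evaluate_classifier(cl, shuffled)
  # within 3 standard errors of 1/M for M = 3 classes
  n <- length(shuffled$sequences)
  se <- sqrt((1 / 3) * (2 / 3) / n)
  expect_lt(abs(ev$overall - 1 / 3), 3 * se + 0.1)
})
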