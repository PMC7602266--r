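# Sequence classifiers over per-trial feature / motion-factor sequences.
#
# Two classifiers share one interface: a single-layer LSTM (final-step
# readout, softmax output, full-batch Adam) and a deterministic
# nearest-centroid fallback on time-averaged sequences. The fallback has no
# training variance, which makes ordering comparisons between pipelines
# independent of neural-network optimization noise.

#' Bundle per-trial sequences into a classification dataset
#'
#' @param sequences List of numeric matrices, one per trial, each
#'   `n_steps x n_dims` (time steps are sliding windows). `n_dims` must be
#'   constant across trials.
#' @param labels Character/factor vector of motion labels, one per trial.
#' @param subjects Character vector of subject ids, one per trial.
#' @return A `sequence_dataset` list.
#' @export
sequence_dataset <- function(sequences, labels, subjects = rep(NA_character_, length(sequences))) {
  if (length(sequences) == 0L) stop("no sequences", call. = FALSE)
  sequences <- lapply(sequences, function(s) {
    s <- as.matrix(s)
    if (nrow(s) < 1L) stop("sequences need at least one time step", call. = FALSE)
    if (any(!is.finite(s))) stop("sequences must be finite", call. = FALSE)
    s
  })
  dims <- vapply(sequences, ncol, integer(1))
  if (length(unique(dims)) != 1L) {
    stop("all sequences must share the same number of dimensions", call. = FALSE)
  }
  if (length(labels) != length(sequences) || length(subjects) != length(sequences)) {
    stop("labels/subjects length must match sequences", call. = FALSE)
  }
  structure(
    list(sequences = sequences, labels = as.character(labels),
         subjects = as.character(subjects), n_dims = dims[1]),
    class = "sequence_dataset"
  )
}

subset_dataset <- function(ds, idx) {
  sequence_dataset(ds$sequences[idx], ds$labels[idx], ds$subjects[idx])
}

#' Build sequence samples from extracted features
#'
#' Flattens each trial's feature array (windows x channels x features) into a
#' `n_windows x (channels*features)` sequence, channels varying fastest.
#'
#' @param series_list List of `feature_series` from [extract_features()].
#' @return A [sequence_dataset()].
#' @export
build_sequences <- function(series_list) {
  seqs <- lapply(series_list, function(fs) {
    d <- dim(fs$values)
    matrix(fs$values, nrow = d[1], ncol = d[2] * d[3])
  })
  sequence_dataset(
    seqs,
    labels = vapply(series_list, `[[`, character(1), "motion_label"),
    subjects = vapply(series_list, `[[`, character(1), "subject_id")
  )
}

#' Training configuration for the LSTM classifier
#'
#' @param learning_rate Adam step size (default 1e-4).
#' @param iterations Number of full-batch training epochs (default 500).
#' @param hidden_size LSTM hidden state width (default 64).
#' @param seed Seed for the weight initialization.
#' @return A `train_config` list.
#' @export
train_config <- function(learning_rate = 1e-4, iterations = 500L,
                         hidden_size = 64L, seed = 1L) {
  stopifnot_scalar_number(learning_rate, "learning_rate", positive = TRUE)
  iterations <- as.integer(iterations)
  if (iterations < 1L) stop("iterations must be >= 1", call. = FALSE)
  list(learning_rate = learning_rate, iterations = iterations,
       hidden_size = as.integer(hidden_size), seed = as.integer(seed))
}

sigmoid <- function(x) 1 / (1 + exp(-x))

softmax_rows <- function(x) {
  x <- x - apply(x, 1L, max)
  e <- exp(x)
  e / rowSums(e)
}

# Stack a dataset's sequences into a T x B x D array (requires equal T).
stack_sequences <- function(ds) {
  Ts <- vapply(ds$sequences, nrow, integer(1))
  if (length(unique(Ts)) != 1L) {
    stop("LSTM training requires equal-length sequences", call. = FALSE)
  }
  T_len <- Ts[1]; B <- length(ds$sequences); D <- ds$n_dims
  arr <- array(0, dim = c(T_len, B, D))
  for (b in seq_len(B)) arr[, b, ] <- ds$sequences[[b]]
  arr
}

lstm_forward <- function(weights, arr, hidden) {
  T_len <- dim(arr)[1]; B <- dim(arr)[2]
  H <- hidden
  Hs <- vector("list", T_len + 1L)
  Cs <- vector("list", T_len + 1L)
  gates <- vector("list", T_len)
  Hs[[1]] <- matrix(0, B, H); Cs[[1]] <- matrix(0, B, H)
  idx <- list(i = 1:H, f = (H + 1):(2 * H), g = (2 * H + 1):(3 * H),
              o = (3 * H + 1):(4 * H))
  for (t in seq_len(T_len)) {
    Xt <- matrix(arr[t, , ], nrow = B)
    A <- Xt %*% weights$Wx + Hs[[t]] %*% weights$Wh +
      matrix(weights$b, B, 4 * H, byrow = TRUE)
    i <- sigmoid(A[, idx$i, drop = FALSE])
    f <- sigmoid(A[, idx$f, drop = FALSE])
    g <- tanh(A[, idx$g, drop = FALSE])
    o <- sigmoid(A[, idx$o, drop = FALSE])
    Cs[[t + 1L]] <- f * Cs[[t]] + i * g
    Hs[[t + 1L]] <- o * tanh(Cs[[t + 1L]])
    gates[[t]] <- list(i = i, f = f, g = g, o = o)
  }
  logits <- Hs[[T_len + 1L]] %*% weights$Wy +
    matrix(weights$by, B, length(weights$by), byrow = TRUE)
  list(Hs = Hs, Cs = Cs, gates = gates, logits = logits,
       probs = softmax_rows(logits))
}

lstm_backward <- function(weights, arr, fwd, onehot, hidden) {
  T_len <- dim(arr)[1]; B <- dim(arr)[2]
  H <- hidden
  grads <- list(Wx = 0 * weights$Wx, Wh = 0 * weights$Wh, b = 0 * weights$b,
                Wy = 0 * weights$Wy, by = 0 * weights$by)
  dlogits <- (fwd$probs - onehot) / B
  grads$Wy <- t(fwd$Hs[[T_len + 1L]]) %*% dlogits
  grads$by <- matrix(colSums(dlogits), nrow = 1)
  dH <- dlogits %*% t(weights$Wy)
  dC <- matrix(0, B, H)
  for (t in rev(seq_len(T_len))) {
    g <- fwd$gates[[t]]
    tc <- tanh(fwd$Cs[[t + 1L]])
    do_ <- dH * tc
    dC <- dC + dH * g$o * (1 - tc^2)
    di <- dC * g$g
    dg <- dC * g$i
    df <- dC * fwd$Cs[[t]]
    dC_prev <- dC * g$f
    dA <- cbind(di * g$i * (1 - g$i),
                df * g$f * (1 - g$f),
                dg * (1 - g$g^2),
                do_ * g$o * (1 - g$o))
    Xt <- matrix(arr[t, , ], nrow = B)
    grads$Wx <- grads$Wx + t(Xt) %*% dA
    grads$Wh <- grads$Wh + t(fwd$Hs[[t]]) %*% dA
    grads$b <- grads$b + matrix(colSums(dA), nrow = 1)
    dH <- dA %*% t(weights$Wh)
    dC <- dC_prev
  }
  grads
}

lstm_loss <- function(probs, onehot) {
  -mean(log(pmax(rowSums(probs * onehot), .Machine$double.xmin)))
}

train_lstm <- function(ds, config) {
  classes <- sort(unique(ds$labels))
  K <- length(classes)
  arr <- stack_sequences(ds)
  D <- ds$n_dims
  H <- config$hidden_size
  onehot <- outer(ds$labels, classes, `==`) * 1
  r_in <- 1 / sqrt(max(D, 1)); r_h <- 1 / sqrt(H)
  weights <- with_seed(config$seed, {
    w <- list(
      Wx = matrix(stats::runif(D * 4 * H, -r_in, r_in), D, 4 * H),
      Wh = matrix(stats::runif(H * 4 * H, -r_h, r_h), H, 4 * H),
      b = matrix(0, 1, 4 * H),
      Wy = matrix(stats::runif(H * K, -r_h, r_h), H, K),
      by = matrix(0, 1, K)
    )
    w$b[1, (H + 1):(2 * H)] <- 1  # forget-gate bias: retain memory early on
    w
  })
  m <- lapply(weights, function(x) 0 * x)
  v <- lapply(weights, function(x) 0 * x)
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  loss_history <- numeric(config$iterations)
  for (it in seq_len(config$iterations)) {
    fwd <- lstm_forward(weights, arr, H)
    loss <- lstm_loss(fwd$probs, onehot)
    if (!is.finite(loss)) {
      stop(sprintf("LSTM training diverged (non-finite loss at epoch %d); lower the learning rate", it),
           call. = FALSE)
    }
    loss_history[it] <- loss
    grads <- lstm_backward(weights, arr, fwd, onehot, H)
    for (nm in names(weights)) {
      m[[nm]] <- beta1 * m[[nm]] + (1 - beta1) * grads[[nm]]
      v[[nm]] <- beta2 * v[[nm]] + (1 - beta2) * grads[[nm]]^2
      mhat <- m[[nm]] / (1 - beta1^it)
      vhat <- v[[nm]] / (1 - beta2^it)
      weights[[nm]] <- weights[[nm]] -
        config$learning_rate * mhat / (sqrt(vhat) + eps)
    }
  }
  list(weights = weights, classes = classes, loss_history = loss_history)
}

#' Train a sequence classifier
#'
#' @param ds A [sequence_dataset()] with at least two classes.
#' @param kind `"lstm"` (single-layer LSTM, final-step softmax readout,
#'   full-batch Adam) or `"centroid"` (deterministic nearest class centroid
#'   on time-averaged sequences).
#' @param config A [train_config()]; ignored by the centroid classifier.
#' @return An `emg_classifier` with fields `kind`, `classes`, `weights`,
#'   `config` and (LSTM only) `loss_history`.
#' @export
train_classifier <- function(ds, kind = c("centroid", "lstm"),
                             config = train_config()) {
  stopifnot(inherits(ds, "sequence_dataset"))
  kind <- match.arg(kind)
  classes <- sort(unique(ds$labels))
  if (length(classes) < 2L) {
    stop("training requires at least two classes", call. = FALSE)
  }
  if (kind == "centroid") {
    means <- t(vapply(ds$sequences, colMeans, numeric(ds$n_dims)))
    centroids <- do.call(rbind, lapply(classes, function(cl) {
      colMeans(means[ds$labels == cl, , drop = FALSE])
    }))
    out <- list(kind = "centroid", classes = classes,
                weights = list(centroids = centroids),
                config = list())
  } else {
    fit <- train_lstm(ds, config)
    out <- list(kind = "lstm", classes = fit$classes, weights = fit$weights,
                config = config, loss_history = fit$loss_history)
  }
  structure(out, class = "emg_classifier")
}

#' Predict motion labels for sequence samples
#'
#' @param classifier An `emg_classifier` from [train_classifier()].
#' @param ds A [sequence_dataset()].
#' @return List with `labels` (character) and `scores` (matrix, one row per
#'   sample, columns named by class, rows summing to 1).
#' @export
predict_classifier <- function(classifier, ds) {
  stopifnot(inherits(classifier, "emg_classifier"),
            inherits(ds, "sequence_dataset"))
  if (classifier$kind == "centroid") {
    cen <- classifier$weights$centroids
    if (ncol(cen) != ds$n_dims) {
      stop("dimension mismatch between classifier and data", call. = FALSE)
    }
    means <- t(vapply(ds$sequences, colMeans, numeric(ds$n_dims)))
    d2 <- outer(rowSums(means^2), rep(1, nrow(cen))) -
      2 * means %*% t(cen) + outer(rep(1, nrow(means)), rowSums(cen^2))
    scale <- stats::median(d2)
    if (!is.finite(scale) || scale <= 0) scale <- 1
    scores <- softmax_rows(-d2 / scale)
  } else {
    H <- ncol(classifier$weights$Wh) %/% 4L
    arr <- stack_sequences(ds)
    fwd <- lstm_forward(classifier$weights, arr, H)
    scores <- fwd$probs
  }
  colnames(scores) <- classifier$classes
  labels <- classifier$classes[max.col(scores, ties.method = "first")]
  list(labels = labels, scores = scores)
}

#' Evaluate a classifier on labeled samples
#'
#' @param classifier An `emg_classifier`.
#' @param ds A labeled [sequence_dataset()].
#' @param classes Optional full class set for the confusion matrix rows and
#'   columns (defaults to the union of truth and classifier classes).
#' @return An `eval_result`: `confusion` (actual x predicted counts),
#'   `per_motion` and `per_subject` accuracy vectors, `overall` accuracy and
#'   `n` samples.
#' @export
evaluate_classifier <- function(classifier, ds, classes = NULL) {
  pred <- predict_classifier(classifier, ds)
  eval_predictions(ds$labels, pred$labels, ds$subjects, classes)
}

# Assemble an eval_result from truth/prediction vectors.
eval_predictions <- function(truth, predicted, subjects = NULL, classes = NULL) {
  classes <- classes %||% sort(unique(c(truth, predicted)))
  confusion <- table(factor(truth, levels = classes),
                     factor(predicted, levels = classes))
  confusion <- unclass(confusion)
  names(dimnames(confusion)) <- c("actual", "predicted")
  per_motion <- diag(confusion) / pmax(rowSums(confusion), 1L)
  per_subject <- if (!is.null(subjects) && !all(is.na(subjects))) {
    vapply(split(truth == predicted, subjects), mean, numeric(1))
  } else {
    NULL
  }
  structure(
    list(confusion = confusion, per_motion = per_motion,
         per_subject = per_subject,
         overall = mean(truth == predicted), n = length(truth)),
    class = "eval_result"
  )
}

#' @export
print.eval_result <- function(x, ...) {
  cat(sprintf("<eval_result> overall accuracy %.3f on %d samples, %d classes\n",
              x$overall, x$n, nrow(x$confusion)))
  invisible(x)
}
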