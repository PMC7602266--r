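# Bilinear user x motion factorization of stacked EMG feature matrices.
#
# Model: a single value for channel c, user u, motion m, repetition n is
#   y_{c,n}^{u,m} = z_u' W_c x_n^m
# with z_u in R^I the user factor, x_n^m in R^J the motion factor and W_c an
# I x J per-channel interaction matrix. Collected over a cohort this reads
#   Y = [W^ST Z]^ST X,   equivalently   Y^ST = [W X]^ST Z,
# where Y is the (C*U) x (M*N) stacked data matrix with C channel blocks
# (rows within a block are users), columns ordered motion-major
# (col = (m-1)*N + n), Z = [z_1 .. z_U] (I x U), X = [x_1^1 .. x_N^M]
# (J x MN) and W = [W_1; ..; W_C] ((I*C) x J).

# Column index for (motion m, repetition n) given N repetitions per motion.
layout_column <- function(m, n, N) (m - 1L) * N + n

# Row index for (channel c, user u) given U users: channel-major blocks.
layout_row <- function(c, u, U) (c - 1L) * U + u

# First k rows of V' from the SVD of A, with each row's sign fixed so its
# largest-magnitude entry is positive (the raw SVD sign is arbitrary).
svd_vt_rows <- function(A, k) {
  if (k > ncol(A)) stop("requested more singular vectors than columns", call. = FALSE)
  nv <- if (k > min(dim(A))) ncol(A) else min(dim(A))
  s <- svd(A, nu = 0, nv = nv)
  vt <- t(s$v)[seq_len(k), , drop = FALSE]
  for (i in seq_len(nrow(vt))) {
    j <- which.max(abs(vt[i, ]))
    if (vt[i, j] < 0) vt[i, ] <- -vt[i, ]
  }
  vt
}

#' Compose a stacked data matrix from bilinear factors
#'
#' Evaluates `Y = [W^ST Z]^ST X`: block `c` of the result is `Z' W_c X`, so
#' entry (row `(c-1)*U + u`, column `(m-1)*N + n`) equals `z_u' W_c x_n^m`.
#'
#' @param Z Numeric `I x U` matrix of user factors (columns).
#' @param W An `(I*C) x J` [stacked_matrix()] of per-channel interactions
#'   (or plain matrix with `block_count` supplied).
#' @param X Numeric `J x (M*N)` matrix of motion factors (columns).
#' @param block_count Block count if `W` is a plain matrix.
#' @return A [stacked_matrix()] of shape `(C*U) x (M*N)` with `C` blocks.
#' @export
bl_compose <- function(Z, W, X, block_count = NULL) {
  W <- as_stacked(W, block_count %||% 1L)
  Z <- as.matrix(Z)
  X <- as.matrix(X)
  I <- nrow(Z)
  if (W$block_rows != I) {
    stop(sprintf("W block height %d does not match nrow(Z) = %d",
                 W$block_rows, I), call. = FALSE)
  }
  if (ncol(W$data) != nrow(X)) {
    stop(sprintf("ncol(W) = %d does not match nrow(X) = %d",
                 ncol(W$data), nrow(X)), call. = FALSE)
  }
  wz <- stacked_transpose(W)$data %*% Z          # (J*C) x U, C blocks
  y <- stacked_transpose(stacked_matrix(wz, W$block_count))$data %*% X
  stacked_matrix(y, W$block_count)
}

#' Residual sum of squares of a bilinear model
#'
#' The fitting objective: the Frobenius residual
#' `sum((Y - compose(Z, W, X))^2)`, i.e. the sum over channels, users,
#' motions and repetitions of the squared reconstruction errors.
#'
#' @param Y Observed [stacked_matrix()] (`(C*U) x (M*N)`).
#' @param model A `bilinear_model` (see [bl_fit()]) or a list with `Z`, `W`,
#'   `X`.
#' @return Non-negative scalar; zero iff the model reproduces `Y` exactly.
#' @export
bl_objective <- function(Y, model) {
  Y <- as_stacked(Y, if (inherits(model$W, "stacked_matrix")) model$W$block_count else 1L)
  Yhat <- bl_compose(model$Z, model$W, model$X)
  if (!identical(dim(Yhat$data), dim(Y$data))) {
    stop("model dimensions do not match Y", call. = FALSE)
  }
  sum((Y$data - Yhat$data)^2)
}

#' Fit the bilinear model by alternating singular value decompositions
#'
#' Initializes `X` as the top `J` right-singular rows of `Y`, then alternates:
#' `Z` <- top `I` right-singular rows of `[Y X']^ST`, and `X` <- top `J`
#' right-singular rows of `[Y^ST Z']^ST`. After each round, `W` is the
#' least-squares interaction given the (row-orthonormal) `Z` and `X`:
#' `W_c = Z Y_c X'`. Each round solves its subproblem exactly, so the
#' objective is non-increasing; iteration stops when the relative objective
#' change drops below `tol` or `max_iter` is reached. Singular-vector signs
#' are canonicalized (largest-magnitude entry positive), so the fit is
#' deterministic given `Y`.
#'
#' @param Y `(C*U) x (M*N)` [stacked_matrix()] (or plain matrix plus
#'   `block_count`).
#' @param I User-factor dimension, `1 <= I <= U`.
#' @param J Motion-factor dimension, `1 <= J <= M*N`.
#' @param n_motions Number of motions `M`; needed to label the columns of
#'   `X` with motions (columns are motion-major). Default 1 treats all
#'   columns as one motion.
#' @param tol Relative objective-change tolerance (default 1e-6).
#' @param max_iter Maximum alternating rounds (default 50; convergence is
#'   typically reached within a handful).
#' @param block_count Block count if `Y` is a plain matrix.
#' @return A `bilinear_model`: factors `Z` (`I x U`), `W` (stacked
#'   `(I*C) x J`), `X` (`J x MN`), `dims`, `motion_of_column`,
#'   `objective_history` (one value per round), `iterations`, `converged`,
#'   and `config`.
#' @export
bl_fit <- function(Y, I, J, n_motions = 1L, tol = 1e-6, max_iter = 50L,
                   block_count = NULL) {
  Y <- as_stacked(Y, block_count %||% 1L)
  C <- Y$block_count
  U <- Y$block_rows
  MN <- ncol(Y$data)
  I <- as.integer(I); J <- as.integer(J)
  n_motions <- as.integer(n_motions)
  if (I < 1L || I > U) {
    stop(sprintf("I must be in [1, U = %d], got %d", U, I), call. = FALSE)
  }
  if (J < 1L || J > MN) {
    stop(sprintf("J must be in [1, M*N = %d], got %d", MN, J), call. = FALSE)
  }
  if (MN %% n_motions != 0L) {
    stop("ncol(Y) must be divisible by n_motions", call. = FALSE)
  }
  normY2 <- sum(Y$data^2)
  if (normY2 == 0) stop("cannot fit an all-zero Y", call. = FALSE)

  fit_W <- function(Z, X) {
    blocks <- lapply(seq_len(C), function(c) Z %*% stacked_block(Y, c) %*% t(X))
    stacked_matrix(do.call(rbind, blocks), C)
  }

  X <- svd_vt_rows(Y$data, J)
  Z <- NULL
  history <- numeric(0)
  converged <- FALSE
  iterations <- 0L
  floor_ref <- .Machine$double.eps * normY2
  for (k in seq_len(max_iter)) {
    yxt <- stacked_matrix(Y$data %*% t(X), C)        # (U*C) x J, C blocks
    Z <- svd_vt_rows(stacked_transpose(yxt)$data, I) # from (J*C) x U
    ytz <- stacked_matrix(stacked_transpose(Y)$data %*% t(Z), C)  # (MN*C) x I
    X <- svd_vt_rows(stacked_transpose(ytz)$data, J) # from (I*C) x MN
    W <- fit_W(Z, X)
    E <- bl_objective(Y, list(Z = Z, W = W, X = X))
    history <- c(history, E)
    iterations <- k
    if (k >= 2L) {
      delta <- abs(history[k - 1L] - E)
      if (delta / max(history[k - 1L], floor_ref) < tol) {
        converged <- TRUE
        break
      }
    }
  }
  N_per_motion <- MN %/% n_motions
  structure(
    list(
      Z = Z, W = W, X = X,
      dims = list(I = I, J = J, C = C, U = U, M = n_motions,
                  N = N_per_motion),
      motion_of_column = as.integer((seq_len(MN) - 1L) %/% N_per_motion + 1L),
      objective_history = history,
      iterations = iterations,
      converged = converged,
      config = list(tol = tol, max_iter = as.integer(max_iter))
    ),
    class = "bilinear_model"
  )
}

#' @export
print.bilinear_model <- function(x, ...) {
  d <- x$dims
  cat(sprintf(
    "<bilinear_model> I=%d J=%d C=%d U=%d M=%d N=%d; %d iteration(s), %s (final E = %.3e)\n",
    d$I, d$J, d$C, d$U, d$M, d$N, x$iterations,
    if (isTRUE(x$converged)) "converged" else "not converged",
    utils::tail(x$objective_history, 1)
  ))
  invisible(x)
}

#' Adapt a fitted bilinear model to a new user
#'
#' Closed-form three-step adaptation from calibration data of a single
#' motion: the new user's factor is the least-squares solution of
#' `Y_new^ST = [W X_m]^ST z_new`; the new interaction matrix is
#' `W_new = [Y_new^ST (z_new)^+]^ST (X_m)^+` (per channel the least-squares
#' `W_c = pinv(z') y_c pinv(X_m)`); and the calibration motion factors are
#' re-extracted as `X_new = ([W_new^ST z_new]^ST)^+ Y_new`. All
#' pseudo-inverses use a relative singular-value cutoff; the worst condition
#' number encountered is reported so rank-hungry small-calibration cases are
#' visible.
#'
#' @param model A fitted `bilinear_model`.
#' @param Y_new `C x N_new` calibration data for one motion: one row per
#'   channel block (a single new user), one column per repetition, in the
#'   same feature space as the training `Y`. Plain matrix or
#'   [stacked_matrix()] with `C` blocks of one row.
#' @param motion Motion index `m` of the calibration data.
#' @param rcond Relative singular-value cutoff for pseudo-inverses.
#' @return An `adaptation_result`: `z_new` (`I x 1`), `W_new` (stacked
#'   `(I*C) x J`), `X_new` (`J x N_new`), the relative reconstruction
#'   `residual`, `condition` (worst pseudo-inverse condition number),
#'   `motion` and `n_cal`.
#' @export
bl_adapt <- function(model, Y_new, motion, rcond = 1e-10) {
  stopifnot(inherits(model, "bilinear_model"))
  d <- model$dims
  Y_new <- if (inherits(Y_new, "stacked_matrix")) Y_new else
    stacked_matrix(as.matrix(Y_new), d$C)
  if (Y_new$block_rows != 1L || Y_new$block_count != d$C) {
    stop(sprintf("Y_new must be %d channel blocks of one row each", d$C),
         call. = FALSE)
  }
  motion <- as.integer(motion)
  if (motion < 1L || motion > d$M) stop("motion index out of range", call. = FALSE)
  n_cal <- ncol(Y_new$data)
  cols <- which(model$motion_of_column == motion)
  if (n_cal > length(cols)) {
    stop(sprintf("calibration has %d repetitions but the model stores only %d for motion %d",
                 n_cal, length(cols), motion), call. = FALSE)
  }
  X_m <- model$X[, cols[seq_len(n_cal)], drop = FALSE]     # J x n_cal

  conds <- numeric(0)
  take_pinv <- function(A) {
    P <- pinv(A, rcond)
    conds[[length(conds) + 1L]] <<- attr(P, "condition")
    P
  }

  y_st <- stacked_transpose(Y_new)$data                    # (n_cal*C) x 1
  # z_new = ([W X_m]^ST)^+ Y_new^ST
  B <- stacked_transpose(stacked_matrix(model$W$data %*% X_m, d$C))$data
  z_new <- take_pinv(B) %*% y_st                           # I x 1
  # W_new = [Y_new^ST (z_new)^+]^ST (X_m)^+
  wn <- stacked_transpose(stacked_matrix(y_st %*% take_pinv(z_new), d$C))$data %*%
    take_pinv(X_m)                                         # (I*C) x J
  W_new <- stacked_matrix(wn, d$C)
  # X_new = ([W_new^ST z_new]^ST)^+ Y_new
  A_cal <- stacked_transpose(stacked_matrix(stacked_transpose(W_new)$data %*% z_new,
                                            d$C))$data     # C x J
  A_cal_pinv <- take_pinv(A_cal)
  X_new <- A_cal_pinv %*% Y_new$data                       # J x n_cal
  recon <- A_cal %*% X_new
  residual <- sqrt(sum((Y_new$data - recon)^2)) /
    max(sqrt(sum(Y_new$data^2)), .Machine$double.xmin)
  # extraction map through the consensus interaction W with the adapted z:
  # rows z_new' W_c. Unlike A_cal (built from the single calibration motion,
  # rank <= n_cal), this map has the conditioning of the fitted model and is
  # the default for projecting unlabeled trials.
  A_model <- stacked_transpose(stacked_matrix(stacked_transpose(model$W)$data %*% z_new,
                                              d$C))$data   # C x J
  A_model_pinv <- take_pinv(A_model)
  structure(
    list(z_new = z_new, W_new = W_new, X_new = X_new,
         projection = A_model, projection_pinv = A_model_pinv,
         projection_cal = A_cal, projection_cal_pinv = A_cal_pinv,
         residual = residual, condition = max(conds),
         motion = motion, n_cal = n_cal, dims = d, rcond = rcond),
    class = "adaptation_result"
  )
}

#' Project new-user trials onto motion factors
#'
#' Applies the adapted user's extraction map to unlabeled `C x n` trial data,
#' yielding one `J`-dimensional motion-factor column per input column. Two
#' maps are available: `"model"` (default) extracts through the fitted
#' consensus interaction, the pseudo-inverse of the `C x J` matrix with rows
#' `z_new' W_c`; `"calibration"` extracts through the re-estimated
#' single-motion interaction (rows `z_new' W_new_c`), whose rank is limited
#' by the number of calibration repetitions -- with it, projecting the
#' calibration data reproduces `X_new` exactly. Both maps are linear, so
#' scaling the input scales the factors.
#'
#' @param adapted An `adaptation_result` from [bl_adapt()].
#' @param Y_trial `C x n` matrix (channels x windows/repetitions).
#' @param interaction `"model"` or `"calibration"` (see above).
#' @return `J x n` matrix of motion factors.
#' @export
bl_project <- function(adapted, Y_trial,
                       interaction = c("model", "calibration")) {
  stopifnot(inherits(adapted, "adaptation_result"))
  interaction <- match.arg(interaction)
  Y_trial <- if (inherits(Y_trial, "stacked_matrix")) Y_trial$data else
    as.matrix(Y_trial)
  if (nrow(Y_trial) != adapted$dims$C) {
    stop(sprintf("trial has %d channels, model expects %d",
                 nrow(Y_trial), adapted$dims$C), call. = FALSE)
  }
  P <- if (interaction == "model") adapted$projection_pinv else
    adapted$projection_cal_pinv
  P %*% Y_trial
}

#' Grid search over the latent dimensions (I, J)
#'
#' Evaluates a user-supplied accuracy callback on every `(I, J)` pair and
#' reports the full surface plus the best pair, ties broken toward smaller
#' `I`, then smaller `J`.
#'
#' @param I_values,J_values Candidate latent dimensions (non-empty).
#' @param eval_fn Function `(I, J) -> accuracy` in `[0, 1]`.
#' @return List with `surface` (data.frame `I`, `J`, `accuracy`) and `best`
#'   (one-row data.frame).
#' @export
grid_search_ij <- function(I_values, J_values, eval_fn) {
  if (length(I_values) == 0L || length(J_values) == 0L) {
    stop("candidate lists must be non-empty", call. = FALSE)
  }
  grid <- expand.grid(J = sort(as.integer(J_values)),
                      I = sort(as.integer(I_values)))[, c("I", "J")]
  grid <- grid[order(grid$I, grid$J), , drop = FALSE]
  rownames(grid) <- NULL
  grid$accuracy <- NA_real_
  for (r in seq_len(nrow(grid))) {
    acc <- tryCatch(
      eval_fn(grid$I[r], grid$J[r]),
      error = function(e) stop(sprintf("grid evaluation failed at I=%d, J=%d: %s",
                                       grid$I[r], grid$J[r],
                                       conditionMessage(e)), call. = FALSE)
    )
    grid$accuracy[r] <- acc
  }
  best <- grid[which.max(grid$accuracy), , drop = FALSE]
  list(surface = grid, best = best)
}
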