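test_that("stacked transpose is a blockwise involution", {
  # worked 2-block example: each block transposed independently, order kept
  A <- stacked_matrix(rbind(c(1, 2), c(3, 4), c(5, 6), c(7, 8)), 2)
  st <- stacked_transpose(A)
  expect_equal(st$data, rbind(c(1, 3), c(2, 4), c(5, 7), c(6, 8)))

  set.seed(31)
  for (i in 1:100) {
    C <- sample(1:4, 1)
    r <- sample(1:5, 1); k <- sample(1:5, 1)
    A <- stacked_matrix(matrix(rnorm(C * r * k), C * r, k), C)
    st <- stacked_transpose(A)
    expect_equal(st$block_count, C)
    expect_equal(dim(st$data), c(k * C, r))
    expect_equal(stacked_transpose(st)$data, A$data, tolerance = 1e-12)
    if (C == 1) expect_equal(st$data, t(A$data))
  }
  expect_error(stacked_matrix(matrix(0, 5, 2), 2), "divisible")
})

test_that("composition agrees with the entrywise triple-product oracle", {
  set.seed(32)
  for (i in 1:100) {
    I <- sample(1:3, 1); J <- sample(1:4, 1); C <- sample(1:3, 1)
    U <- sample(1:4, 1); MN <- sample(1:6, 1)
    Z <- matrix(rnorm(I * U), I, U)
    W <- stacked_matrix(matrix(rnorm(I * C * J), I * C, J), C)
    X <- matrix(rnorm(J * MN), J, MN)
    Y <- bl_compose(Z, W, X)
    Yo <- oracle_compose(Z, W$data, X, I, J, C, U, MN)
    expect_lt(max(abs(Y$data - Yo)) / max(1, max(abs(Yo))), 1e-10)
    # the two printed matrix forms are equivalent
    lhs <- stacked_transpose(Y)$data
    rhs <- stacked_transpose(stacked_matrix(W$data %*% X, C))$data %*% Z
    expect_lt(max(abs(lhs - rhs)) / max(1, max(abs(lhs))), 1e-10)
  }
  # scalar degenerate case
  Y1 <- bl_compose(matrix(2), stacked_matrix(matrix(3), 1), matrix(5))
  expect_equal(drop(Y1$data), 30)
  expect_error(bl_compose(matrix(0, 2, 3), stacked_matrix(matrix(0, 4, 5), 2),
                          matrix(0, 4, 6)), "nrow\\(X\\)")
})

test_that("the objective is the residual sum of squares", {
  inst <- generate_bilinear_instance(2, 3, 3, 4, 2, 3, seed = 33)
  model <- list(Z = inst$Z, W = inst$W, X = inst$X)
  expect_equal(bl_objective(inst$Y, model), 0, tolerance = 1e-18)
  zeroX <- list(Z = inst$Z, W = inst$W, X = 0 * inst$X)
  expect_equal(bl_objective(inst$Y, zeroX), sum(inst$Y$data^2))
  # quadruple-loop oracle on a perturbed model
  model2 <- list(Z = inst$Z + 0.1, W = inst$W, X = inst$X)
  Yhat <- oracle_compose(model2$Z, inst$W$data, inst$X, 2, 3, 3, 4, 6)
  E <- 0
  for (r in seq_len(nrow(Yhat))) for (k in seq_len(ncol(Yhat))) {
    E <- E + (inst$Y$data[r, k] - Yhat[r, k])^2
  }
  expect_equal(bl_objective(inst$Y, model2), E, tolerance = 1e-10)
})

test_that("alternating-SVD fitting recovers noise-free generative instances", {
  for (seed in 1:3) {
    inst <- generate_bilinear_instance(3, 8, 4, 6, 5, 4, seed = seed)
    fit <- bl_fit(inst$Y, 3, 8, n_motions = 5)
    relE <- utils::tail(fit$objective_history, 1) / sum(inst$Y$data^2)
    expect_lt(relE, 1e-8)
    expect_true(fit$converged)
    expect_lte(fit$iterations, 10)
    # objective history non-increasing within numerical tolerance (the
    # eps * ||Y||^2 term covers machine noise once the fit is exact)
    h <- fit$objective_history
    if (length(h) > 1) {
      expect_true(all(diff(h) <= 1e-9 * h[1] +
                        .Machine$double.eps * sum(inst$Y$data^2)))
    }
  }
})

test_that("the objective decreases monotonically on noisy data", {
  for (seed in 1:5) {
    inst <- generate_bilinear_instance(2, 6, 4, 8, 5, 6, noise_sd = 0.5,
                                       seed = seed)
    fit <- bl_fit(inst$Y, 2, 6, n_motions = 5, tol = 0, max_iter = 15)
    h <- fit$objective_history
    expect_gt(length(h), 2)
    expect_true(all(diff(h) <= 1e-9 * h[1]))
  }
})

test_that("full-dimensional fits reconstruct arbitrary data exactly", {
  set.seed(35)
  C <- 3; U <- 4; MN <- 6
  Y <- stacked_matrix(matrix(rnorm(C * U * MN), C * U, MN), C)
  fit <- bl_fit(Y, I = U, J = MN, n_motions = 2)
  expect_lt(utils::tail(fit$objective_history, 1) / sum(Y$data^2), 1e-16)
})

test_that("fitting is deterministic and validates its inputs", {
  inst <- generate_bilinear_instance(2, 4, 3, 5, 2, 4, noise_sd = 0.2, seed = 36)
  f1 <- bl_fit(inst$Y, 2, 4, n_motions = 2)
  f2 <- bl_fit(inst$Y, 2, 4, n_motions = 2)
  expect_identical(f1$Z, f2$Z)
  expect_identical(f1$X, f2$X)
  expect_identical(f1$objective_history, f2$objective_history)
  expect_error(bl_fit(inst$Y, 99, 4), "I must be")
  expect_error(bl_fit(inst$Y, 2, 99), "J must be")
  expect_error(bl_fit(stacked_matrix(matrix(0, 6, 4), 3), 2, 2), "all-zero")
})

test_that("fitted residual approaches the noise floor at matching dims", {
  sigma <- 0.3
  ratios <- vapply(1:10, function(seed) {
    inst <- generate_bilinear_instance(2, 5, 6, 15, 8, 10, noise_sd = sigma,
                                       seed = seed)
    fit <- bl_fit(inst$Y, 2, 5, n_motions = 8)
    n_entries <- length(inst$Y$data)
    utils::tail(fit$objective_history, 1) / n_entries / sigma^2
  }, numeric(1))
  expect_lt(abs(mean(ratios) - 1), 0.2)
})

test_that("new-user adaptation is self-consistent on model-generated data", {
  # dims with J <= min(C, N) so the closed-form chain is full rank
  inst <- generate_bilinear_instance(3, 4, 8, 10, 5, 6, seed = 41)
  fit <- bl_fit(inst$Y, 3, 4, n_motions = 5)
  I <- 3; C <- 8; U <- 10; N <- 6
  m <- 2
  cols <- which(fit$motion_of_column == m)

  # a new user drawn from the fitted model's own factors
  z_star <- rnorm(I)
  X_m <- fit$X[, cols, drop = FALSE]
  Y_new <- do.call(rbind, lapply(seq_len(C), function(c) {
    Wc <- fit$W$data[((c - 1) * I + 1):(c * I), , drop = FALSE]
    t(z_star) %*% Wc %*% X_m
  }))
  ad <- bl_adapt(fit, Y_new, m)
  expect_equal(drop(ad$z_new), z_star, tolerance = 1e-6)
  expect_lt(ad$residual, 1e-8)
  expect_equal(ad$X_new, X_m, tolerance = 1e-6, ignore_attr = TRUE)

  # new user identical to a training user recovers that user's motion factors
  u <- 4
  Y_u <- inst$Y$data[(seq_len(C) - 1) * U + u, cols, drop = FALSE]
  ad_u <- bl_adapt(fit, Y_u, m)
  expect_equal(ad_u$X_new, X_m, tolerance = 1e-6, ignore_attr = TRUE)

  # a single calibration repetition still yields consistent shapes
  ad1 <- bl_adapt(fit, Y_new[, 1, drop = FALSE], m)
  expect_equal(dim(ad1$X_new), c(4L, 1L))
  expect_equal(dim(ad1$z_new), c(3L, 1L))
  expect_equal(dim(ad1$W_new$data), c(I * C, 4L))
})

test_that("projection is linear and reproduces the calibration factors", {
  inst <- generate_bilinear_instance(3, 4, 8, 10, 5, 6, seed = 42)
  fit <- bl_fit(inst$Y, 3, 4, n_motions = 5)
  cols <- which(fit$motion_of_column == 1)
  U <- 10; C <- 8
  Y_u <- inst$Y$data[(seq_len(C) - 1) * U + 3, cols, drop = FALSE]
  ad <- bl_adapt(fit, Y_u, 1)
  # the calibration-interaction map reproduces X_new exactly
  expect_equal(bl_project(ad, Y_u, interaction = "calibration"), ad$X_new,
               tolerance = 1e-10, ignore_attr = TRUE)
  # linearity and zero preservation
  P <- bl_project(ad, Y_u)
  expect_equal(bl_project(ad, 2.5 * Y_u), 2.5 * P, tolerance = 1e-10)
  expect_equal(bl_project(ad, 0 * Y_u), 0 * P)
  expect_error(bl_project(ad, Y_u[1:3, ]), "channels")
})

test_that("grid search reports the full surface with deterministic ties", {
  calls <- list()
  res <- grid_search_ij(2, 5, function(I, J) {
    calls[[length(calls) + 1]] <<- c(I, J)
    0.5
  })
  expect_equal(nrow(res$surface), 1)
  expect_equal(res$best$I, 2)
  expect_equal(res$best$J, 5)

  # ties break toward smaller I, then smaller J
  res2 <- grid_search_ij(c(3, 1), c(20, 10), function(I, J) 0.9)
  expect_equal(res2$best$I, 1)
  expect_equal(res2$best$J, 10)
  expect_equal(nrow(res2$surface), 4)

  # same evaluations give the same surface
  f <- function(I, J) sin(I * J)
  expect_identical(grid_search_ij(1:2, 3:4, f)$surface,
                   grid_search_ij(1:2, 3:4, f)$surface)

  expect_error(grid_search_ij(integer(0), 1, f), "non-empty")
  expect_error(grid_search_ij(1, 2, function(I, J) stop("boom")),
               "I=1, J=2")
})
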