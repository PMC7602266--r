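# Naive loop-based oracles for the ten window features, written directly
# from the defining sums and kept independent of the package implementation.

oracle_mav <- function(x) {
  s <- 0
  for (v in x) s <- s + abs(v)
  s / length(x)
}

oracle_std <- function(x) {
  mu <- 0
  for (v in x) mu <- mu + v
  mu <- mu / length(x)
  s <- 0
  for (v in x) s <- s + (v - mu)^2
  sqrt(s / length(x))
}

oracle_rms <- function(x) {
  s <- 0
  for (v in x) s <- s + v^2
  sqrt(s / length(x))
}

oracle_log_detector <- function(x, floor = 1e-12) {
  s <- 0
  for (v in x) s <- s + log(max(abs(v), floor))
  exp(s / length(x))
}

oracle_aac <- function(x) {
  s <- 0
  for (i in seq_len(length(x) - 1)) s <- s + abs(x[i + 1] - x[i])
  s / (length(x) - 1)
}

oracle_mnf <- function(f, p) {
  num <- 0; den <- 0
  for (i in seq_along(f)) {
    num <- num + f[i] * p[i]
    den <- den + p[i]
  }
  num / den
}

oracle_mdf <- function(f, p) {
  half <- sum(p) / 2
  acc <- 0
  for (i in seq_along(f)) {
    acc <- acc + p[i]
    if (acc >= half) return(f[i])
  }
  f[length(f)]
}

oracle_mnp <- function(f, p) {
  num <- 0; den <- 0
  for (i in seq_along(f)) {
    num <- num + f[i] * p[i]
    den <- den + f[i]
  }
  num / den
}

oracle_pkf <- function(f, p) {
  best <- 1
  for (i in seq_along(p)) if (p[i] > p[best]) best <- i
  f[best]
}

oracle_psr <- function(f, p, eps, band = range(f)) {
  f0 <- oracle_pkf(f, p)
  lo <- max(f0 - eps, band[1]); hi <- min(f0 + eps, band[2])
  num <- 0; den <- 0
  for (i in seq_along(f)) {
    if (f[i] >= band[1] && f[i] <= band[2]) {
      den <- den + p[i]
      if (f[i] >= lo && f[i] <= hi) num <- num + p[i]
    }
  }
  num / den
}

random_psd <- function(n_bins = 65, fs = 200) {
  f <- seq(0, fs / 2, length.out = n_bins)
  structure(list(frequencies = f, powers = stats::rexp(n_bins)),
            class = "psd_estimate")
}

# Entrywise Eq-11 style quadruple-loop composition oracle.
oracle_compose <- function(Z, Wdata, X, I, J, C, U, MN) {
  Y <- matrix(NA_real_, C * U, MN)
  for (c in seq_len(C)) {
    Wc <- Wdata[((c - 1) * I + 1):(c * I), , drop = FALSE]
    for (u in seq_len(U)) {
      for (k in seq_len(MN)) {
        Y[(c - 1) * U + u, k] <- drop(t(Z[, u]) %*% Wc %*% X[, k])
      }
    }
  }
  Y
}

small_cohort <- function(seed, n_subjects = 5, n_motions = 6, n_trials = 10) {
  generate_emg_cohort(emg_cohort_config(
    n_subjects = n_subjects, n_motions = n_motions, n_trials = n_trials,
    seed = seed
  ))
}

# The desk-scale LOSO configuration used throughout the tests: 300-sample
# windows (3 per trial), latent dims chosen for a 4-training-subject cohort.
small_loso_config <- function(classifier = "centroid", ...) {
  pipeline_config(
    features = feature_config(window_samples = 300, stride_samples = 150),
    I = 4, J = 10, classifier = classifier, ...
  )
}
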