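# Synthetic data: exact bilinear instances for algorithm verification, and
# multi-subject surface-EMG cohorts with user-specific confounds for
# end-to-end pipeline tests.

#' Generate an exact bilinear-model instance
#'
#' Draws standard-normal factors `Z` (I x U), `W_c` (I x J per channel) and
#' `X` (J x MN), scales them, composes the stacked data matrix
#' `Y = [W^ST Z]^ST X` and adds i.i.d. Gaussian noise. Deterministic given
#' the seed.
#'
#' @param I,J,C,U,M,N Model dimensions (user dim, motion dim, channels,
#'   users, motions, repetitions per motion).
#' @param factor_scale Multiplier applied to each factor (default 1).
#' @param noise_sd Entrywise noise standard deviation (default 0).
#' @param seed RNG seed.
#' @return List with `Y` ([stacked_matrix()], `C*U x M*N`), the true factors
#'   `Z`, `W` (stacked), `X`, and `dims`.
#' @export
generate_bilinear_instance <- function(I, J, C, U, M, N, factor_scale = 1,
                                       noise_sd = 0, seed = 1L) {
  stopifnot(I >= 1, J >= 1, C >= 1, U >= 1, M >= 1, N >= 1, noise_sd >= 0)
  with_seed(seed, {
    Z <- matrix(stats::rnorm(I * U), I, U) * factor_scale
    W <- stacked_matrix(matrix(stats::rnorm(I * C * J), I * C, J) * factor_scale, C)
    X <- matrix(stats::rnorm(J * M * N), J, M * N) * factor_scale
    Y <- bl_compose(Z, W, X)
    if (noise_sd > 0) {
      Y <- stacked_matrix(
        Y$data + matrix(stats::rnorm(length(Y$data), sd = noise_sd),
                        nrow(Y$data), ncol(Y$data)),
        C
      )
    }
    list(Y = Y, Z = Z, W = W, X = X,
         dims = list(I = I, J = J, C = C, U = U, M = M, N = N))
  })
}

#' Configuration for the synthetic EMG cohort generator
#'
#' Defaults describe the recording protocol the pipeline targets (3 s trials
#' of 8-channel EMG at 200 Hz, 10 repetitions per motion) with user confounds
#' strong enough that cross-subject recognition on raw features degrades
#' markedly. Set the three confound parameters to zero for a confound-free
#' cohort.
#'
#' @param n_subjects Number of subjects.
#' @param n_motions Number of motions (default 20, labels `M1`..).
#' @param n_trials Repetitions per (subject, motion) (default 10).
#' @param sampling_rate_hz Sampling rate (default 200).
#' @param duration_s Trial duration in seconds (default 3).
#' @param n_channels EMG channels (default 8).
#' @param gain_sdlog Log-sd of the per-subject gain parameters: each subject
#'   gets channel gains `exp(a_u + w_u * profile)` with a cohort-shared
#'   channel profile and subject-specific `a_u`, `w_u` (electrode impedance /
#'   tissue differences; default 0.8).
#' @param mixing_strength Upper bound of the per-subject cross-talk strength
#'   along a cohort-shared mixing pattern, in `[0, 1)` (default 0.6).
#' @param rotation_max Maximum per-subject electrode rotation, as a fraction
#'   of one channel spacing in `[0, 1]` (implemented as interpolation toward
#'   the neighboring channel; default 0.75).
#' @param amplitude_jitter_sd Log-sd of per-trial envelope amplitude jitter
#'   (default 0.15).
#' @param timing_jitter Fractional jitter of envelope breakpoint times
#'   (default 0.08).
#' @param noise_floor Additive sensor-noise sd relative to unit signal scale
#'   (default 0.05).
#' @param seed RNG seed; the whole cohort is deterministic given the config
#'   and seed.
#' @return An `emg_cohort_config` list.
#' @export
emg_cohort_config <- function(n_subjects = 20L, n_motions = 20L,
                              n_trials = 10L, sampling_rate_hz = 200,
                              duration_s = 3, n_channels = 8L,
                              gain_sdlog = 0.8, mixing_strength = 0.6,
                              rotation_max = 0.75, amplitude_jitter_sd = 0.15,
                              timing_jitter = 0.08, noise_floor = 0.05,
                              seed = 1L) {
  stopifnot(n_subjects >= 1, n_motions >= 1, n_trials >= 1, n_channels >= 1,
            gain_sdlog >= 0, mixing_strength >= 0, mixing_strength < 1,
            rotation_max >= 0, rotation_max <= 1, noise_floor >= 0)
  structure(
    list(n_subjects = as.integer(n_subjects),
         n_motions = as.integer(n_motions),
         n_trials = as.integer(n_trials),
         sampling_rate_hz = sampling_rate_hz, duration_s = duration_s,
         n_channels = as.integer(n_channels), gain_sdlog = gain_sdlog,
         mixing_strength = mixing_strength,
         rotation_max = rotation_max,
         amplitude_jitter_sd = amplitude_jitter_sd,
         timing_jitter = timing_jitter, noise_floor = noise_floor,
         seed = as.integer(seed)),
    class = "emg_cohort_config"
  )
}

# Draw the per-motion archetypes: each motion is a sequence of 2-4
# sub-gesture segments; each channel gets per-segment envelope amplitudes and
# a motion-specific spectral band inside 20-95 Hz. Archetypes must be
# distinct across motions or the motions are indistinguishable in principle.
draw_archetypes <- function(config) {
  lapply(seq_len(config$n_motions), function(m) {
    n_seg <- sample(2:4, 1L)
    amp <- matrix(stats::runif(config$n_channels * (n_seg + 1L), 0.1, 2),
                  config$n_channels, n_seg + 1L)
    centers <- stats::runif(config$n_channels, 30, 85)
    halfwidth <- stats::runif(config$n_channels, 8, 15)
    low <- pmax(20, centers - halfwidth)
    high <- pmin(95, centers + halfwidth)
    list(n_segments = n_seg, node_amplitudes = amp,
         band_low = low, band_high = high)
  })
}

archetype_signature <- function(a) {
  paste(signif(c(a$n_segments, a$node_amplitudes, a$band_low, a$band_high), 8),
        collapse = ",")
}

# Cohort-level confound structure: user variation is low-dimensional across
# the population (a shared gain profile, a shared cross-talk pattern, and a
# common rotation direction), with per-subject strengths. This is the
# user-multiplicative structure a bilinear user x motion factorization can
# absorb; independent full-rank per-subject transforms would make new-user
# adaptation impossible in principle at small cohort sizes.
draw_confound_basis <- function(config) {
  Cc <- config$n_channels
  profile <- stats::rnorm(Cc)
  profile <- profile / max(sqrt(mean(profile^2)), 1e-12)
  mix <- matrix(abs(stats::rnorm(Cc * Cc)), Cc, Cc)
  diag(mix) <- 0
  mix <- mix / pmax(rowSums(mix), 1e-12)
  list(gain_profile = profile, mixing_pattern = mix)
}

# Per-subject transform of the samples-x-channels matrix: fractional circular
# rotation (electrode placement shift by a fraction of one channel spacing),
# then cross-talk of subject-specific strength, then per-channel gains
# exp(a_u + w_u * profile).
draw_confound <- function(config, basis) {
  Cc <- config$n_channels
  a_u <- stats::rnorm(1, 0, config$gain_sdlog)
  w_u <- stats::rnorm(1, 0, config$gain_sdlog)
  gains <- exp(a_u + w_u * basis$gain_profile)
  # every subject is substantially confounded: strengths are drawn from the
  # upper half of their ranges rather than from zero
  alpha <- stats::runif(1, config$mixing_strength / 2, config$mixing_strength)
  A_mix <- (1 - alpha) * diag(Cc) + alpha * basis$mixing_pattern
  beta <- stats::runif(1, config$rotation_max / 2, config$rotation_max)
  R <- (1 - beta) * diag(Cc) + beta * diag(Cc)[c(2:Cc, 1L), , drop = FALSE]
  diag(gains) %*% A_mix %*% R
}

synth_trial_samples <- function(config, archetype, filters, t_len) {
  Cc <- config$n_channels
  n_seg <- archetype$n_segments
  out <- matrix(0, t_len, Cc)
  base_times <- seq(0, 1, length.out = n_seg + 1L)
  for (ch in seq_len(Cc)) {
    carrier <- signal::filtfilt(filters[[ch]], stats::rnorm(t_len))
    carrier <- carrier / max(stats::sd(carrier), 1e-12)
    times <- base_times +
      c(0, stats::rnorm(n_seg - 1L, 0, config$timing_jitter), 0) / n_seg
    times <- pmin(pmax(cummax(times), 0), 1)
    amps <- archetype$node_amplitudes[ch, ] *
      exp(stats::rnorm(n_seg + 1L, 0, config$amplitude_jitter_sd))
    env <- stats::approx(times, amps, xout = seq(0, 1, length.out = t_len),
                         rule = 2)$y
    out[, ch] <- carrier * env +
      stats::rnorm(t_len, 0, config$noise_floor)
  }
  out
}

#' Generate a synthetic multi-subject EMG cohort
#'
#' Each trial is per-channel band-limited Gaussian noise (20-95 Hz)
#' amplitude-modulated by a motion-specific piecewise-linear envelope (2-4
#' sub-gesture segments), with per-trial amplitude and timing jitter and an
#' additive noise floor. Subject identity enters as a linear channel
#' transform -- per-channel gains, cross-channel mixing and a circular
#' channel rotation -- exactly the kind of user-multiplicative structure a
#' bilinear user x motion factorization can absorb.
#'
#' @param config An [emg_cohort_config()].
#' @param archetypes Optional list of motion archetypes (as produced
#'   internally), mainly for testing; must be distinct across motions.
#' @return List of [emg_trial()] objects (subjects `S01`.., motions `M1`..,
#'   trial indices `0..n_trials-1`), with the generating archetypes and
#'   confound transforms attached as attributes `archetypes` and
#'   `confounds`.
#' @export
generate_emg_cohort <- function(config = emg_cohort_config(),
                                archetypes = NULL) {
  stopifnot(inherits(config, "emg_cohort_config"))
  t_len <- as.integer(round(config$duration_s * config$sampling_rate_hz))
  nyq <- config$sampling_rate_hz / 2
  with_seed(config$seed, {
    if (is.null(archetypes)) archetypes <- draw_archetypes(config)
    sigs <- vapply(archetypes, archetype_signature, character(1))
    if (anyDuplicated(sigs)) {
      stop("duplicate motion archetypes: motions must be distinguishable",
           call. = FALSE)
    }
    filters <- lapply(archetypes, function(a) {
      lapply(seq_len(config$n_channels), function(ch) {
        signal::butter(4, c(a$band_low[ch], a$band_high[ch]) / nyq,
                       type = "pass")
      })
    })
    basis <- draw_confound_basis(config)
    confounds <- lapply(seq_len(config$n_subjects),
                        function(u) draw_confound(config, basis))
    trials <- vector("list",
                     config$n_subjects * config$n_motions * config$n_trials)
    k <- 0L
    for (u in seq_len(config$n_subjects)) {
      sid <- sprintf("S%02d", u)
      for (m in seq_len(config$n_motions)) {
        for (tr in seq_len(config$n_trials)) {
          raw <- synth_trial_samples(config, archetypes[[m]], filters[[m]], t_len)
          mixed <- raw %*% t(confounds[[u]])
          k <- k + 1L
          trials[[k]] <- emg_trial(mixed, sid, sprintf("M%d", m), tr - 1L,
                                   config$sampling_rate_hz)
        }
      }
    }
    attr(trials, "archetypes") <- archetypes
    attr(trials, "confounds") <- confounds
    trials
  })
}
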