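#' Canonical feature names
#'
#' The ten window features computed by this package, in canonical order:
#' five time-domain (MAV, STD, RMS, LOG, AAC) and five frequency-domain
#' (MNF, MDF, MNP, PSR, PKF).
#'
#' @return Character vector of length 10.
#' @export
feature_names <- function() {
  c("MAV", "STD", "RMS", "LOG", "AAC", "MNF", "MDF", "MNP", "PSR", "PKF")
}

#' Feature-extraction configuration
#'
#' @param window_samples Sliding-window length in samples (default 600, i.e.
#'   a full 3 s trial at 200 Hz).
#' @param stride_samples Window stride; default `window_samples / 4`.
#' @param welch_segment Welch segment length in samples (default 128).
#' @param welch_overlap_fraction Fractional overlap between Welch segments in
#'   `[0, 1)` (default 0.5).
#' @param psr_epsilon_hz Half-width of the peak band for the power spectrum
#'   ratio, in Hz (default 10).
#' @param psr_band Two-element numeric `(f1, f2)` restricting the PSR energy
#'   band; `NULL` (default) means the full band `(0, Nyquist)`.
#' @param log_floor Magnitude floor applied inside the log detector so that
#'   zero samples stay finite (default 1e-12).
#' @param feature_set Ordered subset of [feature_names()] to compute.
#' @return A list of class `feature_config`.
#' @export
feature_config <- function(window_samples = 600,
                           stride_samples = max(1L, window_samples %/% 4L),
                           welch_segment = 128,
                           welch_overlap_fraction = 0.5,
                           psr_epsilon_hz = 10,
                           psr_band = NULL,
                           log_floor = 1e-12,
                           feature_set = feature_names()) {
  window_samples <- as.integer(window_samples)
  stride_samples <- as.integer(stride_samples)
  welch_segment <- as.integer(welch_segment)
  if (window_samples < 2L) stop("window_samples must be >= 2", call. = FALSE)
  if (stride_samples < 1L) stop("stride_samples must be >= 1", call. = FALSE)
  if (welch_segment < 2L) stop("welch_segment must be >= 2", call. = FALSE)
  if (welch_segment > window_samples) {
    stop("welch_segment must not exceed window_samples", call. = FALSE)
  }
  if (welch_overlap_fraction < 0 || welch_overlap_fraction >= 1) {
    stop("welch_overlap_fraction must be in [0, 1)", call. = FALSE)
  }
  stopifnot_scalar_number(psr_epsilon_hz, "psr_epsilon_hz", positive = TRUE)
  stopifnot_scalar_number(log_floor, "log_floor", positive = TRUE)
  unknown <- setdiff(feature_set, feature_names())
  if (length(unknown) > 0L) {
    stop(sprintf("unknown feature(s): %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  }
  structure(
    list(window_samples = window_samples, stride_samples = stride_samples,
         welch_segment = welch_segment,
         welch_overlap_fraction = welch_overlap_fraction,
         psr_epsilon_hz = psr_epsilon_hz, psr_band = psr_band,
         log_floor = log_floor, feature_set = feature_set),
    class = "feature_config"
  )
}

check_window <- function(x, min_len = 1L) {
  if (!is.numeric(x) || length(x) < min_len) {
    stop(sprintf("window must be a numeric vector of length >= %d", min_len),
         call. = FALSE)
  }
  invisible(x)
}

#' Mean absolute value of a window
#' @param x Numeric vector (one window, one channel).
#' @return `mean(|x|)`.
#' @export
mav <- function(x) {
  check_window(x)
  mean(abs(x))
}

#' Population standard deviation of a window
#'
#' Uses the population normalization 1/N (not the sample 1/(N-1)), so the
#' identity `rms(x)^2 == emg_std(x)^2 + mean(x)^2` holds exactly.
#'
#' @param x Numeric vector.
#' @return Non-negative standard deviation.
#' @export
emg_std <- function(x) {
  check_window(x)
  mu <- mean(x)
  sqrt(mean((x - mu)^2))
}

#' Root mean square of a window
#' @param x Numeric vector.
#' @return `sqrt(mean(x^2))`.
#' @export
rms <- function(x) {
  check_window(x)
  sqrt(mean(x^2))
}

#' Log detector of a window
#'
#' Exponentiated mean log magnitude, `exp(mean(log|x|))` -- the geometric
#' mean of the sample magnitudes, a classic surrogate for contraction force.
#' Magnitudes below `log_floor` are floored so idle (zero) samples stay
#' finite. By the AM-GM inequality, `log_detector(x) <= mav(x)` whenever no
#' flooring triggers.
#'
#' @param x Numeric vector.
#' @param log_floor Positive magnitude floor (default 1e-12).
#' @return Non-negative value.
#' @export
log_detector <- function(x, log_floor = 1e-12) {
  check_window(x)
  stopifnot_scalar_number(log_floor, "log_floor", positive = TRUE)
  exp(mean(log(pmax(abs(x), log_floor))))
}

#' Average amplitude change of a window
#'
#' Mean absolute first difference, `mean(|x[i+1] - x[i]|)` over the N-1
#' consecutive pairs; a waveform-complexity measure.
#'
#' @param x Numeric vector of length >= 2.
#' @return Non-negative value.
#' @export
aac <- function(x) {
  check_window(x, min_len = 2L)
  mean(abs(diff(x)))
}

#' Welch power spectral density estimate
#'
#' Averaged modified periodogram over overlapping Hann-tapered segments.
#' One-sided density scaling: `sum(power) * df` approximates the signal
#' variance (Parseval), with `df` the bin spacing.
#'
#' @param x Numeric signal vector (length >= `segment`).
#' @param sampling_rate_hz Sampling rate in Hz.
#' @param segment Segment length in samples (default 128).
#' @param overlap_fraction Fractional overlap in `[0, 1)` (default 0.5).
#' @return A list of class `psd_estimate` with ascending `frequencies` (Hz,
#'   from 0 to Nyquist) and non-negative `powers` (density, a.u.^2/Hz).
#' @export
welch_psd <- function(x, sampling_rate_hz, segment = 128,
                      overlap_fraction = 0.5) {
  check_window(x, min_len = 2L)
  stopifnot_scalar_number(sampling_rate_hz, "sampling_rate_hz", positive = TRUE)
  segment <- as.integer(segment)
  if (segment > length(x)) {
    stop("welch_psd: segment longer than the signal", call. = FALSE)
  }
  step <- max(1L, as.integer(round(segment * (1 - overlap_fraction))))
  starts <- seq(1L, length(x) - segment + 1L, by = step)
  n <- seq_len(segment) - 1L
  taper <- 0.5 - 0.5 * cos(2 * pi * n / (segment - 1L))  # Hann
  scale <- sampling_rate_hz * sum(taper^2)
  n_freq <- segment %/% 2L + 1L
  acc <- numeric(n_freq)
  for (s in starts) {
    seg <- x[s:(s + segment - 1L)] * taper
    sp <- abs(stats::fft(seg))^2 / scale
    acc <- acc + sp[seq_len(n_freq)]
  }
  p <- acc / length(starts)
  # one-sided: double everything except DC (and Nyquist when segment is even)
  dbl <- rep(2, n_freq)
  dbl[1] <- 1
  if (segment %% 2L == 0L) dbl[n_freq] <- 1
  p <- p * dbl
  freqs <- (seq_len(n_freq) - 1L) * sampling_rate_hz / segment
  structure(list(frequencies = freqs, powers = p), class = "psd_estimate")
}

check_psd <- function(psd) {
  if (!inherits(psd, "psd_estimate")) {
    if (is.list(psd) && all(c("frequencies", "powers") %in% names(psd))) {
      psd <- structure(psd, class = "psd_estimate")
    } else {
      stop("expected a psd_estimate", call. = FALSE)
    }
  }
  if (any(psd$powers < 0)) stop("negative spectral powers", call. = FALSE)
  if (is.unsorted(psd$frequencies, strictly = TRUE)) {
    stop("PSD frequencies must be strictly increasing", call. = FALSE)
  }
  psd
}

#' Mean frequency of a power spectrum
#'
#' Power-weighted mean frequency, `sum(f * P) / sum(P)`.
#'
#' @param psd A `psd_estimate` (see [welch_psd()]).
#' @return Frequency in Hz, within the spectrum's frequency range.
#' @export
mnf <- function(psd) {
  psd <- check_psd(psd)
  tot <- sum(psd$powers)
  if (tot <= 0) stop("mnf undefined: all spectral powers are zero", call. = FALSE)
  sum(psd$frequencies * psd$powers) / tot
}

#' Median frequency of a power spectrum
#'
#' Smallest bin frequency at which the cumulative power reaches half of the
#' total power (bin-wise, no interpolation).
#'
#' @param psd A `psd_estimate`.
#' @return Frequency in Hz.
#' @export
mdf <- function(psd) {
  psd <- check_psd(psd)
  tot <- sum(psd$powers)
  if (tot <= 0) stop("mdf undefined: all spectral powers are zero", call. = FALSE)
  idx <- which(cumsum(psd$powers) >= tot / 2)[1]
  psd$frequencies[idx]
}

#' Mean power of a spectrum (frequency-normalized form)
#'
#' Computed as `sum(f * P) / sum(f)` -- the power-frequency cross sum
#' normalized by the frequency sum. This is the form this pipeline uses
#' throughout; note it differs from the plain spectral mean
#' `mean(P)`, which is available as [mnp_conventional()] for comparison.
#'
#' @param psd A `psd_estimate`.
#' @return Non-negative value; scales like power (amplitude squared).
#' @export
mnp <- function(psd) {
  psd <- check_psd(psd)
  fsum <- sum(psd$frequencies)
  if (fsum <= 0) {
    stop("mnp undefined: frequency sum is zero (single DC bin?)", call. = FALSE)
  }
  sum(psd$frequencies * psd$powers) / fsum
}

#' Conventional mean power of a spectrum
#'
#' The plain average of the spectral values, `mean(P)` -- the form most of
#' the myoelectric literature calls MNP. Provided for comparison with
#' [mnp()].
#'
#' @param psd A `psd_estimate`.
#' @return Non-negative value.
#' @export
mnp_conventional <- function(psd) {
  psd <- check_psd(psd)
  mean(psd$powers)
}

#' Peak frequency of a power spectrum
#'
#' Frequency of the maximum-power bin; ties are broken toward the lowest
#' frequency for determinism.
#'
#' @param psd A `psd_estimate`.
#' @return Frequency in Hz.
#' @export
pkf <- function(psd) {
  psd <- check_psd(psd)
  psd$frequencies[which.max(psd$powers)]
}

#' Power spectrum ratio
#'
#' Ratio `P0 / P` where `P0` sums the spectral power within `epsilon_hz` of
#' the peak frequency (clipped to the band) and `P` sums the power over the
#' whole band `(f1, f2)`.
#'
#' @param psd A `psd_estimate`.
#' @param epsilon_hz Half-width of the peak band, Hz (default 10).
#' @param band Two-element `(f1, f2)` band limits; `NULL` = full spectrum.
#' @return Value in `(0, 1]` when the peak lies inside the band.
#' @export
psr <- function(psd, epsilon_hz = 10, band = NULL) {
  psd <- check_psd(psd)
  f <- psd$frequencies
  p <- psd$powers
  if (is.null(band)) band <- range(f)
  if (band[1] >= band[2]) stop("psr band must have f1 < f2", call. = FALSE)
  in_band <- f >= band[1] & f <= band[2]
  denom <- sum(p[in_band])
  if (denom <= 0) stop("psr undefined: zero power in band", call. = FALSE)
  f0 <- pkf(psd)
  lo <- max(f0 - epsilon_hz, band[1])
  hi <- min(f0 + epsilon_hz, band[2])
  num <- sum(p[f >= lo & f <= hi])
  num / denom
}

# Number of sliding windows for a trial of `n` samples.
n_windows_for <- function(n, window, stride) {
  if (n < window) return(0L)
  as.integer((n - window) %/% stride + 1L)
}

compute_window_features <- function(w, config, sampling_rate_hz) {
  fs <- config$feature_set
  need_psd <- any(fs %in% c("MNF", "MDF", "MNP", "PSR", "PKF"))
  psd <- if (need_psd) {
    welch_psd(w, sampling_rate_hz, segment = config$welch_segment,
              overlap_fraction = config$welch_overlap_fraction)
  } else {
    NULL
  }
  vapply(fs, function(f) {
    switch(f,
      MAV = mav(w),
      STD = emg_std(w),
      RMS = rms(w),
      LOG = log_detector(w, config$log_floor),
      AAC = aac(w),
      MNF = mnf(psd),
      MDF = mdf(psd),
      MNP = mnp(psd),
      PSR = psr(psd, config$psr_epsilon_hz, config$psr_band),
      PKF = pkf(psd)
    )
  }, numeric(1))
}

#' Extract windowed features from one trial
#'
#' Slides half-open windows `[start, start + window)` over the trial with the
#' configured stride and computes the configured features per window and
#' channel.
#'
#' @param trial An [emg_trial()].
#' @param config A [feature_config()].
#' @return A `feature_series`: list with the trial metadata and `values`, a
#'   numeric array of shape (n_windows, n_channels, n_features) with feature
#'   names on the last dimension.
#' @export
extract_features <- function(trial, config = feature_config()) {
  stopifnot(inherits(trial, "emg_trial"))
  n <- nrow(trial$samples)
  nc <- ncol(trial$samples)
  nw <- n_windows_for(n, config$window_samples, config$stride_samples)
  if (nw < 1L) {
    stop(sprintf("trial has %d samples, shorter than one %d-sample window",
                 n, config$window_samples), call. = FALSE)
  }
  nf <- length(config$feature_set)
  vals <- array(NA_real_, dim = c(nw, nc, nf),
                dimnames = list(NULL, NULL, config$feature_set))
  for (wi in seq_len(nw)) {
    start <- (wi - 1L) * config$stride_samples + 1L
    idx <- start:(start + config$window_samples - 1L)
    for (ci in seq_len(nc)) {
      vals[wi, ci, ] <- compute_window_features(
        trial$samples[idx, ci], config, trial$sampling_rate_hz
      )
    }
  }
  structure(
    list(subject_id = trial$subject_id, motion_label = trial$motion_label,
         trial_index = trial$trial_index, values = vals,
         feature_set = config$feature_set),
    class = "feature_series"
  )
}

#' Flatten feature series to a tidy table
#'
#' @param series_list List of `feature_series` (from [extract_features()]).
#' @return data.frame with columns subject, motion, trial, window, channel,
#'   feature, value.
#' @export
features_to_table <- function(series_list) {
  rows <- lapply(series_list, function(fs) {
    d <- dim(fs$values)
    grid <- expand.grid(window = seq_len(d[1]), channel = seq_len(d[2]),
                        feature = fs$feature_set, stringsAsFactors = FALSE)
    grid$value <- as.vector(fs$values)
    grid$subject <- fs$subject_id
    grid$motion <- fs$motion_label
    grid$trial <- fs$trial_index
    grid[, c("subject", "motion", "trial", "window", "channel", "feature",
             "value")]
  })
  do.call(rbind, rows)
}
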