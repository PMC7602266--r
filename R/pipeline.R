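# End-to-end orchestration: feature extraction, standardization, optional
# bilinear factorization with new-user adaptation, classification, and the
# two evaluation protocols (within-subject 80/20 split and
# leave-one-subject-out cross-validation).

#' Pipeline configuration
#'
#' @param features A [feature_config()].
#' @param selected_features Feature subset fed to the classifier / bilinear
#'   stage; default the six features retained by permutation importance:
#'   RMS, LOG, AAC, PSR, MNP, MDF.
#' @param classifier `"centroid"` (deterministic nearest-centroid, the
#'   default evaluation classifier) or `"lstm"`.
#' @param train A [train_config()] for the LSTM.
#' @param bilinear Logical: fit the bilinear stage in LOSO runs.
#' @param I,J Latent user/motion factor dimensions (defaults 6 and 120, the
#'   operating point for a 19-training-user, 10-repetition cohort). Both are
#'   clipped to their feasible ranges for the data at hand: `I <= U`,
#'   `J <= M*N`.
#' @param tol,max_iter Bilinear fit stopping parameters.
#' @param log_amplitude Log-transform the amplitude-scale features (MAV,
#'   STD, RMS, LOG, AAC, MNP) before standardization (default `TRUE`).
#'   Multiplicative user gains -- the dominant between-subject amplitude
#'   confound in surface EMG -- become additive low-rank structure under the
#'   log, which both arms handle better and which the bilinear user factor
#'   can absorb exactly.
#' @param calibration_motion Motion whose trials the held-out subject
#'   contributes for adaptation (default `"M1"`).
#' @param n_calibration_trials How many of that motion's trials to use;
#'   `NULL` (default) uses all of them. Calibration trials are excluded from
#'   testing in both arms.
#' @param seed Seed for splits and LSTM initialization.
#' @param rcond Pseudo-inverse cutoff for adaptation.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(features = feature_config(),
                            selected_features = c("RMS", "LOG", "AAC", "PSR",
                                                  "MNP", "MDF"),
                            classifier = c("centroid", "lstm"),
                            train = train_config(),
                            bilinear = TRUE, I = 6L, J = 120L,
                            tol = 1e-6, max_iter = 50L,
                            log_amplitude = TRUE,
                            calibration_motion = "M1",
                            n_calibration_trials = NULL,
                            seed = 1L, rcond = 1e-10) {
  classifier <- match.arg(classifier)
  structure(
    list(features = features, selected_features = selected_features,
         classifier = classifier, train = train, bilinear = bilinear,
         I = as.integer(I), J = as.integer(J), tol = tol,
         max_iter = as.integer(max_iter), log_amplitude = log_amplitude,
         calibration_motion = calibration_motion,
         n_calibration_trials = n_calibration_trials,
         seed = as.integer(seed), rcond = rcond),
    class = "pipeline_config"
  )
}

# Features that scale with signal amplitude (and so with user gain); these
# are positive and are log-transformed when config$log_amplitude is set.
AMPLITUDE_FEATURES <- c("MAV", "STD", "RMS", "LOG", "AAC", "MNP")

apply_log_amplitude <- function(series_list, floor = 1e-12) {
  lapply(series_list, function(fs) {
    f <- intersect(AMPLITUDE_FEATURES, fs$feature_set)
    if (length(f) > 0L) fs$values[, , f] <- log(pmax(fs$values[, , f], floor))
    fs
  })
}

# Motions ordered by their position in the ASL vocabulary where possible.
motion_order <- function(labels) {
  u <- unique(labels)
  pos <- match(u, names(asl_vocabulary()))
  u[order(ifelse(is.na(pos), Inf, pos), u)]
}

# Per (channel, feature) mean/sd over all windows of the given series.
standardize_stats <- function(series_list, features) {
  mats <- lapply(series_list, function(fs) {
    v <- fs$values[, , features, drop = FALSE]
    matrix(v, nrow = dim(v)[1], ncol = dim(v)[2] * dim(v)[3])
  })
  all <- do.call(rbind, mats)
  mu <- colMeans(all)
  sd <- apply(all, 2L, stats::sd)
  sd[!is.finite(sd) | sd < 1e-12] <- 1
  list(mean = mu, sd = sd, features = features)
}

# Standardized C_eff x n_windows matrix for one trial (rows: channel fastest
# within feature, matching the sequence flattening).
series_matrix <- function(fs, stats) {
  v <- fs$values[, , stats$features, drop = FALSE]
  m <- matrix(v, nrow = dim(v)[1], ncol = dim(v)[2] * dim(v)[3])
  t((t(m) - stats$mean) / stats$sd)  # still windows x dims; transpose below
}

standardized_sequences <- function(series_list, stats) {
  seqs <- lapply(series_list, series_matrix, stats = stats)
  sequence_dataset(
    seqs,
    labels = vapply(series_list, `[[`, character(1), "motion_label"),
    subjects = vapply(series_list, `[[`, character(1), "subject_id")
  )
}

# Stacked data matrix for the bilinear fit. Rows: channel-feature blocks
# (C_eff blocks, one training subject per row within a block); columns:
# motion-major, within a motion ordered by (subject? no -) repetition =
# (trial, window), consistent across subjects. Every (subject, motion) must
# contribute the same number of repetition columns.
build_bilinear_y <- function(series_list, stats, subjects, motions) {
  key <- paste(vapply(series_list, `[[`, character(1), "subject_id"),
               vapply(series_list, `[[`, character(1), "motion_label"))
  mats <- lapply(series_list, function(fs) t(series_matrix(fs, stats)))
  # mats: C_eff x n_windows per trial
  C_eff <- nrow(mats[[1]])
  per_um <- split(seq_along(series_list), key)
  reps <- NULL
  blocks <- array(NA_real_, dim = c(length(subjects), 0, C_eff))
  cols_per_motion <- NULL
  # assemble per (u, m): C_eff x N_eff by concatenating trials (sorted by
  # trial index) along columns
  get_um <- function(u, m) {
    idx <- per_um[[paste(u, m)]]
    if (is.null(idx)) {
      stop(sprintf("no trials for subject %s, motion %s", u, m), call. = FALSE)
    }
    ord <- order(vapply(series_list[idx], `[[`, integer(1), "trial_index"))
    do.call(cbind, mats[idx[ord]])
  }
  n_eff <- ncol(get_um(subjects[1], motions[1]))
  U <- length(subjects); M <- length(motions)
  Y <- matrix(NA_real_, C_eff * U, M * n_eff)
  for (mi in seq_along(motions)) {
    for (ui in seq_along(subjects)) {
      block <- get_um(subjects[ui], motions[mi])
      if (ncol(block) != n_eff) {
        stop("unequal repetition counts across (subject, motion) cells",
             call. = FALSE)
      }
      cols <- ((mi - 1L) * n_eff + 1L):(mi * n_eff)
      rows <- (seq_len(C_eff) - 1L) * U + ui
      Y[rows, cols] <- block
    }
  }
  list(Y = stacked_matrix(Y, C_eff), n_eff = n_eff, C_eff = C_eff)
}

# Sequences (one per trial) from the fitted model's motion-factor columns.
factor_training_sequences <- function(model, motions, n_windows) {
  J <- model$dims$J
  seqs <- list(); labels <- character(0)
  n_eff <- model$dims$N
  n_trials <- n_eff %/% n_windows
  for (mi in seq_along(motions)) {
    base <- (mi - 1L) * n_eff
    for (tr in seq_len(n_trials)) {
      cols <- base + ((tr - 1L) * n_windows + 1L):(tr * n_windows)
      seqs[[length(seqs) + 1L]] <- t(model$X[, cols, drop = FALSE])
      labels <- c(labels, motions[mi])
    }
  }
  sequence_dataset(seqs, labels)
}

fit_fold_classifier <- function(ds, config) {
  train_classifier(ds, config$classifier, config$train)
}

#' Within-subject evaluation with a stratified 80/20 split
#'
#' Extracts features, standardizes them on the training split, trains the
#' configured classifier and evaluates on the held-out 20% of trials
#' (stratified per motion). Mirrors the single-participant protocol.
#'
#' @param trials List of [emg_trial()] (typically one subject).
#' @param config A [pipeline_config()].
#' @param out_dir Optional output directory for result tables and a JSON run
#'   summary.
#' @return List with `eval` (an `eval_result`), `train_idx`, and `config`.
#' @export
run_single_subject <- function(trials, config = pipeline_config(),
                               out_dir = NULL) {
  series <- lapply(trials, extract_features, config = config$features)
  if (isTRUE(config$log_amplitude)) series <- apply_log_amplitude(series)
  labels <- vapply(series, `[[`, character(1), "motion_label")
  train_idx <- with_seed(config$seed, stratified_split(labels, 0.8))
  test_idx <- setdiff(seq_along(series), train_idx)
  stats <- standardize_stats(series[train_idx], config$selected_features)
  classifier <- fit_fold_classifier(standardized_sequences(series[train_idx], stats),
                                    config)
  ev <- evaluate_classifier(classifier,
                            standardized_sequences(series[test_idx], stats),
                            classes = motion_order(labels))
  res <- list(eval = ev, train_idx = train_idx, config = config)
  if (!is.null(out_dir)) {
    write_run_outputs(out_dir, "single_subject",
                      list(overall_accuracy = ev$overall,
                           n_test = ev$n, classifier = config$classifier),
                      confusion = ev$confusion,
                      per_motion = ev$per_motion,
                      per_subject = ev$per_subject)
  }
  res
}

#' Leave-one-subject-out cross-validation
#'
#' One fold per subject: the classifier is trained on all other subjects and
#' tested on the held-out subject. When `config$bilinear` is `TRUE` both arms
#' run on the same folds, features and seeds: the *raw* arm classifies
#' standardized feature sequences directly; the *bilinear* arm fits the
#' user x motion factorization on the training subjects, adapts to the
#' held-out subject from their calibration-motion trials (closed-form
#' three-step adaptation), projects the remaining trials onto motion factors
#' and classifies those. Calibration trials are excluded from testing in
#' both arms so the comparison isolates the bilinear stage.
#'
#' @param trials List of [emg_trial()] spanning >= 2 subjects.
#' @param config A [pipeline_config()].
#' @param series Optional precomputed list of `feature_series` (one per
#'   trial), e.g. when scanning a grid of `(I, J)`.
#' @param out_dir Optional output directory.
#' @return List with `folds` (per subject: `raw` and optionally `bilinear`
#'   `eval_result`s plus the fold's fitted dims), `aggregate_raw`,
#'   `aggregate_bilinear` (pooled over folds), `per_fold` (paired accuracy
#'   table) and the effective `I`, `J`.
#' @export
run_loso <- function(trials, config = pipeline_config(), series = NULL,
                     out_dir = NULL) {
  if (is.null(series)) {
    series <- lapply(trials, extract_features, config = config$features)
  }
  if (isTRUE(config$log_amplitude)) series <- apply_log_amplitude(series)
  subjects <- sort(unique(vapply(series, `[[`, character(1), "subject_id")))
  if (length(subjects) < 2L) stop("LOSO needs at least 2 subjects", call. = FALSE)
  labels <- vapply(series, `[[`, character(1), "motion_label")
  motions <- motion_order(labels)
  subj_of <- vapply(series, `[[`, character(1), "subject_id")

  folds <- list()
  truth_raw <- pred_raw <- truth_bl <- pred_bl <- character(0)
  subj_raw <- subj_bl <- character(0)
  I_eff_used <- J_eff_used <- NA_integer_

  for (s in subjects) {
    train_series <- series[subj_of != s]
    test_all <- series[subj_of == s]
    test_motions <- vapply(test_all, `[[`, character(1), "motion_label")
    cal_idx <- integer(0)
    if (config$bilinear) {
      cand <- which(test_motions == config$calibration_motion)
      if (length(cand) == 0L) {
        stop(sprintf("subject %s has no trials of calibration motion %s",
                     s, config$calibration_motion), call. = FALSE)
      }
      cand <- cand[order(vapply(test_all[cand], `[[`, integer(1), "trial_index"))]
      n_cal <- config$n_calibration_trials %||% length(cand)
      cal_idx <- cand[seq_len(min(n_cal, length(cand)))]
    }
    test_idx <- setdiff(seq_along(test_all), cal_idx)
    test_series <- test_all[test_idx]

    stats <- standardize_stats(train_series, config$selected_features)
    # raw arm
    raw_classifier <- fit_fold_classifier(
      standardized_sequences(train_series, stats), config
    )
    raw_eval <- evaluate_classifier(raw_classifier,
                                    standardized_sequences(test_series, stats),
                                    classes = motions)
    fold <- list(subject = s, raw = raw_eval)
    truth_raw <- c(truth_raw, vapply(test_series, `[[`, character(1), "motion_label"))
    pred_raw <- c(pred_raw,
                  predict_classifier(raw_classifier,
                                     standardized_sequences(test_series, stats))$labels)
    subj_raw <- c(subj_raw, rep(s, length(test_series)))

    if (config$bilinear) {
      train_subjects <- setdiff(subjects, s)
      yb <- build_bilinear_y(train_series, stats, train_subjects, motions)
      n_windows <- nrow(series_matrix(train_series[[1]], stats))
      I_eff <- min(config$I, length(train_subjects))
      J_eff <- min(config$J, length(motions) * yb$n_eff)
      model <- bl_fit(yb$Y, I_eff, J_eff, n_motions = length(motions),
                      tol = config$tol, max_iter = config$max_iter)
      I_eff_used <- I_eff; J_eff_used <- J_eff
      factor_ds <- factor_training_sequences(model, motions, n_windows)
      bl_classifier <- fit_fold_classifier(factor_ds, config)
      # adaptation from the held-out subject's calibration trials
      cal_sorted <- test_all[cal_idx]
      Y_cal <- do.call(cbind, lapply(cal_sorted, function(fs) t(series_matrix(fs, stats))))
      m_cal <- match(config$calibration_motion, motions)
      adapted <- bl_adapt(model, Y_cal, m_cal, rcond = config$rcond)
      proj_seqs <- lapply(test_series, function(fs) {
        t(bl_project(adapted, t(series_matrix(fs, stats))))
      })
      proj_ds <- sequence_dataset(
        proj_seqs,
        labels = vapply(test_series, `[[`, character(1), "motion_label"),
        subjects = rep(s, length(test_series))
      )
      bl_eval <- evaluate_classifier(bl_classifier, proj_ds, classes = motions)
      fold$bilinear <- bl_eval
      fold$adaptation <- list(residual = adapted$residual,
                              condition = adapted$condition)
      fold$dims <- model$dims
      truth_bl <- c(truth_bl, proj_ds$labels)
      pred_bl <- c(pred_bl, predict_classifier(bl_classifier, proj_ds)$labels)
      subj_bl <- c(subj_bl, rep(s, length(test_series)))
    }
    folds[[s]] <- fold
  }

  aggregate_raw <- eval_predictions(truth_raw, pred_raw, subj_raw, motions)
  aggregate_bilinear <- if (config$bilinear) {
    eval_predictions(truth_bl, pred_bl, subj_bl, motions)
  } else {
    NULL
  }
  per_fold <- data.frame(
    subject = subjects,
    raw_accuracy = vapply(folds, function(f) f$raw$overall, numeric(1)),
    bilinear_accuracy = if (config$bilinear) {
      vapply(folds, function(f) f$bilinear$overall, numeric(1))
    } else {
      NA_real_
    },
    row.names = NULL, stringsAsFactors = FALSE
  )
  res <- list(folds = folds, aggregate_raw = aggregate_raw,
              aggregate_bilinear = aggregate_bilinear, per_fold = per_fold,
              I = I_eff_used, J = J_eff_used, config = config)
  if (!is.null(out_dir)) {
    write_run_outputs(out_dir, "loso",
                      list(raw_accuracy = aggregate_raw$overall,
                           bilinear_accuracy = if (config$bilinear) aggregate_bilinear$overall else NULL,
                           I = res$I, J = res$J, n_folds = length(subjects),
                           classifier = config$classifier),
                      confusion = if (config$bilinear) aggregate_bilinear$confusion else aggregate_raw$confusion,
                      per_motion = (aggregate_bilinear %||% aggregate_raw)$per_motion,
                      per_subject = (aggregate_bilinear %||% aggregate_raw)$per_subject,
                      per_fold = per_fold)
  }
  res
}

#' Grid search over (I, J) with the LOSO evaluation callback
#'
#' Runs [run_loso()] at every candidate `(I, J)` (features computed once and
#' shared) and reports the bilinear-arm aggregate accuracy surface.
#'
#' @param trials List of [emg_trial()].
#' @param config A [pipeline_config()].
#' @param I_values,J_values Candidate dimensions.
#' @param out_dir Optional output directory (writes the surface table).
#' @return As [grid_search_ij()]: `surface` and `best`.
#' @export
run_grid <- function(trials, config = pipeline_config(), I_values, J_values,
                     out_dir = NULL) {
  series <- lapply(trials, extract_features, config = config$features)
  res <- grid_search_ij(I_values, J_values, function(I, J) {
    cfg <- config
    cfg$I <- as.integer(I); cfg$J <- as.integer(J)
    run_loso(NULL, cfg, series = series)$aggregate_bilinear$overall
  })
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(res$surface, file.path(out_dir, "grid_surface.csv"),
                     row.names = FALSE)
  }
  res
}

# Write result tables plus a small JSON summary; one line per artifact in a
# plain-text log.
write_run_outputs <- function(out_dir, prefix, summary, confusion = NULL,
                              per_motion = NULL, per_subject = NULL,
                              per_fold = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- sprintf("[%s] %s run", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                       prefix)
  save_tbl <- function(x, name) {
    p <- file.path(out_dir, sprintf("%s_%s.csv", prefix, name))
    utils::write.csv(x, p, row.names = !is.null(rownames(x)))
    log_lines <<- c(log_lines, sprintf("wrote %s", p))
  }
  if (!is.null(confusion)) save_tbl(as.data.frame.matrix(confusion), "confusion")
  if (!is.null(per_motion)) {
    save_tbl(data.frame(motion = names(per_motion),
                        accuracy = unname(per_motion)), "per_motion")
  }
  if (!is.null(per_subject)) {
    save_tbl(data.frame(subject = names(per_subject),
                        accuracy = unname(per_subject)), "per_subject")
  }
  if (!is.null(per_fold)) save_tbl(per_fold, "per_fold")
  jsonlite::write_json(summary, file.path(out_dir, sprintf("%s_summary.json", prefix)),
                       auto_unbox = TRUE, digits = NA)
  writeLines(log_lines, file.path(out_dir, sprintf("%s_run.log", prefix)))
  invisible(out_dir)
}
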