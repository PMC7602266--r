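#' The 20-phrase ASL motion vocabulary
#'
#' Ordered label vocabulary used throughout the package: codes `M1`..`M20`
#' mapped to the American Sign Language phrases the recognizer targets
#' ("How are you?" through "I love you.").
#'
#' @return Named character vector of length 20; names are the motion codes
#'   `M1`..`M20`, values are the phrases.
#' @export
#' @examples
#' asl_vocabulary()[c("M1", "M20")]
asl_vocabulary <- function() {
  c(
    M1  = "How are you?",
    M2  = "Nice to meet you.",
    M3  = "See you later.",
    M4  = "That's what I mean.",
    M5  = "I don't understand.",
    M6  = "What is your name?",
    M7  = "Where are you from?",
    M8  = "What happens?",
    M9  = "What is wrong?",
    M10 = "Please call 911.",
    M11 = "Where is the store?",
    M12 = "How can I get food?",
    M13 = "How much does it cost?",
    M14 = "Yes, thank you.",
    M15 = "I am sorry.",
    M16 = "Where is the hospital?",
    M17 = "I don't feel good.",
    M18 = "Please help me.",
    M19 = "Please write it.",
    M20 = "I love you."
  )
}

#' Construct a single EMG trial
#'
#' An `emg_trial` holds one recording window of a subject performing one
#' motion: a numeric samples-by-channels matrix plus identifying metadata.
#'
#' @param samples Numeric matrix, rows = time samples, columns = channels.
#'   All values must be finite; at least 2 rows and 1 column.
#' @param subject_id Character scalar subject identifier.
#' @param motion_label Character scalar motion code (e.g. `"M1"`).
#' @param trial_index Integer >= 0, repetition index within (subject, motion).
#' @param sampling_rate_hz Positive sampling rate in Hz (default 200, the
#'   rate of the 8-channel armband the pipeline targets).
#' @return An object of class `emg_trial`.
#' @export
emg_trial <- function(samples, subject_id, motion_label, trial_index,
                      sampling_rate_hz = 200) {
  samples <- as.matrix(samples)
  storage.mode(samples) <- "double"
  if (nrow(samples) < 2L) stop("trial needs at least 2 samples", call. = FALSE)
  if (ncol(samples) < 1L) stop("trial needs at least 1 channel", call. = FALSE)
  if (any(!is.finite(samples))) {
    stop("trial samples contain non-finite values", call. = FALSE)
  }
  stopifnot_scalar_number(sampling_rate_hz, "sampling_rate_hz", positive = TRUE)
  trial_index <- as.integer(trial_index)
  if (is.na(trial_index) || trial_index < 0L) {
    stop("`trial_index` must be a non-negative integer", call. = FALSE)
  }
  structure(
    list(
      subject_id = as.character(subject_id),
      motion_label = as.character(motion_label),
      trial_index = trial_index,
      sampling_rate_hz = as.numeric(sampling_rate_hz),
      samples = samples
    ),
    class = "emg_trial"
  )
}

#' @export
print.emg_trial <- function(x, ...) {
  cat(sprintf(
    "<emg_trial> subject %s, motion %s, trial %d: %d samples x %d channels @ %g Hz\n",
    x$subject_id, x$motion_label, x$trial_index,
    nrow(x$samples), ncol(x$samples), x$sampling_rate_hz
  ))
  invisible(x)
}

# Detect the delimiter of one data line: comma, tab, else whitespace.
detect_delim <- function(line) {
  if (grepl(",", line, fixed = TRUE)) return(",")
  if (grepl("\t", line, fixed = TRUE)) return("\t")
  "[[:space:]]+"
}

#' Read one EMG trial from a delimited text file
#'
#' Trial files are plain delimited numeric tables (comma, tab or whitespace
#' separated, auto-detected), one row per time sample, one column per channel,
#' no header. Metadata comes from the accompanying manifest entry.
#'
#' @param path Path to the signal file.
#' @param subject_id,motion_label,trial_index,sampling_rate_hz Trial metadata
#'   (typically one manifest row).
#' @param n_channels Optional expected channel count; a mismatch is an error.
#' @return An [emg_trial()].
#' @export
read_trial <- function(path, subject_id, motion_label, trial_index,
                       sampling_rate_hz = 200, n_channels = NULL) {
  if (!file.exists(path)) stop(sprintf("trial file not found: %s", path), call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop(sprintf("empty trial file: %s", path), call. = FALSE)
  delim <- detect_delim(lines[[1]])
  parts <- strsplit(trimws(lines), delim)
  ncols <- lengths(parts)
  if (any(ncols != ncols[1])) {
    bad <- which(ncols != ncols[1])[1]
    stop(sprintf("parse error in %s at line %d: expected %d columns, found %d",
                 path, bad, ncols[1], ncols[bad]), call. = FALSE)
  }
  vals <- suppressWarnings(as.numeric(unlist(parts, use.names = FALSE)))
  if (anyNA(vals)) {
    bad_line <- which(vapply(parts, function(p) {
      anyNA(suppressWarnings(as.numeric(p)))
    }, logical(1)))[1]
    stop(sprintf("parse error in %s at line %d: non-numeric value",
                 path, bad_line), call. = FALSE)
  }
  if (any(!is.finite(vals))) {
    stop(sprintf("validation error in %s: non-finite sample values", path),
         call. = FALSE)
  }
  mat <- matrix(vals, nrow = length(parts), ncol = ncols[1], byrow = TRUE)
  if (!is.null(n_channels) && ncol(mat) != n_channels) {
    stop(sprintf("validation error in %s: %d channels, expected %d",
                 path, ncol(mat), n_channels), call. = FALSE)
  }
  emg_trial(mat, subject_id, motion_label, trial_index, sampling_rate_hz)
}

#' Write one EMG trial to a delimited text file
#'
#' Writes the samples matrix as comma-separated text at full double precision
#' (`%.17g`), so `read_trial(write_trial(x))` reproduces the samples exactly.
#'
#' @param trial An [emg_trial()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trial <- function(trial, path) {
  stopifnot(inherits(trial, "emg_trial"))
  m <- trial$samples
  rows <- apply(m, 1L, function(r) paste(sprintf("%.17g", r), collapse = ","))
  writeLines(rows, path)
  invisible(path)
}

#' Read a dataset manifest
#'
#' The manifest is a header-ed CSV with columns `path`, `subject`, `motion`,
#' `trial` and optionally `sampling_rate`. Relative signal paths are resolved
#' against the manifest's directory.
#'
#' @param path Manifest CSV path.
#' @param vocabulary Ordered motion vocabulary codes; defaults to the names of
#'   [asl_vocabulary()].
#' @return A data.frame with the resolved entries plus attributes
#'   `vocabulary` and `sampling_rate_hz`.
#' @export
read_manifest <- function(path, vocabulary = names(asl_vocabulary())) {
  if (!file.exists(path)) stop(sprintf("manifest not found: %s", path), call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("path", "subject", "motion", "trial")
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols) > 0L) {
    stop(sprintf("manifest missing column(s): %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  if (nrow(df) > 0L) {
    key <- paste(df$subject, df$motion, df$trial, sep = "\r")
    if (anyDuplicated(key)) {
      stop("manifest contains duplicate (subject, motion, trial) entries",
           call. = FALSE)
    }
    bad <- setdiff(unique(df$motion), vocabulary)
    if (length(bad) > 0L) {
      stop(sprintf("manifest motion label(s) not in vocabulary: %s",
                   paste(bad, collapse = ", ")), call. = FALSE)
    }
    rel <- !grepl("^(/|[A-Za-z]:)", df$path)
    df$path[rel] <- file.path(dirname(path), df$path[rel])
  }
  rate <- if ("sampling_rate" %in% names(df) && nrow(df) > 0L) {
    r <- unique(df$sampling_rate)
    if (length(r) != 1L) {
      stop("manifest has inconsistent sampling rates", call. = FALSE)
    }
    r
  } else {
    200
  }
  attr(df, "vocabulary") <- vocabulary
  attr(df, "sampling_rate_hz") <- rate
  df
}

#' Load a whole dataset of EMG trials from a manifest
#'
#' Reads every trial listed in the manifest, in manifest order, and validates
#' that channel counts agree across the dataset.
#'
#' @param manifest_path Path to a manifest CSV (see [read_manifest()]).
#' @param vocabulary Motion vocabulary codes.
#' @return List of [emg_trial()] objects, one per manifest row.
#' @export
load_dataset <- function(manifest_path, vocabulary = names(asl_vocabulary())) {
  mf <- read_manifest(manifest_path, vocabulary)
  rate <- attr(mf, "sampling_rate_hz")
  trials <- vector("list", nrow(mf))
  n_channels <- NULL
  for (i in seq_len(nrow(mf))) {
    if (!file.exists(mf$path[i])) {
      stop(sprintf("manifest entry %d (%s, %s, trial %s): file not found: %s",
                   i, mf$subject[i], mf$motion[i], mf$trial[i], mf$path[i]),
           call. = FALSE)
    }
    tr <- read_trial(mf$path[i], mf$subject[i], mf$motion[i], mf$trial[i],
                     sampling_rate_hz = rate, n_channels = n_channels)
    if (is.null(n_channels)) n_channels <- ncol(tr$samples)
    trials[[i]] <- tr
  }
  trials
}

#' Write a cohort of trials plus manifest to a directory
#'
#' Companion to [load_dataset()]: writes one delimited signal file per trial
#' and a manifest CSV, so synthetic cohorts can be fed through the file-based
#' pipeline unchanged.
#'
#' @param trials List of [emg_trial()] objects.
#' @param dir Output directory (created if needed).
#' @param manifest_name File name for the manifest CSV.
#' @return Path to the manifest, invisibly.
#' @export
write_dataset <- function(trials, dir, manifest_name = "manifest.csv") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(seq_along(trials), function(i) {
    tr <- trials[[i]]
    fname <- sprintf("%s_%s_t%02d.csv", tr$subject_id, tr$motion_label,
                     tr$trial_index)
    write_trial(tr, file.path(dir, fname))
    data.frame(path = fname, subject = tr$subject_id,
               motion = tr$motion_label, trial = tr$trial_index,
               sampling_rate = tr$sampling_rate_hz,
               stringsAsFactors = FALSE)
  })
  mf <- do.call(rbind, rows)
  mpath <- file.path(dir, manifest_name)
  utils::write.csv(mf, mpath, row.names = FALSE)
  invisible(mpath)
}

serialize_matrix <- function(m) {
  list(dim = dim(m), data = sprintf("%.17g", as.vector(m)))
}

deserialize_matrix <- function(obj) {
  matrix(as.numeric(obj$data), nrow = obj$dim[1], ncol = obj$dim[2])
}

MODEL_FORMAT_VERSION <- "emgsign-model-1"

#' Save a fitted model to a portable text container
#'
#' Serializes a fitted bilinear model (or trained classifier) to a single
#' JSON container holding named matrices at full double precision plus
#' metadata (dimensions, configuration, format version). The round trip
#' `load_model(save_model(m))` reproduces all matrices bit-identically.
#'
#' @param model A fitted `bilinear_model` (see [bl_fit()]) or a classifier
#'   from [train_classifier()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path) {
  if (inherits(model, "bilinear_model")) {
    payload <- list(
      version = MODEL_FORMAT_VERSION,
      type = "bilinear_model",
      dims = model$dims,
      Z = serialize_matrix(model$Z),
      W = serialize_matrix(model$W$data),
      W_block_count = model$W$block_count,
      X = serialize_matrix(model$X),
      motion_of_column = model$motion_of_column,
      objective_history = sprintf("%.17g", model$objective_history),
      converged = model$converged,
      iterations = model$iterations,
      config = model$config
    )
  } else if (inherits(model, "emg_classifier")) {
    mats <- lapply(model$weights, serialize_matrix)
    payload <- list(
      version = MODEL_FORMAT_VERSION,
      type = "emg_classifier",
      kind = model$kind,
      classes = model$classes,
      weights = mats,
      config = model$config
    )
  } else {
    stop("save_model: unsupported or unfitted model object", call. = FALSE)
  }
  json <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA, null = "null")
  writeLines(json, path)
  invisible(path)
}

#' Load a model saved by [save_model()]
#'
#' @param path Path to a model container file.
#' @return The deserialized model object.
#' @export
load_model <- function(path) {
  if (!file.exists(path)) stop(sprintf("model file not found: %s", path), call. = FALSE)
  payload <- tryCatch(
    jsonlite::fromJSON(readLines(path, warn = FALSE), simplifyVector = TRUE),
    error = function(e) stop(sprintf("cannot parse model file %s: %s",
                                     path, conditionMessage(e)), call. = FALSE)
  )
  if (!identical(payload$version, MODEL_FORMAT_VERSION)) {
    stop(sprintf("model format version mismatch: found %s, expected %s",
                 payload$version %||% "<none>", MODEL_FORMAT_VERSION),
         call. = FALSE)
  }
  if (identical(payload$type, "bilinear_model")) {
    out <- structure(
      list(
        Z = deserialize_matrix(payload$Z),
        W = stacked_matrix(deserialize_matrix(payload$W),
                           payload$W_block_count),
        X = deserialize_matrix(payload$X),
        dims = lapply(payload$dims, as.integer),
        motion_of_column = as.integer(payload$motion_of_column),
        objective_history = as.numeric(payload$objective_history),
        converged = payload$converged,
        iterations = payload$iterations,
        config = payload$config
      ),
      class = "bilinear_model"
    )
    return(out)
  }
  if (identical(payload$type, "emg_classifier")) {
    weights <- lapply(payload$weights, deserialize_matrix)
    return(structure(
      list(kind = payload$kind, classes = payload$classes,
           weights = weights, config = payload$config),
      class = "emg_classifier"
    ))
  }
  stop(sprintf("unknown model type in %s", path), call. = FALSE)
}
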