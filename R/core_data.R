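#' Construct a recording set
#'
#' A recording set holds one subject's trials as a dense
#' `trials x channels x samples` array of microvolt-scale amplitudes, together
#' with the sampling rate and channel names. All trials in one set share the
#' same channel count and sample count; benchmark-shaped sets are
#' 40 trials x 40 channels x 8064 samples at 128 Hz, of which the first 32
#' channels are scalp EEG.
#'
#' @param data numeric 3-d array, `trials x channels x samples`.
#' @param fs sampling rate in Hz (> 0).
#' @param channel_names optional character vector, one name per channel;
#'   defaults to `ch00, ch01, ...` (zero-based, matching provenance indices).
#' @param subject_id opaque subject identifier (coerced to character).
#' @return an object of class `recording_set` with fields `data`, `fs`,
#'   `channel_names`, `subject_id`.
#' @export
recording_set <- function(data, fs, channel_names = NULL, subject_id = "s00") {
  if (!is.array(data) || length(dim(data)) != 3L) {
    stop("`data` must be a 3-d array (trials x channels x samples)")
  }
  d <- dim(data)
  if (is.null(channel_names)) {
    channel_names <- default_channel_names(d[2L])
  }
  rec <- structure(
    list(
      data = data,
      fs = as.numeric(fs),
      channel_names = as.character(channel_names),
      subject_id = as.character(subject_id)[1L]
    ),
    class = "recording_set"
  )
  validate_recording_set(rec)
  rec
}

default_channel_names <- function(n) sprintf("ch%02d", seq_len(n) - 1L)

#' Validate a recording set
#'
#' Re-checks the structural invariants: positive sampling rate, positive
#' sample count, finite amplitudes, channel-name length. Called after every
#' reader and every preprocessing operation; a violation is always an error,
#' never a silent fix.
#'
#' @param rec a `recording_set`.
#' @return `rec`, invisibly.
#' @export
validate_recording_set <- function(rec) {
  stopifnot(inherits(rec, "recording_set"))
  d <- dim(rec$data)
  if (length(d) != 3L) stop("recording data must be trials x channels x samples")
  if (!is.numeric(rec$fs) || length(rec$fs) != 1L || !is.finite(rec$fs) || rec$fs <= 0) {
    stop("sampling rate `fs` must be a single positive number")
  }
  if (d[3L] < 1L) stop("recording must contain at least one sample per trial")
  if (length(rec$channel_names) != d[2L]) {
    stop(sprintf("channel_names has length %d but data has %d channels",
                 length(rec$channel_names), d[2L]))
  }
  if (anyNA(rec$data) || !all(is.finite(rec$data))) {
    stop("recording contains non-finite amplitude values")
  }
  invisible(rec)
}

#' @export
print.recording_set <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<recording_set> subject %s: %d trials x %d channels x %d samples @ %g Hz\n",
              x$subject_id, d[1L], d[2L], d[3L], x$fs))
  invisible(x)
}

n_trials <- function(rec) dim(rec$data)[1L]
n_channels <- function(rec) dim(rec$data)[2L]
n_samples <- function(rec) dim(rec$data)[3L]

#' Construct a self-assessment rating table
#'
#' Per-trial emotion self-reports on the continuous 1-9 scale, in the fixed
#' column order (valence, arousal, dominance, liking).
#'
#' @param ratings numeric matrix `trials x 4`, every entry in \[1, 9\].
#' @return an object of class `rating_table`.
#' @export
rating_table <- function(ratings) {
  ratings <- as.matrix(ratings)
  if (ncol(ratings) != 4L) {
    stop("rating table must have 4 columns (valence, arousal, dominance, liking)")
  }
  if (anyNA(ratings) || !all(is.finite(ratings))) stop("ratings contain non-finite values")
  if (any(ratings < 1 | ratings > 9)) stop("all ratings must lie on the 1-9 scale")
  colnames(ratings) <- c("valence", "arousal", "dominance", "liking")
  structure(list(ratings = ratings), class = "rating_table")
}

#' @export
print.rating_table <- function(x, ...) {
  cat(sprintf("<rating_table> %d trials x 4 dimensions (1-9 scale)\n", nrow(x$ratings)))
  invisible(x)
}

#' Construct a labelled trial set
#'
#' Variable-length multichannel trials with a binary class per trial, the
#' container used for film-clip style corpora where each trial is already
#' labelled positive (1) or negative (0).
#'
#' @param trials list of numeric `channels x samples` matrices; sample counts
#'   may differ across trials, channel counts may not.
#' @param labels integer vector in `{0, 1}`, one per trial.
#' @param subject_id opaque subject identifier.
#' @param fs sampling rate in Hz.
#' @return an object of class `labeled_trial_set`.
#' @export
labeled_trial_set <- function(trials, labels, subject_id = "s00", fs = 128) {
  if (!is.list(trials) || length(trials) == 0L) stop("`trials` must be a non-empty list")
  labels <- as.integer(labels)
  if (length(labels) != length(trials)) stop("one label per trial required")
  if (!all(labels %in% c(0L, 1L))) stop("labels must be 0 or 1")
  nch <- vapply(trials, nrow, integer(1))
  if (length(unique(nch)) != 1L) stop("all trials must share one channel count")
  for (tr in trials) {
    if (anyNA(tr) || !all(is.finite(tr))) stop("trial contains non-finite values")
  }
  structure(
    list(trials = trials, labels = labels,
         subject_id = as.character(subject_id)[1L], fs = as.numeric(fs)),
    class = "labeled_trial_set"
  )
}

#' @export
print.labeled_trial_set <- function(x, ...) {
  ns <- vapply(x$trials, ncol, integer(1))
  cat(sprintf("<labeled_trial_set> subject %s: %d trials (%d pos / %d neg), %d channels, %d-%d samples @ %g Hz\n",
              x$subject_id, length(x$trials), sum(x$labels == 1L), sum(x$labels == 0L),
              nrow(x$trials[[1L]]), min(ns), max(ns), x$fs))
  invisible(x)
}

# ---- per-subject file dialects ------------------------------------------

#' Read a per-subject benchmark-dialect file
#'
#' The preprocessed-release dialect is a serialized mapping with two entries:
#' `data`, a `trials x channels x samples` numeric array, and `labels`, a
#' `trials x 4` rating matrix. Files are written/read as RDS, R's native
#' serialization of such mappings. The canonical shape is 40 x 40 x 8064 at
#' 128 Hz; other shapes are accepted but flagged with a message as
#' nonstandard.
#'
#' @param path path to an RDS file holding `list(data = ..., labels = ...)`.
#' @param fs sampling rate to attach (the dialect itself does not store one);
#'   default 128 Hz.
#' @param subject_id subject identifier; defaults to the file stem.
#' @return `list(recording = recording_set, ratings = rating_table)`.
#' @export
read_deap_subject <- function(path, fs = 128, subject_id = NULL) {
  if (!file.exists(path)) stop(sprintf("subject file not found: %s", path))
  obj <- readRDS(path)
  if (!is.list(obj)) stop(sprintf("format error in %s: not a serialized mapping", path))
  missing <- setdiff(c("data", "labels"), names(obj))
  if (length(missing) > 0L) {
    stop(sprintf("format error in %s: missing entries: %s",
                 path, paste(missing, collapse = ", ")))
  }
  if (!is.numeric(obj$data)) stop(sprintf("format error in %s: entry 'data' is not numeric", path))
  if (!is.numeric(obj$labels)) stop(sprintf("format error in %s: entry 'labels' is not numeric", path))
  if (is.null(subject_id)) subject_id <- sub("\\.[^.]*$", "", basename(path))
  d <- dim(obj$data)
  if (!identical(as.integer(d), c(40L, 40L, 8064L))) {
    message(sprintf("nonstandard recording shape in %s: %s (expected 40 x 40 x 8064)",
                    path, paste(d, collapse = " x ")))
  }
  channel_names <- attr(obj$data, "channel_names")
  data <- obj$data
  attr(data, "channel_names") <- NULL
  list(
    recording = recording_set(data, fs = fs,
                              channel_names = channel_names,
                              subject_id = subject_id),
    ratings = rating_table(obj$labels)
  )
}

#' Write a per-subject benchmark-dialect file
#'
#' Inverse of [read_deap_subject()]: serializes `list(data, labels)` to RDS.
#'
#' @param rec a `recording_set`.
#' @param ratings a `rating_table` with one row per trial.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_deap_subject <- function(rec, ratings, path) {
  validate_recording_set(rec)
  stopifnot(inherits(ratings, "rating_table"))
  if (nrow(ratings$ratings) != n_trials(rec)) {
    stop("rating row count must equal trial count")
  }
  data <- rec$data
  attr(data, "channel_names") <- rec$channel_names
  saveRDS(list(data = data, labels = ratings$ratings), path)
  invisible(path)
}

#' Read a per-subject labelled-trial file
#'
#' Dialect for film-clip style corpora: a serialized mapping with `trials`
#' (list of `channels x samples` matrices), `labels` (0/1 per trial) and
#' optionally `fs`.
#'
#' @param path RDS file path.
#' @param subject_id subject identifier; defaults to the file stem.
#' @return a `labeled_trial_set`.
#' @export
read_seed_subject <- function(path, subject_id = NULL) {
  if (!file.exists(path)) stop(sprintf("subject file not found: %s", path))
  obj <- readRDS(path)
  missing <- setdiff(c("trials", "labels"), names(obj))
  if (length(missing) > 0L) {
    stop(sprintf("format error in %s: missing entries: %s",
                 path, paste(missing, collapse = ", ")))
  }
  if (is.null(subject_id)) subject_id <- sub("\\.[^.]*$", "", basename(path))
  fs <- if (!is.null(obj$fs)) obj$fs else 128
  labeled_trial_set(obj$trials, obj$labels, subject_id = subject_id, fs = fs)
}

#' Write a per-subject labelled-trial file
#'
#' @param lts a `labeled_trial_set`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_seed_subject <- function(lts, path) {
  stopifnot(inherits(lts, "labeled_trial_set"))
  saveRDS(list(trials = lts$trials, labels = lts$labels, fs = lts$fs), path)
  invisible(path)
}

# ---- feature tables ------------------------------------------------------

#' Write a feature table to CSV
#'
#' One header row, then one row per segment: provenance columns
#' (`subject`, `trial`, `segment`; trial/segment indices zero-based),
#' the feature columns, and a final `label` column when labels are supplied.
#'
#' @param fm a `feature_matrix` (see [extract_features()]).
#' @param path output CSV path.
#' @param labels optional label vector, one per row of `fm`.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(fm, path, labels = NULL) {
  stopifnot(inherits(fm, "feature_matrix"))
  df <- cbind(fm$provenance, as.data.frame(fm$values, optional = TRUE))
  if (!is.null(labels)) {
    if (length(labels) != nrow(fm$values)) {
      stop(sprintf("dimension error: %d labels for %d feature rows",
                   length(labels), nrow(fm$values)))
    }
    df$label <- as.integer(labels)
  }
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Read a feature table written by [write_feature_table()]
#'
#' @param path CSV path.
#' @return `list(features = feature_matrix, labels = integer vector or NULL)`.
#' @export
read_feature_table <- function(path) {
  if (!file.exists(path)) stop(sprintf("feature table not found: %s", path))
  df <- utils::read.csv(path, check.names = FALSE,
                        colClasses = c(subject = "character"))
  prov_cols <- c("subject", "trial", "segment")
  if (!all(prov_cols %in% names(df))) {
    stop("format error: feature table lacks provenance columns subject/trial/segment")
  }
  has_label <- "label" %in% names(df)
  feat_cols <- setdiff(names(df), c(prov_cols, "label"))
  values <- as.matrix(df[, feat_cols, drop = FALSE])
  labels <- if (has_label) as.integer(df$label) else NULL
  fm <- feature_matrix(values, df[, prov_cols, drop = FALSE])
  list(features = fm, labels = labels)
}

#' Construct a feature matrix
#'
#' Segments x (channels x features) numeric table with per-column names
#' (e.g. `DE_ch07`, `HFD_ch31`) and per-row provenance carried over from the
#' segment set.
#'
#' @param values numeric matrix with column names.
#' @param provenance data frame with columns `subject`, `trial`, `segment`
#'   (trial/segment zero-based), one row per matrix row.
#' @return an object of class `feature_matrix`.
#' @export
feature_matrix <- function(values, provenance) {
  values <- as.matrix(values)
  if (!all(is.finite(values))) stop("feature matrix contains non-finite values")
  if (is.null(colnames(values))) stop("feature matrix requires column names")
  provenance <- as.data.frame(provenance)
  if (nrow(provenance) != nrow(values)) stop("provenance row count mismatch")
  structure(list(values = values, provenance = provenance), class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %d segments x %d columns (%s%s)\n",
              nrow(x$values), ncol(x$values),
              paste(utils::head(colnames(x$values), 3L), collapse = ", "),
              if (ncol(x$values) > 3L) ", ..." else ""))
  invisible(x)
}
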