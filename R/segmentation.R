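#' Construct a segment set
#'
#' Flattened `segments x channels x window_samples` array with per-segment
#' provenance `(subject, trial, segment)`; trial and segment indices are
#' zero-based.
#'
#' @param data numeric 3-d array.
#' @param provenance data frame with columns `subject`, `trial`, `segment`.
#' @param fs sampling rate in Hz.
#' @param channel_names optional channel names.
#' @return an object of class `segment_set`.
#' @export
segment_set <- function(data, provenance, fs, channel_names = NULL) {
  if (length(dim(data)) != 3L) stop("segment data must be 3-d")
  provenance <- as.data.frame(provenance)
  stopifnot(all(c("subject", "trial", "segment") %in% names(provenance)))
  if (nrow(provenance) != dim(data)[1L]) stop("one provenance row per segment required")
  key <- paste(provenance$subject, provenance$trial, provenance$segment)
  if (anyDuplicated(key)) stop("provenance triples must be unique")
  if (is.null(channel_names)) channel_names <- default_channel_names(dim(data)[2L])
  structure(list(data = data, provenance = provenance, fs = as.numeric(fs),
                 channel_names = channel_names),
            class = "segment_set")
}

#' @export
print.segment_set <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<segment_set> %d segments x %d channels x %d samples @ %g Hz (%d trials)\n",
              d[1L], d[2L], d[3L], x$fs,
              nrow(unique(x$provenance[, c("subject", "trial")]))))
  invisible(x)
}

n_segments <- function(segs) dim(segs$data)[1L]

#' Segment trials into fixed-duration windows
#'
#' Splits every trial into consecutive non-overlapping windows of
#' `window_seconds`; trailing samples that do not fill a window are dropped
#' (never padded). With the benchmark geometry — 60-s trials at 128 Hz and
#' 3-s windows — each trial yields 20 segments of 384 samples, so
#' 32 subjects x 40 trials give 25,600 segments.
#'
#' @param rec a `recording_set`.
#' @param window_seconds window duration in seconds; `window_seconds * fs`
#'   must be a positive integer.
#' @return a `segment_set`.
#' @export
segment_trials <- function(rec, window_seconds = 3) {
  validate_recording_set(rec)
  win <- window_seconds * rec$fs
  if (abs(win - round(win)) > 1e-9 || win < 1) {
    stop("window_seconds * fs must be a positive integer")
  }
  win <- as.integer(round(win))
  per_trial <- n_samples(rec) %/% win
  if (per_trial < 1L) {
    stop(sprintf("no segments: window of %d samples exceeds %d-sample trials",
                 win, n_samples(rec)))
  }
  nt <- n_trials(rec)
  nch <- n_channels(rec)
  out <- array(0, dim = c(nt * per_trial, nch, win))
  row <- 1L
  prov <- vector("list", nt)
  for (tr in seq_len(nt)) {
    for (sg in seq_len(per_trial)) {
      idx <- ((sg - 1L) * win + 1L):(sg * win)
      out[row, , ] <- rec$data[tr, , idx]
      row <- row + 1L
    }
    prov[[tr]] <- data.frame(subject = rec$subject_id,
                             trial = tr - 1L,
                             segment = seq_len(per_trial) - 1L,
                             stringsAsFactors = FALSE)
  }
  segment_set(out, do.call(rbind, prov), fs = rec$fs,
              channel_names = rec$channel_names)
}

#' Segment variable-length trials into a fixed number of windows
#'
#' Splits every trial of a labelled trial set into `n_segments` equal-length
#' non-overlapping windows of `floor(samples / n_segments)` samples each;
#' the remainder is dropped. When trials differ in length the window length
#' is per-trial — downstream feature extraction is length-agnostic — and the
#' resulting per-trial segment blocks are returned as a list so unequal
#' window lengths never share one array.
#'
#' @param lts a `labeled_trial_set`.
#' @param n_segments windows per trial (>= 1).
#' @return `list(segments = list of segment_set (one per distinct window
#'   length), labels = integer vector aligned with the concatenated segment
#'   rows, provenance = combined provenance data frame)`.
#' @export
segment_trials_by_count <- function(lts, n_segments = 20) {
  stopifnot(inherits(lts, "labeled_trial_set"))
  if (n_segments < 1L) stop("n_segments must be positive")
  ns <- vapply(lts$trials, ncol, integer(1))
  if (any(ns < n_segments)) {
    stop(sprintf("trial with %d samples cannot yield %d segments", min(ns), n_segments))
  }
  win_len <- ns %/% n_segments
  groups <- split(seq_along(lts$trials), win_len)
  seg_sets <- vector("list", length(groups))
  labels <- integer(0)
  for (g in seq_along(groups)) {
    idx <- groups[[g]]
    win <- win_len[idx[1L]]
    nch <- nrow(lts$trials[[1L]])
    out <- array(0, dim = c(length(idx) * n_segments, nch, win))
    prov <- vector("list", length(idx))
    row <- 1L
    for (k in seq_along(idx)) {
      tr <- idx[k]
      x <- lts$trials[[tr]]
      for (sg in seq_len(n_segments)) {
        cols <- ((sg - 1L) * win + 1L):(sg * win)
        out[row, , ] <- x[, cols]
        row <- row + 1L
      }
      prov[[k]] <- data.frame(subject = lts$subject_id, trial = tr - 1L,
                              segment = seq_len(n_segments) - 1L,
                              stringsAsFactors = FALSE)
      labels <- c(labels, rep(lts$labels[tr], n_segments))
    }
    seg_sets[[g]] <- segment_set(out, do.call(rbind, prov), fs = lts$fs)
  }
  list(segments = seg_sets, labels = labels,
       provenance = do.call(rbind, lapply(seg_sets, `[[`, "provenance")))
}

#' Binarize self-assessment ratings
#'
#' Maps continuous 1-9 ratings of one dimension to binary classes at a
#' threshold: ratings at or below the threshold become 0 (low), ratings
#' above it become 1 (high). The conventional threshold is 4.5, with the tie
#' (exactly 4.5) assigned to class 0.
#'
#' @param ratings a `rating_table`.
#' @param dimension `"valence"` or `"arousal"`.
#' @param threshold rating threshold in \[1, 9\].
#' @return an integer trial-level label vector in `{0, 1}`.
#' @export
binarize_ratings <- function(ratings, dimension = c("valence", "arousal"),
                             threshold = 4.5) {
  stopifnot(inherits(ratings, "rating_table"))
  dimension <- match.arg(dimension)
  if (threshold < 1 || threshold > 9) stop("threshold must lie in [1, 9]")
  as.integer(ratings$ratings[, dimension] > threshold)
}

#' Broadcast trial-level labels to segments
#'
#' Every segment inherits the label of its parent trial, matched through the
#' provenance `trial` index (zero-based), never through row position.
#'
#' @param trial_labels integer vector, one label per trial; element `i`
#'   labels provenance trial index `i - 1`.
#' @param segs a `segment_set` (or anything with a `provenance` data frame).
#' @return an integer segment-level label vector.
#' @export
expand_to_segments <- function(trial_labels, segs) {
  prov <- if (is.data.frame(segs)) segs else segs$provenance
  tr <- prov$trial
  if (length(tr) == 0L) return(integer(0))
  if (any(tr < 0L) || any(tr + 1L > length(trial_labels))) {
    stop("provenance references a trial with no label")
  }
  as.integer(trial_labels[tr + 1L])
}
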