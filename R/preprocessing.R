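#' Filter specification
#'
#' Describes one conditioning filter: a Butterworth band-pass
#' (`low_hz`/`high_hz`, `order`) or a second-order notch
#' (`center_hz`, `q_factor`).
#'
#' @param kind `"bandpass"` or `"notch"`.
#' @param low_hz,high_hz band edges in Hz (band-pass only).
#' @param center_hz notch center frequency in Hz (notch only).
#' @param q_factor notch quality factor (center / -3 dB width).
#' @param order filter order (band-pass; >= 1).
#' @return an object of class `filter_spec`.
#' @export
filter_spec <- function(kind = c("bandpass", "notch"),
                        low_hz = 4, high_hz = 45,
                        center_hz = 50, q_factor = 30,
                        order = 4) {
  kind <- match.arg(kind)
  if (kind == "bandpass") {
    if (!(low_hz > 0 && low_hz < high_hz)) stop("need 0 < low_hz < high_hz")
    if (order < 1) stop("filter order must be >= 1")
  } else {
    if (center_hz <= 0) stop("notch center must be positive")
    if (q_factor <= 0) stop("notch Q must be positive")
  }
  structure(list(kind = kind, low_hz = low_hz, high_hz = high_hz,
                 center_hz = center_hz, q_factor = q_factor, order = order),
            class = "filter_spec")
}

# Reflection-padding length for zero-phase filtering: three times the
# coefficient count (the conventional choice; initial-condition matching
# keeps edge transients small without longer padding), capped below the
# series length.
filter_padlen <- function(b, a, n) {
  min(n - 1L, 3L * max(length(a), length(b)))
}

# Apply an ARMA filter trial-by-trial, channel-by-channel. Zero-phase
# (forward-backward) by default, which doubles the effective order and leaves
# no group delay; one-pass application available by flag.
filter_recording <- function(rec, filt, zero_phase = TRUE) {
  d <- dim(rec$data)
  b <- as.numeric(filt$b)
  a <- as.numeric(filt$a)
  warmup <- 3L * (max(length(b), length(a)) - 1L)
  if (d[3L] <= warmup) {
    stop(sprintf("trial too short: %d samples for a filter needing > %d", d[3L], warmup))
  }
  if (zero_phase) {
    rec$data <- filtfilt_array_cpp(b, a, rec$data, filter_padlen(b, a, d[3L]))
  } else {
    out <- rec$data
    for (tr in seq_len(d[1L])) {
      for (ch in seq_len(d[2L])) {
        out[tr, ch, ] <- as.numeric(signal::filter(filt, rec$data[tr, ch, ]))
      }
    }
    rec$data <- out
  }
  validate_recording_set(rec)
  rec
}

design_bandpass <- function(low_hz, high_hz, fs, order) {
  nyq <- fs / 2
  if (!(low_hz > 0 && high_hz > low_hz && high_hz < nyq)) {
    stop(sprintf("band edges (%g, %g) Hz invalid for fs = %g Hz", low_hz, high_hz, fs))
  }
  signal::butter(order, c(low_hz, high_hz) / nyq, type = "pass")
}

# Second-order IIR notch: zeros on the unit circle at +-w0, pole radius set
# from the -3 dB bandwidth w0/Q with bilinear (tan) prewarping so the design
# stays accurate close to Nyquist.
design_notch <- function(center_hz, q, fs) {
  nyq <- fs / 2
  if (center_hz >= nyq) stop(sprintf("notch center %g Hz must lie below Nyquist %g Hz", center_hz, nyq))
  w0 <- 2 * pi * center_hz / fs
  beta <- tan((w0 / q) / 2)
  gain <- 1 / (1 + beta)
  b <- gain * c(1, -2 * cos(w0), 1)
  a <- c(1, -2 * gain * cos(w0), 2 * gain - 1)
  signal::Arma(b = b, a = a)
}

#' Down-sample a recording by integer decimation
#'
#' Applies an anti-aliasing low-pass (8th-order Butterworth at 0.8 x the
#' target Nyquist, zero-phase) and keeps every `fs/target_fs`-th sample.
#' The benchmark corpus ships 63-s trials down-sampled 512 -> 128 Hz, giving
#' 8064 samples per trial.
#'
#' @param rec a `recording_set`.
#' @param target_fs target rate in Hz; must divide `rec$fs`.
#' @return the decimated `recording_set` with `fs` updated.
#' @export
downsample_recording <- function(rec, target_fs) {
  validate_recording_set(rec)
  if (target_fs > rec$fs) stop("target_fs must not exceed the current sampling rate")
  ratio <- rec$fs / target_fs
  if (abs(ratio - round(ratio)) > 1e-9) {
    stop(sprintf("fs %g is not an integer multiple of target %g", rec$fs, target_fs))
  }
  ratio <- as.integer(round(ratio))
  if (ratio == 1L) return(rec)
  aa <- signal::butter(8, 0.8 * (target_fs / 2) / (rec$fs / 2), type = "low")
  rec <- filter_recording(rec, aa, zero_phase = TRUE)
  keep <- seq(1L, n_samples(rec), by = ratio)
  rec$data <- rec$data[, , keep, drop = FALSE]
  rec$fs <- as.numeric(target_fs)
  validate_recording_set(rec)
  rec
}

#' Band-pass filter a recording
#'
#' 4th-order Butterworth band-pass, 4-45 Hz by default, applied independently
#' per trial and channel. Zero-phase (forward-backward) application is the
#' default so features see no group delay; set `zero_phase = FALSE` for a
#' single causal pass. The 0.5-45 Hz variant is available by changing
#' `low_hz`.
#'
#' @param rec a `recording_set`.
#' @param low_hz,high_hz pass-band edges in Hz.
#' @param order Butterworth order (per pass).
#' @param zero_phase forward-backward application (default `TRUE`).
#' @return the filtered `recording_set`; shape unchanged.
#' @export
apply_bandpass <- function(rec, low_hz = 4, high_hz = 45, order = 4,
                           zero_phase = TRUE) {
  validate_recording_set(rec)
  filt <- design_bandpass(low_hz, high_hz, rec$fs, order)
  filter_recording(rec, filt, zero_phase = zero_phase)
}

#' Notch-filter a recording
#'
#' Narrow-band rejection of powerline interference (50 Hz by default) with a
#' second-order constrained notch; `q` sets the rejection bandwidth
#' (-3 dB width = center / q, so Q = 30 at 50 Hz rejects about 1.7 Hz).
#'
#' @param rec a `recording_set`.
#' @param center_hz notch center in Hz.
#' @param q quality factor.
#' @param zero_phase forward-backward application (default `TRUE`).
#' @return the filtered `recording_set`; shape unchanged.
#' @export
apply_notch <- function(rec, center_hz = 50, q = 30, zero_phase = TRUE) {
  validate_recording_set(rec)
  filt <- design_notch(center_hz, q, rec$fs)
  filter_recording(rec, filt, zero_phase = zero_phase)
}

#' Trim pre-trial baseline samples
#'
#' Drops the first `pre_seconds` of every trial. On the benchmark corpus,
#' removing the 3-s pre-trial baseline from 8064-sample trials at 128 Hz
#' leaves 7680 samples (60 s) per trial.
#'
#' @param rec a `recording_set`.
#' @param pre_seconds seconds to drop; `pre_seconds * fs` must be an integer
#'   strictly smaller than the per-trial sample count.
#' @return the trimmed `recording_set`.
#' @export
trim_pretrial <- function(rec, pre_seconds = 3) {
  validate_recording_set(rec)
  n_drop <- pre_seconds * rec$fs
  if (abs(n_drop - round(n_drop)) > 1e-9) {
    stop("pre_seconds * fs must be an integer number of samples")
  }
  n_drop <- as.integer(round(n_drop))
  if (n_drop < 0L) stop("pre_seconds must be non-negative")
  if (n_drop >= n_samples(rec)) {
    stop(sprintf("trimming %d samples would leave nothing of %d-sample trials",
                 n_drop, n_samples(rec)))
  }
  if (n_drop == 0L) return(rec)
  rec$data <- rec$data[, , (n_drop + 1L):n_samples(rec), drop = FALSE]
  validate_recording_set(rec)
  rec
}

#' Keep the leading EEG channels
#'
#' Benchmark recording sets carry the 32 scalp-EEG channels first, followed
#' by peripheral/status channels; feature extraction uses the EEG channels
#' exclusively. Retains the first `n_first` channels in order.
#'
#' @param rec a `recording_set`.
#' @param n_first number of leading channels to keep (1..channels).
#' @return the reduced `recording_set` with channel names subset accordingly.
#' @export
select_eeg_channels <- function(rec, n_first = 32) {
  validate_recording_set(rec)
  if (n_first < 1L) stop("n_first must be at least 1")
  if (n_first > n_channels(rec)) {
    stop(sprintf("cannot select %d of %d channels", n_first, n_channels(rec)))
  }
  if (n_first == n_channels(rec)) return(rec)
  rec$data <- rec$data[, seq_len(n_first), , drop = FALSE]
  rec$channel_names <- rec$channel_names[seq_len(n_first)]
  validate_recording_set(rec)
  rec
}

#' Run the full conditioning chain on a recording
#'
#' Convenience wrapper: optional down-sampling, band-pass, notch, pre-trial
#' trim, EEG-channel selection — in that order (filters before trimming; both
#' stages are linear and time-invariant so the order only affects trial
#' edges).
#'
#' @param rec a `recording_set`.
#' @param target_fs target rate, or `NULL` to skip down-sampling.
#' @param band_low_hz,band_high_hz,filter_order band-pass parameters; set
#'   `band_low_hz = NULL` to skip.
#' @param notch_hz,notch_q notch parameters; `notch_hz = NULL` to skip.
#' @param pretrial_seconds baseline seconds to trim (0 to skip).
#' @param n_eeg_channels leading channels to keep, or `NULL` to keep all.
#' @return the conditioned `recording_set`.
#' @export
preprocess_recording <- function(rec, target_fs = NULL,
                                 band_low_hz = 4, band_high_hz = 45,
                                 filter_order = 4,
                                 notch_hz = 50, notch_q = 30,
                                 pretrial_seconds = 3,
                                 n_eeg_channels = 32) {
  # every stage acts per channel, so channel selection commutes with the
  # rest of the chain; doing it first avoids filtering channels that are
  # dropped anyway
  if (!is.null(n_eeg_channels) && n_eeg_channels < n_channels(rec)) {
    rec <- select_eeg_channels(rec, n_eeg_channels)
  }
  if (!is.null(target_fs) && target_fs != rec$fs) {
    rec <- downsample_recording(rec, target_fs)
  }
  if (!is.null(band_low_hz)) {
    rec <- apply_bandpass(rec, band_low_hz, band_high_hz, filter_order)
  }
  if (!is.null(notch_hz) && notch_hz < rec$fs / 2) {
    rec <- apply_notch(rec, notch_hz, notch_q)
  }
  if (pretrial_seconds > 0) rec <- trim_pretrial(rec, pretrial_seconds)
  rec
}
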