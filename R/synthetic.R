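#' Synthetic dataset specification
#'
#' Parameters of the class-conditional signal model used to emulate
#' benchmark-shaped corpora. Each trial carries a latent binary class; its
#' EEG channels are drawn from that class's AR(1)-plus-sinusoid model
#' `x_t = phi * x_{t-1} + eps_t + A sin(2 pi f t + phase)`, where the
#' innovation scale `sigma` controls signal variance (hence differential
#' entropy) and the AR coefficient `phi` controls smoothness (hence fractal
#' dimension) — one independent knob per feature. Self-report ratings are
#' drawn on the correct side of the 4.5 threshold with probability
#' `label_fidelity`.
#'
#' Defaults emulate the two benchmark geometries. `"deap"`: 32 subjects x
#' 40 trials x 40 channels x 63 s at 128 Hz (8064 samples, 3-s pre-trial
#' baseline included), first 32 channels class-driven, peripheral channels
#' 33-40 pure unit noise; class innovation scales 1 vs 3 (ratio 3) and AR
#' coefficients 0.8 vs 0.4. `"seed"`: 10 subjects x 30 balanced trials
#' (15/15) x 32 channels x 4-min trials at 128 Hz, with subject-specific
#' offset/gain modelling inter-subject variability.
#'
#' @param dataset `"deap"` or `"seed"` geometry.
#' @param n_subjects,n_trials,n_channels,fs,trial_seconds shape overrides.
#' @param class0,class1 lists with `phi`, `sigma`, `sine_amp`, `sine_hz`.
#' @param rating_means length-2 class rating means on the 1-9 scale
#'   (low, high); must straddle 4.5.
#' @param rating_sd rating dispersion.
#' @param label_fidelity probability that a trial's rating lands on its
#'   latent class's side of the threshold (default 1).
#' @param subject_offset_sd,subject_gain_sd inter-subject amplitude
#'   variability (labelled-trial geometry only).
#' @param seed base RNG seed; subject `i` uses stream `seed + i`.
#' @return an object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(dataset = c("deap", "seed"),
                           n_subjects = NULL, n_trials = NULL,
                           n_channels = NULL, fs = 128,
                           trial_seconds = NULL,
                           class0 = list(phi = 0.8, sigma = 1, sine_amp = 1, sine_hz = 10),
                           class1 = list(phi = 0.4, sigma = 3, sine_amp = 1, sine_hz = 10),
                           rating_means = c(3, 6.5), rating_sd = 0.8,
                           label_fidelity = 1,
                           subject_offset_sd = 2, subject_gain_sd = 0.1,
                           seed = 42L) {
  dataset <- match.arg(dataset)
  if (is.null(n_subjects)) n_subjects <- if (dataset == "deap") 32L else 10L
  if (is.null(n_trials)) n_trials <- if (dataset == "deap") 40L else 30L
  if (is.null(n_channels)) n_channels <- if (dataset == "deap") 40L else 32L
  if (is.null(trial_seconds)) trial_seconds <- if (dataset == "deap") 63 else 240
  for (cls in list(class0, class1)) {
    if (abs(cls$phi) >= 1) stop("AR coefficient must satisfy |phi| < 1")
    if (cls$sigma <= 0) stop("innovation scale sigma must be positive")
  }
  if (!(rating_means[1L] <= 4.5 && rating_means[2L] > 4.5)) {
    stop("spec error: class rating means must straddle the 4.5 threshold (low <= 4.5 < high)")
  }
  if (label_fidelity < 0 || label_fidelity > 1) stop("label_fidelity must lie in [0, 1]")
  if (dataset == "seed" && n_trials %% 2L != 0L) {
    stop("balanced labelled-trial sets need an even trial count")
  }
  structure(list(dataset = dataset, n_subjects = as.integer(n_subjects),
                 n_trials = as.integer(n_trials), n_channels = as.integer(n_channels),
                 fs = fs, trial_seconds = trial_seconds,
                 class0 = class0, class1 = class1,
                 rating_means = rating_means, rating_sd = rating_sd,
                 label_fidelity = label_fidelity,
                 subject_offset_sd = subject_offset_sd,
                 subject_gain_sd = subject_gain_sd,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Stationary AR(1) signal
#'
#' `x_t = phi * x_{t-1} + eps_t`, `eps ~ N(0, sigma^2)`, initialized from the
#' stationary distribution `N(0, sigma^2 / (1 - phi^2))`.
#'
#' @param n number of samples.
#' @param phi AR coefficient, `|phi| < 1`.
#' @param sigma innovation standard deviation (> 0).
#' @param seed optional seed; when given the draw is reproducible.
#' @return numeric vector of length `n`.
#' @export
ar1_signal <- function(n, phi, sigma, seed = NULL) {
  if (abs(phi) >= 1) stop("AR coefficient must satisfy |phi| < 1")
  if (sigma <= 0) stop("sigma must be positive")
  if (!is.null(seed)) set.seed(seed)
  x0 <- stats::rnorm(1L, 0, sigma / sqrt(1 - phi^2))
  eps <- stats::rnorm(n, 0, sigma)
  as.numeric(stats::filter(eps, phi, method = "recursive", init = x0))
}

# One class-conditional channel: AR(1) bed plus a sinusoid with random phase.
class_channel <- function(n, fs, cls) {
  t <- (seq_len(n) - 1L) / fs
  phase <- stats::runif(1L, 0, 2 * pi)
  ar1_signal(n, cls$phi, cls$sigma) + cls$sine_amp * sin(2 * pi * cls$sine_hz * t + phase)
}

# Rating on the requested side of 4.5: truncated-normal by resampling, with
# a hard clip as the fallback guard.
draw_rating <- function(mean, sd, side) {
  lo <- if (side == "low") 1 else 4.6
  hi <- if (side == "low") 4.5 else 9
  for (i in 1:50) {
    r <- stats::rnorm(1L, mean, sd)
    if (r >= lo && r <= hi) return(r)
  }
  min(max(stats::rnorm(1L, mean, sd), lo), hi)
}

#' Simulate one benchmark-geometry subject
#'
#' Draws the subject's latent trial classes, synthesizes the first 32
#' channels from the class-conditional signal model (remaining channels are
#' unrelated unit noise, mimicking peripheral channels a correct pipeline
#' drops) and produces ratings whose binarization at 4.5 recovers the latent
#' class with probability `label_fidelity`. Deterministic given
#' `spec$seed + subject_index`.
#'
#' @param spec a `synthetic_spec` with `dataset = "deap"`.
#' @param subject_index 1-based subject number.
#' @return `list(recording, ratings, classes)` where `classes` is the latent
#'   trial class vector.
#' @export
simulate_deap_subject <- function(spec, subject_index) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed + subject_index)
  ns <- as.integer(round(spec$trial_seconds * spec$fs))
  n_eeg <- min(32L, spec$n_channels)
  classes <- stats::rbinom(spec$n_trials, 1L, 0.5)
  data <- array(0, dim = c(spec$n_trials, spec$n_channels, ns))
  ratings <- matrix(0, nrow = spec$n_trials, ncol = 4L)
  for (tr in seq_len(spec$n_trials)) {
    cls <- if (classes[tr] == 1L) spec$class1 else spec$class0
    for (ch in seq_len(n_eeg)) data[tr, ch, ] <- class_channel(ns, spec$fs, cls)
    if (spec$n_channels > n_eeg) {
      for (ch in (n_eeg + 1L):spec$n_channels) data[tr, ch, ] <- stats::rnorm(ns)
    }
    faithful <- stats::runif(1L) < spec$label_fidelity
    side_cls <- if (faithful) classes[tr] else 1L - classes[tr]
    side <- if (side_cls == 1L) "high" else "low"
    m <- spec$rating_means[side_cls + 1L]
    ratings[tr, 1L] <- draw_rating(m, spec$rating_sd, side)  # valence
    ratings[tr, 2L] <- draw_rating(m, spec$rating_sd, side)  # arousal
    ratings[tr, 3L] <- stats::runif(1L, 1, 9)                # dominance
    ratings[tr, 4L] <- stats::runif(1L, 1, 9)                # liking
  }
  list(
    recording = recording_set(data, fs = spec$fs,
                              subject_id = sprintf("s%02d", subject_index)),
    ratings = rating_table(ratings),
    classes = classes
  )
}

#' Simulate one labelled-trial-geometry subject
#'
#' Balanced positive/negative trials from the class-conditional signal
#' model, with a subject-specific additive offset and multiplicative gain
#' emulating inter-subject variability. Deterministic given
#' `spec$seed + subject_index`.
#'
#' @param spec a `synthetic_spec` with `dataset = "seed"`.
#' @param subject_index 1-based subject number.
#' @return a `labeled_trial_set`.
#' @export
simulate_seed_subject <- function(spec, subject_index) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed + subject_index)
  ns <- as.integer(round(spec$trial_seconds * spec$fs))
  labels <- sample(rep(c(0L, 1L), each = spec$n_trials %/% 2L))
  offset <- stats::rnorm(1L, 0, spec$subject_offset_sd)
  gain <- exp(stats::rnorm(1L, 0, spec$subject_gain_sd))
  trials <- vector("list", spec$n_trials)
  for (tr in seq_len(spec$n_trials)) {
    cls <- if (labels[tr] == 1L) spec$class1 else spec$class0
    m <- matrix(0, nrow = spec$n_channels, ncol = ns)
    for (ch in seq_len(spec$n_channels)) {
      m[ch, ] <- gain * class_channel(ns, spec$fs, cls) + offset
    }
    trials[[tr]] <- m
  }
  labeled_trial_set(trials, labels, subject_id = sprintf("s%02d", subject_index),
                    fs = spec$fs)
}

#' Generate a benchmark-geometry dataset on disk
#'
#' Writes one per-subject file in the corresponding dialect plus a
#' `manifest.json` recording the spec, seed and MD5 hash of every file;
#' regenerating with the same spec and seed reproduces the hashes exactly.
#'
#' @param spec a `synthetic_spec`.
#' @param dir output directory (created if missing).
#' @return the manifest, invisibly.
#' @export
generate_synthetic_dataset <- function(spec, dir) {
  stopifnot(inherits(spec, "synthetic_spec"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(spec$n_subjects)
  for (i in seq_len(spec$n_subjects)) {
    path <- file.path(dir, sprintf("s%02d.rds", i))
    if (spec$dataset == "deap") {
      sub <- simulate_deap_subject(spec, i)
      write_deap_subject(sub$recording, sub$ratings, path)
    } else {
      write_seed_subject(simulate_seed_subject(spec, i), path)
    }
    files[i] <- path
  }
  manifest <- list(
    dataset = spec$dataset, seed = spec$seed,
    n_subjects = spec$n_subjects, n_trials = spec$n_trials,
    n_channels = spec$n_channels, fs = spec$fs,
    trial_seconds = spec$trial_seconds,
    files = lapply(files, function(f) {
      list(file = basename(f), md5 = unname(tools::md5sum(f)))
    })
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

#' @rdname generate_synthetic_dataset
#' @export
generate_deap_like <- function(spec, dir) {
  if (spec$dataset != "deap") stop("spec has dataset != 'deap'")
  generate_synthetic_dataset(spec, dir)
}

#' @rdname generate_synthetic_dataset
#' @export
generate_seed_like <- function(spec, dir) {
  if (spec$dataset != "seed") stop("spec has dataset != 'seed'")
  generate_synthetic_dataset(spec, dir)
}
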