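# Independent reference implementations used as oracles. These deliberately
# use the naive direct formulas, never the package's own code paths.

# Naive triple-loop Higuchi estimator: curve lengths by explicit subsampled
# series, the 1/j curvilinear-time correction at the averaging stage, slope
# by closed-form least squares.
hfd_reference <- function(x, kmax) {
  N <- length(x)
  L <- numeric(kmax)
  for (j in seq_len(kmax)) {
    acc <- 0
    for (i in seq_len(j)) {
      M <- (N - i) %/% j
      s <- 0
      for (m in seq_len(M)) {
        s <- s + abs(x[i + m * j] - x[i + (m - 1) * j])
      }
      acc <- acc + s * (N - 1) / (M * j)
    }
    L[j] <- acc / (j * j)
  }
  lx <- log(1 / seq_len(kmax))
  ly <- log(L)
  sum((lx - mean(lx)) * (ly - mean(ly))) / sum((lx - mean(lx))^2)
}

hfd_curve_length_reference <- function(x, i, j) {
  N <- length(x)
  sub <- x[seq(i, N, by = j)]
  sum(abs(diff(sub))) * (N - 1) / ((length(sub) - 1) * j)
}

# Direct evaluation of the four ratio metrics for one positive label.
metrics_reference <- function(y_true, y_pred, positive) {
  tp <- sum(y_true == positive & y_pred == positive)
  fp <- sum(y_true != positive & y_pred == positive)
  fn <- sum(y_true == positive & y_pred != positive)
  tn <- sum(y_true != positive & y_pred != positive)
  p <- if (tp + fp == 0) NA_real_ else tp / (tp + fp)
  r <- if (tp + fn == 0) NA_real_ else tp / (tp + fn)
  f1 <- if (is.na(p) || is.na(r) || p + r == 0) NA_real_ else 2 * p * r / (p + r)
  list(accuracy = (tp + tn) / length(y_true), precision = p, recall = r, f1 = f1)
}

# Rank-sum AUC: Mann-Whitney U with midranks for ties, divided by n0 * n1.
auc_rank_reference <- function(y_true, scores) {
  r <- rank(scores)
  n1 <- sum(y_true == 1)
  n0 <- sum(y_true == 0)
  (sum(r[y_true == 1]) - n1 * (n1 + 1) / 2) / (n0 * n1)
}

# Two well-separated (or overlapping) Gaussian blobs in d dimensions.
make_blobs <- function(n_per_class, d = 2, sep = 6, seed = 1) {
  set.seed(seed)
  x <- rbind(matrix(stats::rnorm(n_per_class * d), ncol = d),
             matrix(stats::rnorm(n_per_class * d, mean = sep), ncol = d))
  colnames(x) <- sprintf("f%02d", seq_len(d))
  list(x = x, y = rep(c(0L, 1L), each = n_per_class))
}

# Tiny recording set with deterministic content.
toy_recording <- function(trials = 2, channels = 3, samples = 640, fs = 128,
                          seed = 1, subject_id = "toy") {
  set.seed(seed)
  recording_set(array(stats::rnorm(trials * channels * samples),
                      dim = c(trials, channels, samples)),
                fs = fs, subject_id = subject_id)
}

sine_recording <- function(freq, fs, seconds, trials = 1, channels = 1, amp = 1) {
  t <- (seq_len(fs * seconds) - 1) / fs
  x <- amp * sin(2 * pi * freq * t)
  recording_set(array(rep(x, each = trials * channels),
                      dim = c(trials, channels, length(t))), fs = fs)
}

rms <- function(x) sqrt(mean(x^2))

# Magnitude response of a digital filter at frequency f (Hz) for rate fs.
filter_gain <- function(b, a, f, fs) {
  z <- exp(-1i * 2 * pi * f / fs)
  Mod(sum(b * z^(seq_along(b) - 1)) / sum(a * z^(seq_along(a) - 1)))
}
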