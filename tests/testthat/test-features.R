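test_that("histogram density integrates to one and tracks the flat density", {
  set.seed(41)
  x <- runif(10000)
  h <- histogram_density(x)
  expect_lt(abs(sum(h$density * h$widths) - 1), 1e-9)
  expect_true(all(h$widths > 0))
  expect_true(all(abs(h$density - 1) < 0.15))  # true density is 1 on [0,1]
  expect_error(histogram_density(c(0, 0, 0, 0)), "degenerate")
  expect_error(histogram_density(3), "at least 2")
})

test_that("histogram entropy matches the Gaussian closed form", {
  for (s2 in c(0.25, 1, 4)) {
    set.seed(42)
    x <- rnorm(50000, sd = sqrt(s2))
    expect_lt(abs(differential_entropy(x) - gaussian_differential_entropy(s2)),
              0.05)
  }
  set.seed(43)
  expect_lt(abs(differential_entropy(runif(50000)) - 0), 0.05)
})

test_that("entropy obeys the scaling and location laws", {
  set.seed(44)
  x <- rnorm(50000)
  expect_lt(abs(differential_entropy(2 * x) - differential_entropy(x) - log(2)),
            0.05)
  expect_lt(abs(differential_entropy(x + 100) - differential_entropy(x)), 0.02)
})

test_that("entropy estimate converges toward the closed form with n", {
  target <- gaussian_differential_entropy(1)
  med_err <- vapply(c(1e3, 1e4, 1e5), function(n) {
    errs <- vapply(1:20, function(s) {
      set.seed(1000 + s)
      abs(differential_entropy(rnorm(n)) - target)
    }, numeric(1))
    stats::median(errs)
  }, numeric(1))
  expect_true(all(diff(med_err) <= 0))
})

test_that("Gaussian closed form evaluates exactly", {
  expect_equal(gaussian_differential_entropy(1), 0.5 * log(2 * pi * exp(1)))
  expect_equal(gaussian_differential_entropy(1 / (2 * pi * exp(1))), 0)
  expect_equal(gaussian_differential_entropy(4) - gaussian_differential_entropy(1),
               log(2), tolerance = 1e-12)
  expect_equal(gaussian_differential_entropy(1, mu = 50),
               gaussian_differential_entropy(1, mu = -2))
  expect_error(gaussian_differential_entropy(0), "positive")
})

test_that("curve lengths match explicit enumeration", {
  expect_equal(higuchi_curve_length(rep(5, 50), 1, 3), 0)
  # ramp 0..9: nine unit steps, M = 9, normalization 9/(9*1)
  expect_equal(higuchi_curve_length(0:9, 1, 1), 9)
  # i = 1, j = 3 picks X(1), X(4), X(7), X(10) = 0, 3, 6, 9:
  # sum |diff| = 9, M = 3, so 9 * 9 / (3 * 3) = 9
  expect_equal(higuchi_curve_length(0:9, 1, 3), 9)
  expect_error(higuchi_curve_length(0:9, 4, 3), "must not exceed")
  expect_error(higuchi_curve_length(c(1, 2), 1, 5), "degenerate")
})

test_that("curve lengths equal the naive reference on random series", {
  set.seed(45)
  for (r in 1:50) {
    x <- rnorm(100)
    i <- sample(1:5, 1)
    j <- sample(i:10, 1)
    expect_equal(higuchi_curve_length(x, i, j),
                 hfd_curve_length_reference(x, i, j), tolerance = 1e-10)
  }
})

test_that("fractal dimension hits the canonical anchors", {
  expect_lt(abs(higuchi_fd(seq_len(1000), kmax = 10) - 1), 0.05)
  set.seed(46)
  mean_fd <- mean(vapply(1:100, function(i) higuchi_fd(rnorm(384), kmax = 10),
                         numeric(1)))
  expect_lt(abs(mean_fd - 2), 0.15)
  t <- (0:999) / 1000
  expect_lt(abs(higuchi_fd(sin(2 * pi * 3 * t), kmax = 10) - 1), 0.1)
})

test_that("fractal dimension equals the naive triple-loop reference", {
  set.seed(47)
  for (r in 1:50) {
    x <- rnorm(100)
    expect_equal(higuchi_fd(x, kmax = 8), hfd_reference(x, kmax = 8),
                 tolerance = 1e-10)
  }
})

test_that("fractal dimension is amplitude-scale invariant and orders complexity", {
  set.seed(48)
  x <- rnorm(2000)
  expect_lt(abs(higuchi_fd(17.3 * x, 10) - higuchi_fd(x, 10)), 1e-9)

  fds <- vapply(1:50, function(s) {
    set.seed(100 + s)
    wn <- higuchi_fd(rnorm(384), 10)
    ar <- higuchi_fd(ar1_signal(384, 0.9, 1), 10)
    ramp <- higuchi_fd(seq_len(384) + rnorm(384, sd = 1e-6), 10)
    c(wn, ar, ramp)
  }, numeric(3))
  m <- rowMeans(fds)
  expect_gt(m[1], m[2])  # white noise > AR(1) phi = 0.9
  expect_gt(m[2], m[3])  # AR(1) > smooth ramp
  expect_error(higuchi_fd(rep(1, 100), 10), "degenerate")
  expect_error(higuchi_fd(rnorm(15), 10), "longer than")
})

test_that("feature extraction produces the advertised layout", {
  rec <- toy_recording(trials = 2, channels = 2, samples = 5 * 384, fs = 128)
  segs <- segment_trials(rec, 3)
  fm <- extract_features(segs, which = c("de", "hfd"))
  expect_equal(dim(fm$values), c(10, 4))
  expect_identical(colnames(fm$values),
                   c("DE_ch00", "DE_ch01", "HFD_ch00", "HFD_ch01"))
  expect_true(all(is.finite(fm$values)))
  expect_identical(fm$provenance, segs$provenance)
  expect_error(extract_features(segs, which = character(0)), "feature")
  expect_error(extract_features(segs, which = "psd"), "unknown")
})

test_that("the fast entropy path agrees with the reference estimator", {
  rec <- toy_recording(trials = 1, channels = 1, samples = 20 * 384, fs = 128,
                       seed = 49)
  segs <- segment_trials(rec, 3)
  fm <- extract_features(segs, which = "de")
  ref <- vapply(seq_len(20), function(s) {
    differential_entropy(segs$data[s, 1, ], rule = "auto")
  }, numeric(1))
  expect_equal(unname(fm$values[, 1]), ref, tolerance = 1e-12)
})

test_that("extraction failures name the offending segment", {
  rec <- toy_recording(trials = 1, channels = 2, samples = 2 * 384, fs = 128)
  rec$data[1, 2, 385:768] <- 7  # constant second window on channel 2
  segs <- segment_trials(rec, 3)
  expect_error(extract_features(segs, which = "de"),
               "trial 0, segment 1, channel 1")
})

test_that("feature structure report matches brute-force Pearson", {
  set.seed(50)
  vals <- matrix(rnorm(15), 5, 3,
                 dimnames = list(NULL, c("DE_ch00", "DE_ch01", "DE_ch02")))
  fm <- feature_matrix(vals, data.frame(subject = "s", trial = 0L, segment = 0:4))
  rep <- feature_structure_report(fm, "DE")
  expect_equal(unname(diag(rep$correlation)), rep(1, 3))
  expect_lt(max(abs(rep$correlation - t(rep$correlation))), 1e-12)
  for (i in 1:3) for (j in 1:3) {
    a <- vals[, i]; b <- vals[, j]
    pearson <- sum((a - mean(a)) * (b - mean(b))) /
      sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
    expect_equal(unname(rep$correlation[i, j]), pearson, tolerance = 1e-12)
  }
  expect_equal(nrow(rep$summary), 3)
})

test_that("zero-variance feature columns are flagged undefined", {
  vals <- cbind(DE_ch00 = rnorm(5), DE_ch01 = rep(2, 5))
  fm <- feature_matrix(vals, data.frame(subject = "s", trial = 0L, segment = 0:4))
  rep <- feature_structure_report(fm, "DE")
  expect_identical(rep$undefined_columns, "DE_ch01")
  expect_true(is.na(rep$correlation["DE_ch00", "DE_ch01"]))
})
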