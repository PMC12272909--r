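test_that("confusion counts match the hand-countable example", {
  rep <- confusion_metrics(c(1, 1, 1, 0, 0, 0), c(1, 1, 1, 0, 0, 1))
  expect_equal(rep$tp, 3); expect_equal(rep$fp, 1)
  expect_equal(rep$tn, 2); expect_equal(rep$fn, 0)
  expect_equal(rep$accuracy, 5 / 6)
  expect_equal(rep$per_class$support, c(3, 3))
  expect_equal(rep$confusion["1", "1"], 3)
  expect_equal(rep$tp + rep$tn + rep$fp + rep$fn, rep$n)
})

test_that("perfect prediction yields unit metrics for both classes", {
  y <- c(0, 1, 0, 1, 1)
  rep <- confusion_metrics(y, y)
  expect_equal(rep$accuracy, 1)
  expect_equal(rep$per_class$precision, c(1, 1))
  expect_equal(rep$per_class$recall, c(1, 1))
  expect_equal(rep$per_class$f1, c(1, 1))
})

test_that("metrics equal brute-force formula evaluation on random labels", {
  set.seed(71)
  for (r in 1:20) {
    y <- rbinom(30, 1, 0.5); p <- rbinom(30, 1, 0.5)
    rep <- confusion_metrics(y, p)
    for (cls in c(0L, 1L)) {
      ref <- metrics_reference(y, p, cls)
      row <- rep$per_class[rep$per_class$label == cls, ]
      expect_equal(rep$accuracy, ref$accuracy)
      expect_equal(row$precision, ref$precision)
      expect_equal(row$recall, ref$recall)
      expect_equal(row$f1, ref$f1)
    }
    # micro-averaged recall over both classes is exactly the accuracy
    pc <- rep$per_class
    micro <- sum(pc$recall * pc$support, na.rm = TRUE) /
      sum(pc$support[!is.na(pc$recall)])
    expect_equal(micro, rep$accuracy)
    # F1 is the harmonic mean wherever defined
    ok <- !is.na(pc$f1)
    expect_equal(pc$f1[ok],
                 2 * pc$precision[ok] * pc$recall[ok] /
                   (pc$precision[ok] + pc$recall[ok]))
  }
})

test_that("undefined ratios surface as NA, never as silent zeros", {
  rep <- confusion_metrics(c(1, 1, 1), c(1, 1, 1))  # nothing predicted as 0
  row0 <- rep$per_class[1, ]
  expect_true(is.na(row0$precision))  # 0/0
  expect_true(is.na(row0$recall))     # no true 0s
  expect_equal(rep$per_class$recall[2], 1)
})

test_that("ROC endpoints, monotonicity and extreme rankings behave", {
  y <- c(0, 0, 1, 1)
  perfect <- roc_auc(y, c(0.1, 0.2, 0.8, 0.9))
  expect_equal(perfect$auc, 1.0)
  reversed <- roc_auc(y, c(0.9, 0.8, 0.2, 0.1))
  expect_equal(reversed$auc, 0.0)
  pts <- perfect$roc_points
  expect_equal(c(pts$fpr[1], pts$tpr[1]), c(0, 0))
  expect_equal(c(pts$fpr[nrow(pts)], pts$tpr[nrow(pts)]), c(1, 1))
  expect_true(all(diff(pts$fpr) >= 0) && all(diff(pts$tpr) >= 0))
  expect_error(roc_auc(c(1, 1), c(0.2, 0.3)), "single class")
})

test_that("random scores give chance-level AUC on average", {
  set.seed(72)
  aucs <- vapply(1:50, function(i) {
    y <- rep(c(0L, 1L), each = 100)
    roc_auc(y, runif(200))$auc
  }, numeric(1))
  expect_lt(abs(mean(aucs) - 0.5), 0.05)
})

test_that("sweep AUC equals the rank-sum statistic, ties included", {
  set.seed(73)
  for (r in 1:50) {
    y <- rbinom(40, 1, 0.5)
    if (length(unique(y)) < 2) y[1] <- 1L - y[1]
    # integer scores force ties between and within classes
    s <- sample(1:8, 40, replace = TRUE) + ifelse(y == 1, rpois(40, 1), 0)
    expect_equal(roc_auc(y, s)$auc, auc_rank_reference(y, s),
                 tolerance = 1e-12)
  }
})

test_that("sweep AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(74)
  y <- rbinom(150, 1, 0.4)
  s <- rnorm(150) + y
  ref <- as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE, direction = "<")))
  expect_equal(roc_auc(y, s)$auc, ref, tolerance = 1e-12)
})

test_that("paired t-test matches the textbook formula and stats::t.test", {
  a <- c(0.90, 0.915, 0.89, 0.905, 0.90)
  b <- c(0.85, 0.862, 0.843, 0.851, 0.848)
  got <- paired_accuracy_ttest(a, b)
  d <- a - b
  t_ref <- mean(d) / (sd(d) / sqrt(5))
  p_ref <- 2 * pt(-abs(t_ref), df = 4)
  expect_equal(got$t_stat, t_ref, tolerance = 1e-10)
  expect_equal(got$p_value, p_ref, tolerance = 1e-10)
  ref <- stats::t.test(a, b, paired = TRUE)
  expect_equal(got$t_stat, unname(ref$statistic), tolerance = 1e-10)
  expect_equal(got$p_value, ref$p.value, tolerance = 1e-10)
  expect_equal(got$df, 4L)
  expect_equal(got$mean_a, mean(a)); expect_equal(got$sd_b, sd(b))
})

test_that("degenerate difference vectors are handled explicitly", {
  same <- c(0.8, 0.9, 0.85)
  r0 <- paired_accuracy_ttest(same, same)
  expect_equal(r0$t_stat, 0); expect_equal(r0$p_value, 1)
  expect_false(r0$degenerate)
  rconst <- paired_accuracy_ttest(same + 0.05, same)
  expect_true(rconst$degenerate)
  expect_gt(rconst$p_value, 0)
  expect_lt(rconst$p_value, 1e-100)
  expect_error(paired_accuracy_ttest(0.9, 0.8), "at least 2")
  expect_error(paired_accuracy_ttest(c(1, 2), 1), "equal length")
})

test_that("rendered reports have one row per model/dimension/class", {
  y <- rep(c(0L, 1L), each = 30)
  p <- y; p[c(1, 40)] <- 1L - p[c(1, 40)]
  entry <- function(m, dim) list(model = m, feature = "DE", dimension = dim,
                                 cv = confusion_metrics(y, p, scores = p + rnorm(60, sd = 0.1)))
  one <- render_report(list(entry("xgboost", "valence")))
  expect_equal(nrow(one), 2)
  grid <- list()
  for (m in c("knn", "svm", "xgboost", "gradient_boosting")) {
    for (d in c("valence", "arousal")) grid <- c(grid, list(entry(m, d)))
  }
  all16 <- render_report(grid)
  expect_equal(nrow(all16), 16)
  expect_true(all(c("accuracy", "precision", "recall", "f1", "support") %in%
                    names(all16)))
})

test_that("JSON reports keep full precision while rendering rounds", {
  y <- rep(c(0L, 1L), each = 50)
  p <- y; p[1:7] <- 1L - p[1:7]
  entry <- list(model = "knn", feature = "DE", dimension = "valence",
                cv = confusion_metrics(y, p))
  path <- withr::local_tempfile(fileext = ".json")
  write_report_json(list(entry), path)
  back <- jsonlite::read_json(path)
  expect_equal(back[[1]]$accuracy, entry$cv$accuracy, tolerance = 1e-15)
  rendered <- render_report(list(entry))
  expect_equal(rendered$accuracy[1], round(entry$cv$accuracy, 2))
})
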