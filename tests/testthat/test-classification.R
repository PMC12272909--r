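test_that("estimator specs validate family and parameter names", {
  expect_error(estimator_spec("random_forest"), "arg")
  expect_error(estimator_spec("knn", params = list(k = 3)), "unknown parameter")
  # tuned defaults for the four families
  expect_equal(estimator_spec("knn")$params$n_neighbors, 5L)
  expect_equal(estimator_spec("svm")$params$C, 1)
  expect_identical(estimator_spec("svm")$params$gamma, "scale")
  expect_equal(estimator_spec("gradient_boosting")$params$n_estimators, 100L)
  expect_equal(estimator_spec("xgboost")$random_state, 42L)
})

test_that("every family separates well-separated blobs perfectly", {
  blobs <- make_blobs(100, d = 2, sep = 6, seed = 51)
  idx <- seq(1, 200, by = 2)
  for (fam in c("knn", "svm", "xgboost", "gradient_boosting")) {
    fp <- fit_predict(estimator_spec(fam), blobs$x[idx, ], blobs$y[idx],
                      blobs$x[-idx, ])
    expect_equal(mean(fp$pred == blobs$y[-idx]), 1.0)
    expect_length(fp$score, 100)
    expect_true(all(fp$score >= 0 & fp$score <= 1))
  }
})

test_that("fit_predict enforces its contract", {
  blobs <- make_blobs(20, seed = 52)
  bad <- blobs$x; colnames(bad) <- c("zz", "f02")
  expect_error(fit_predict(estimator_spec("knn"), blobs$x, blobs$y, bad),
               "contract")
  expect_error(fit_predict(estimator_spec("svm"), blobs$x, rep(1L, 40), blobs$x),
               "degenerate training")
})

test_that("1-NN labels its own training points perfectly", {
  blobs <- make_blobs(50, sep = 2, seed = 53)  # overlapping on purpose
  fp <- fit_predict(estimator_spec("knn", params = list(n_neighbors = 1L)),
                    blobs$x, blobs$y, blobs$x)
  expect_equal(mean(fp$pred == blobs$y), 1.0)
})

test_that("stratified folds partition the rows and preserve class ratio", {
  set.seed(54)
  y <- rbinom(503, 1, 0.37)
  x <- matrix(rnorm(503 * 3), ncol = 3, dimnames = list(NULL, c("a", "b", "c")))
  cv <- kfold_evaluate(estimator_spec("knn"), x, y, k = 5, seed = 7)
  f <- cv$fold_assignment
  expect_setequal(unique(f), 1:5)
  expect_equal(sum(table(f)), 503)          # disjoint union = all rows
  expect_true(max(table(f)) - min(table(f)) <= 1)
  global1 <- sum(y == 1)
  for (k in 1:5) {
    expect_lt(abs(sum(y[f == k] == 1) - global1 / 5), 2 + 1e-9)
  }
})

test_that("fold assignment and pooled confusion are reproducible from the seed", {
  blobs <- make_blobs(60, sep = 3, seed = 55)
  cv1 <- kfold_evaluate(estimator_spec("xgboost"), blobs$x, blobs$y, k = 5, seed = 11)
  cv2 <- kfold_evaluate(estimator_spec("xgboost"), blobs$x, blobs$y, k = 5, seed = 11)
  expect_identical(cv1$fold_assignment, cv2$fold_assignment)
  expect_identical(cv1$pooled$confusion, cv2$pooled$confusion)
  cv3 <- kfold_evaluate(estimator_spec("xgboost"), blobs$x, blobs$y, k = 5, seed = 12)
  expect_false(identical(cv1$fold_assignment, cv3$fold_assignment))
})

test_that("separable classes give pooled accuracy 1 in cross-validation", {
  blobs <- make_blobs(100, sep = 6, seed = 56)
  for (fam in c("svm", "knn")) {
    cv <- kfold_evaluate(estimator_spec(fam), blobs$x, blobs$y, k = 5)
    expect_equal(cv$pooled$accuracy, 1.0)
    expect_equal(cv$accuracies, rep(1, 5))
  }
})

test_that("label-shuffled features score at the majority-class rate", {
  set.seed(57)
  x <- matrix(rnorm(500 * 4), ncol = 4,
              dimnames = list(NULL, paste0("f", 1:4)))
  y <- rep(c(0L, 1L), c(300, 200))          # majority fraction 0.6
  y <- sample(y)                            # no relation to x by construction
  # a strongly regularized SVM falls back to the class prior under the null
  cv <- kfold_evaluate(estimator_spec("svm", params = list(C = 0.1)),
                       x, y, k = 5, seed = 3)
  expect_lt(abs(cv$pooled$accuracy - 0.6), 0.03 + 1e-9)
})

test_that("grouped splits never let a group straddle folds", {
  set.seed(58)
  groups <- rep(sprintf("t%02d", 1:40), each = 10)
  x <- matrix(rnorm(400 * 2), ncol = 2, dimnames = list(NULL, c("a", "b")))
  y <- rep(rbinom(40, 1, 0.5), each = 10)
  if (length(unique(y)) == 1L) y[1:10] <- 1L - y[1:10]
  cv <- kfold_evaluate(estimator_spec("knn"), x, y, k = 4, seed = 2,
                       split = "trial", groups = groups)
  spread <- tapply(cv$fold_assignment, groups, function(v) length(unique(v)))
  expect_true(all(spread == 1))
})

test_that("grid search is an argmax over the candidate grid", {
  blobs <- make_blobs(60, sep = 1.5, seed = 59)  # moderate overlap
  gs1 <- grid_search("knn", list(n_neighbors = 5L), blobs$x, blobs$y, k = 3)
  expect_equal(gs1$best_params$n_neighbors, 5L)
  expect_equal(gs1$best_score, gs1$all_scores$mean_cv_accuracy[1])

  gs <- grid_search("knn", list(n_neighbors = c(1L, 5L, 51L)),
                    blobs$x, blobs$y, k = 3, seed = 4)
  # oracle: evaluate each candidate independently
  singles <- vapply(c(1L, 5L, 51L), function(k) {
    sp <- estimator_spec("knn", params = list(n_neighbors = k))
    mean(kfold_evaluate(sp, blobs$x, blobs$y, k = 3, seed = 4)$accuracies)
  }, numeric(1))
  expect_equal(gs$best_score, max(singles))
  expect_equal(gs$all_scores$mean_cv_accuracy, singles)
  expect_equal(gs$best_params$n_neighbors, c(1L, 5L, 51L)[which.max(singles)])
  expect_error(grid_search("knn", list(), blobs$x, blobs$y), "empty")
  expect_error(grid_search("knn", list(n_neighbors = integer(0)), blobs$x, blobs$y),
               "empty candidate")
})

test_that("grid search best score reproduces when re-run with best params", {
  blobs <- make_blobs(50, sep = 1.5, seed = 60)
  gs <- grid_search("knn", list(n_neighbors = c(3L, 9L)), blobs$x, blobs$y,
                    k = 3, seed = 5)
  sp <- estimator_spec("knn", params = gs$best_params)
  rerun <- mean(kfold_evaluate(sp, blobs$x, blobs$y, k = 3, seed = 5)$accuracies)
  expect_equal(rerun, gs$best_score, tolerance = 0.005)
})

test_that("LOSO builds one fold per subject and respects subject boundaries", {
  blobs <- make_blobs(100, sep = 6, seed = 61)
  subjects <- rep(sprintf("s%02d", 1:10), times = 20)
  res <- loso_evaluate(estimator_spec("knn"), blobs$x, blobs$y, subjects)
  expect_length(res$per_subject, 10)
  expect_equal(sum(vapply(res$per_subject, function(r) r$n, numeric(1))), 200)
  expect_equal(res$averages$accuracy, 1.0)

  two <- loso_evaluate(estimator_spec("svm"), blobs$x, blobs$y,
                       rep(c("a", "b"), 100))
  expect_length(two$per_subject, 2)
  expect_equal(two$averages$accuracy, 1.0)
  expect_error(loso_evaluate(estimator_spec("knn"), blobs$x, blobs$y,
                             rep("a", 200)), "at least 2")
})

test_that("subject-specific offsets without class signal stay at chance in LOSO", {
  set.seed(62)
  n_sub <- 8; n_per <- 60
  x <- NULL; y <- NULL; subj <- NULL
  for (s in 1:n_sub) {
    xs <- matrix(rnorm(n_per * 3), ncol = 3) + rnorm(1, sd = 3)  # subject offset
    x <- rbind(x, xs)
    y <- c(y, rbinom(n_per, 1, 0.5))  # labels carry no signal
    subj <- c(subj, rep(sprintf("s%d", s), n_per))
  }
  colnames(x) <- paste0("f", 1:3)
  res <- loso_evaluate(estimator_spec("xgboost", params = list(nrounds = 50L)),
                       x, y, subj)
  expect_lt(abs(res$averages$accuracy - 0.5), 0.05 + 1e-9)
})

test_that("single-class subjects are flagged and excluded from LOSO averages", {
  blobs <- make_blobs(30, sep = 6, seed = 63)
  # s1 and s2 see both classes; s3's rows are all class 1
  subj <- c(rep("s1", 15), rep("s2", 15), rep("s1", 15), rep("s2", 5), rep("s3", 10))
  expect_warning(
    res <- loso_evaluate(estimator_spec("knn"), blobs$x, blobs$y, subj),
    "single class")
  expect_identical(res$excluded_subjects, "s3")
})
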