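#' Estimator specification
#'
#' One of four classifier families behind a common fit/predict contract:
#' `knn` (k-nearest neighbours, Euclidean distance, uniform votes),
#' `svm` (RBF-kernel support vector machine), `xgboost` (extreme gradient
#' boosting, binary logistic objective with log-loss evaluation), and
#' `gradient_boosting` (classic gradient boosting: shrinkage 0.1, depth-3
#' trees, 100 rounds, no stochastic subsampling; run on the same boosted-tree
#' backend). Distance-based families (`knn`, `svm`) receive features
#' standardized with training-fold statistics; tree ensembles receive raw
#' features.
#'
#' Defaults mirror the tuned values commonly reported for this task:
#' `knn` `n_neighbors = 5`; `svm` `C = 1`, `gamma = "scale"`; `xgboost`
#' log-loss metric; `gradient_boosting` `n_estimators = 100`.
#'
#' @param family one of `"knn"`, `"svm"`, `"xgboost"`, `"gradient_boosting"`.
#' @param params named list of family parameters; unknown names are rejected.
#' @param random_state integer seed controlling every stochastic step of the
#'   family (default 42).
#' @return an object of class `estimator_spec`.
#' @export
estimator_spec <- function(family = c("knn", "svm", "xgboost", "gradient_boosting"),
                           params = list(), random_state = 42L) {
  family <- match.arg(family)
  defaults <- switch(family,
    knn = list(n_neighbors = 5L),
    svm = list(C = 1, gamma = "scale"),
    xgboost = list(nrounds = 100L, max_depth = 6L, eta = 0.3),
    gradient_boosting = list(n_estimators = 100L, learning_rate = 0.1, max_depth = 3L)
  )
  unknown <- setdiff(names(params), names(defaults))
  if (length(unknown) > 0L) {
    stop(sprintf("unknown parameter(s) for family %s: %s",
                 family, paste(unknown, collapse = ", ")))
  }
  defaults[names(params)] <- params
  structure(list(family = family, params = defaults,
                 random_state = as.integer(random_state)),
            class = "estimator_spec")
}

#' @export
print.estimator_spec <- function(x, ...) {
  p <- paste(names(x$params), vapply(x$params, format, character(1)),
             sep = " = ", collapse = ", ")
  cat(sprintf("<estimator_spec> %s (%s), random_state = %d\n",
              x$family, p, x$random_state))
  invisible(x)
}

needs_scaling <- function(spec) spec$family %in% c("knn", "svm")

as_values <- function(x) {
  if (inherits(x, "feature_matrix")) x$values else as.matrix(x)
}

#' Fit an estimator and predict test labels and scores
#'
#' Trains the specified family on `(train_x, train_y)` and returns one
#' predicted label plus one continuous class-1 score per test row.
#' Probability-producing families return the class-1 probability; the SVM
#' returns its signed decision value min-max mapped to \[0, 1\]. Deterministic
#' given `spec$random_state`.
#'
#' @param spec an `estimator_spec`.
#' @param train_x,test_x numeric feature matrices (or `feature_matrix`
#'   objects) with matching column names.
#' @param train_y integer labels in `{0, 1}`; both classes must be present.
#' @return `list(pred = integer labels, score = numeric class-1 scores)`.
#' @export
fit_predict <- function(spec, train_x, train_y, test_x) {
  stopifnot(inherits(spec, "estimator_spec"))
  train_x <- as_values(train_x)
  test_x <- as_values(test_x)
  if (!identical(colnames(train_x), colnames(test_x))) {
    stop("contract error: test columns do not match training columns")
  }
  train_y <- as.integer(train_y)
  if (length(train_y) != nrow(train_x)) stop("one label per training row required")
  if (length(unique(train_y)) < 2L) {
    stop("degenerate training set: only one class present")
  }
  if (needs_scaling(spec)) {
    mu <- colMeans(train_x)
    sdv <- apply(train_x, 2L, stats::sd)
    sdv[sdv == 0] <- 1
    train_x <- sweep(sweep(train_x, 2L, mu), 2L, sdv, "/")
    test_x <- sweep(sweep(test_x, 2L, mu), 2L, sdv, "/")
  }
  switch(spec$family,
    knn = fit_predict_knn(spec, train_x, train_y, test_x),
    svm = fit_predict_svm(spec, train_x, train_y, test_x),
    xgboost = fit_predict_boost(train_x, train_y, test_x,
                                nrounds = spec$params$nrounds,
                                max_depth = spec$params$max_depth,
                                eta = spec$params$eta,
                                seed = spec$random_state),
    gradient_boosting = fit_predict_boost(train_x, train_y, test_x,
                                          nrounds = spec$params$n_estimators,
                                          max_depth = spec$params$max_depth,
                                          eta = spec$params$learning_rate,
                                          seed = spec$random_state)
  )
}

fit_predict_knn <- function(spec, train_x, train_y, test_x) {
  k <- as.integer(spec$params$n_neighbors)
  old_seed <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  set.seed(spec$random_state)  # vote ties in class::knn are broken at random
  on.exit(restore_seed(old_seed))
  pred <- class::knn(train_x, test_x, factor(train_y, levels = c(0L, 1L)),
                     k = k, prob = TRUE)
  win_prob <- attr(pred, "prob")
  pred <- as.integer(as.character(pred))
  score <- ifelse(pred == 1L, win_prob, 1 - win_prob)
  list(pred = pred, score = as.numeric(score))
}

fit_predict_svm <- function(spec, train_x, train_y, test_x) {
  gamma <- spec$params$gamma
  if (identical(gamma, "scale")) {
    v <- mean(apply(train_x, 2L, stats::var))
    gamma <- if (v > 0) 1 / (ncol(train_x) * v) else 1 / ncol(train_x)
  }
  y <- factor(train_y, levels = c(0L, 1L))
  fit <- e1071::svm(train_x, y, kernel = "radial", cost = spec$params$C,
                    gamma = gamma, scale = FALSE)
  pr <- stats::predict(fit, test_x, decision.values = TRUE)
  dv <- attr(pr, "decision.values")[, 1L]
  # orient decision values so larger means class 1
  if (grepl("^0/", colnames(attr(pr, "decision.values"))[1L])) dv <- -dv
  rng <- range(dv)
  score <- if (rng[1L] == rng[2L]) rep(0.5, length(dv)) else (dv - rng[1L]) / diff(rng)
  list(pred = as.integer(as.character(pr)), score = as.numeric(score))
}

fit_predict_boost <- function(train_x, train_y, test_x, nrounds, max_depth, eta, seed) {
  dtrain <- xgboost::xgb.DMatrix(data = unname(train_x), label = train_y, nthread = 1)
  params <- list(objective = "binary:logistic", eval_metric = "logloss",
                 max_depth = as.integer(max_depth), eta = eta,
                 nthread = 1, seed = as.integer(seed))
  bst <- xgboost::xgb.train(params = params, data = dtrain,
                            nrounds = as.integer(nrounds), verbose = 0)
  prob <- stats::predict(bst, xgboost::xgb.DMatrix(unname(test_x), nthread = 1))
  list(pred = as.integer(prob > 0.5), score = as.numeric(prob))
}

restore_seed <- function(old_seed) {
  if (is.null(old_seed)) {
    if (exists(".Random.seed", .GlobalEnv)) rm(".Random.seed", envir = .GlobalEnv)
  } else {
    assign(".Random.seed", old_seed, envir = .GlobalEnv)
  }
}

# Stratified shuffled fold assignment: within each class, indices are
# shuffled and dealt cyclically; the dealing position carries over between
# classes so total fold sizes differ by at most one row.
make_stratified_folds <- function(y, k, seed) {
  n <- length(y)
  folds <- integer(n)
  old_seed <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  set.seed(seed)
  on.exit(restore_seed(old_seed))
  pos <- 0L
  for (cls in sort(unique(y))) {
    idx <- sample(which(y == cls))
    folds[idx] <- ((pos + seq_along(idx) - 1L) %% k) + 1L
    pos <- (pos + length(idx)) %% k
  }
  folds
}

# Group-aware fold assignment: whole groups (trials or subjects) are shuffled
# and dealt cyclically, so no group straddles folds.
make_group_folds <- function(groups, k, seed) {
  u <- unique(groups)
  if (length(u) < k) stop(sprintf("only %d groups for %d folds", length(u), k))
  old_seed <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  set.seed(seed)
  on.exit(restore_seed(old_seed))
  shuffled <- sample(u)
  gf <- ((seq_along(shuffled) - 1L) %% k) + 1L
  gf[match(groups, shuffled)]
}

#' Stratified k-fold cross-validation
#'
#' Evaluates an estimator with stratified shuffled k-fold CV. The default
#' split is at segment level (segments of one trial may land in different
#' folds), matching the within-subject protocol; because segment-level
#' splitting lets a classifier exploit trial identity, trial- and
#' subject-grouped splitters are also provided via `split` + `groups`.
#'
#' @param spec an `estimator_spec`.
#' @param x feature matrix (or `feature_matrix`).
#' @param y integer labels in `{0, 1}`.
#' @param k number of folds (default 5, i.e. 80/20 train/test per fold).
#' @param seed fold-shuffling seed (default 42); the assignment is
#'   reproducible from it.
#' @param split `"segment"` (stratified rows), `"trial"` or `"subject"`
#'   (grouped; requires `groups`).
#' @param groups group key per row for grouped splits.
#' @return an object of class `cv_result`: `per_fold` (list of
#'   `evaluation_report`), `pooled` (report over concatenated test
#'   predictions, with ROC), `fold_assignment`, `accuracies` (per-fold),
#'   `flagged_folds` (folds whose test part had a single class).
#' @export
kfold_evaluate <- function(spec, x, y, k = 5, seed = 42,
                           split = c("segment", "trial", "subject"),
                           groups = NULL) {
  split <- match.arg(split)
  xv <- as_values(x)
  y <- as.integer(y)
  if (k < 2L) stop("k must be at least 2")
  if (nrow(xv) < k) stop("fewer rows than folds")
  if (length(y) != nrow(xv)) stop("one label per row required")
  folds <- if (split == "segment") {
    make_stratified_folds(y, k, seed)
  } else {
    if (is.null(groups)) stop(sprintf("split = '%s' requires `groups`", split))
    make_group_folds(as.character(groups), k, seed)
  }
  per_fold <- vector("list", k)
  accuracies <- numeric(k)
  flagged <- integer(0)
  all_pred <- integer(nrow(xv))
  all_score <- numeric(nrow(xv))
  for (f in seq_len(k)) {
    test_idx <- which(folds == f)
    train_idx <- which(folds != f)
    fp <- fit_predict(spec, xv[train_idx, , drop = FALSE], y[train_idx],
                      xv[test_idx, , drop = FALSE])
    all_pred[test_idx] <- fp$pred
    all_score[test_idx] <- fp$score
    if (length(unique(y[test_idx])) < 2L) flagged <- c(flagged, f)
    per_fold[[f]] <- confusion_metrics(y[test_idx], fp$pred,
                                       scores = if (length(unique(y[test_idx])) > 1L) fp$score)
    accuracies[f] <- per_fold[[f]]$accuracy
  }
  pooled <- confusion_metrics(y, all_pred,
                              scores = if (length(unique(y)) > 1L) all_score)
  structure(list(per_fold = per_fold, pooled = pooled,
                 fold_assignment = folds, accuracies = accuracies,
                 flagged_folds = flagged, k = k, seed = seed, split = split),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> %d-fold (%s split): pooled accuracy %.4f, per-fold %s\n",
              x$k, x$split, x$pooled$accuracy,
              paste(sprintf("%.3f", x$accuracies), collapse = " ")))
  invisible(x)
}

#' Exhaustive grid search over estimator parameters
#'
#' Evaluates every combination of the candidate lists by mean k-fold CV
#' accuracy; ties are broken by the first combination encountered in the
#' deterministic grid order (`expand.grid` over the candidates as given).
#'
#' @param family estimator family name.
#' @param grid named list of candidate vectors (non-empty).
#' @param x,y,k,seed as in [kfold_evaluate()].
#' @param random_state seed forwarded to each estimator.
#' @return `list(best_params, best_score, all_scores)` where `all_scores` is
#'   a data frame of combinations and their mean CV accuracy.
#' @export
grid_search <- function(family, grid, x, y, k = 5, seed = 42, random_state = 42L) {
  if (length(grid) == 0L) stop("empty grid")
  if (any(vapply(grid, length, integer(1)) == 0L)) stop("empty candidate list in grid")
  combos <- expand.grid(grid, stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  scores <- numeric(nrow(combos))
  for (i in seq_len(nrow(combos))) {
    params <- as.list(combos[i, , drop = FALSE])
    names(params) <- names(combos)
    spec <- estimator_spec(family, params = params, random_state = random_state)
    cv <- kfold_evaluate(spec, x, y, k = k, seed = seed)
    scores[i] <- mean(cv$accuracies)
  }
  best <- which.max(scores)  # first max in grid order
  all_scores <- cbind(combos, mean_cv_accuracy = scores)
  best_params <- as.list(combos[best, , drop = FALSE])
  names(best_params) <- names(combos)
  list(best_params = best_params, best_score = scores[best], all_scores = all_scores)
}

#' Leave-one-subject-out cross-validation
#'
#' One fold per distinct subject: the model trains on all other subjects and
#' is tested on the held-out subject's rows, so reported performance reflects
#' generalization to unseen individuals. Subjects whose rows contain a single
#' class are flagged and excluded from the averaged metrics with a warning.
#'
#' @param spec an `estimator_spec`.
#' @param x feature matrix (or `feature_matrix`).
#' @param y integer labels in `{0, 1}`.
#' @param subject_ids subject key per row (>= 2 distinct values).
#' @return an object of class `loso_result`: `per_subject` (named list of
#'   `evaluation_report`), `averages` (mean accuracy and mean per-class
#'   precision/recall/F1 over included folds), `excluded_subjects`.
#' @export
loso_evaluate <- function(spec, x, y, subject_ids) {
  xv <- as_values(x)
  y <- as.integer(y)
  subject_ids <- as.character(subject_ids)
  if (length(subject_ids) != nrow(xv)) stop("one subject id per row required")
  subjects <- unique(subject_ids)
  if (length(subjects) < 2L) stop("LOSO requires at least 2 distinct subjects")
  per_subject <- stats::setNames(vector("list", length(subjects)), subjects)
  excluded <- character(0)
  for (s in subjects) {
    test_idx <- which(subject_ids == s)
    train_idx <- which(subject_ids != s)
    fp <- fit_predict(spec, xv[train_idx, , drop = FALSE], y[train_idx],
                      xv[test_idx, , drop = FALSE])
    single <- length(unique(y[test_idx])) < 2L
    per_subject[[s]] <- confusion_metrics(y[test_idx], fp$pred,
                                          scores = if (!single) fp$score)
    if (single) {
      warning(sprintf("subject %s has a single class; excluded from averages", s))
      excluded <- c(excluded, s)
    }
  }
  included <- setdiff(subjects, excluded)
  avg_of <- function(get) mean(vapply(per_subject[included], get, numeric(1)), na.rm = TRUE)
  averages <- list(
    accuracy = avg_of(function(r) r$accuracy),
    precision = c(class0 = avg_of(function(r) r$per_class$precision[1L]),
                  class1 = avg_of(function(r) r$per_class$precision[2L])),
    recall = c(class0 = avg_of(function(r) r$per_class$recall[1L]),
               class1 = avg_of(function(r) r$per_class$recall[2L])),
    f1 = c(class0 = avg_of(function(r) r$per_class$f1[1L]),
           class1 = avg_of(function(r) r$per_class$f1[2L]))
  )
  structure(list(per_subject = per_subject, averages = averages,
                 excluded_subjects = excluded),
            class = "loso_result")
}

#' @export
print.loso_result <- function(x, ...) {
  cat(sprintf("<loso_result> %d subjects, mean accuracy %.4f%s\n",
              length(x$per_subject), x$averages$accuracy,
              if (length(x$excluded_subjects) > 0L)
                sprintf(" (%d excluded)", length(x$excluded_subjects)) else ""))
  invisible(x)
}
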