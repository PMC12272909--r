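#' Confusion-matrix metrics for binary predictions
#'
#' Computes accuracy `(TP+TN)/(TP+TN+FP+FN)` and, for each class treated in
#' turn as positive, precision `TP/(TP+FP)`, recall `TP/(TP+FN)` and the F1
#' harmonic mean `2PR/(P+R)`, plus the class supports. Ratios with zero
#' denominators are reported as `NA` (undefined), never silently zero-filled.
#' When continuous class-1 scores are supplied the ROC sweep and AUC are
#' attached.
#'
#' @param y_true,y_pred integer vectors in `{0, 1}`, equal length >= 1.
#' @param scores optional continuous class-1 scores for ROC/AUC.
#' @return an object of class `evaluation_report`: `tp`, `tn`, `fp`, `fn`
#'   (class-1 viewpoint), `accuracy`, `per_class` data frame
#'   (label, precision, recall, f1, support), `confusion` (2x2, rows = true),
#'   and optionally `roc_points`/`auc`.
#' @export
confusion_metrics <- function(y_true, y_pred, scores = NULL) {
  y_true <- as.integer(y_true)
  y_pred <- as.integer(y_pred)
  n <- length(y_true)
  if (n < 1L || length(y_pred) != n) stop("y_true and y_pred must have equal length >= 1")
  if (!all(c(y_true, y_pred) %in% c(0L, 1L))) stop("labels must be 0 or 1")
  tp <- sum(y_true == 1L & y_pred == 1L)
  tn <- sum(y_true == 0L & y_pred == 0L)
  fp <- sum(y_true == 0L & y_pred == 1L)
  fn <- sum(y_true == 1L & y_pred == 0L)
  accuracy <- (tp + tn) / n
  ratio <- function(num, den) if (den == 0L) NA_real_ else num / den
  class_row <- function(label) {
    # per-class view: `label` as the positive class
    tpc <- sum(y_true == label & y_pred == label)
    fpc <- sum(y_true != label & y_pred == label)
    fnc <- sum(y_true == label & y_pred != label)
    p <- ratio(tpc, tpc + fpc)
    r <- ratio(tpc, tpc + fnc)
    f1 <- if (is.na(p) || is.na(r) || p + r == 0) NA_real_ else 2 * p * r / (p + r)
    data.frame(label = label, precision = p, recall = r, f1 = f1,
               support = sum(y_true == label))
  }
  per_class <- rbind(class_row(0L), class_row(1L))
  confusion <- matrix(c(tn, fp, fn, tp), nrow = 2L, byrow = TRUE,
                      dimnames = list(true = c("0", "1"), pred = c("0", "1")))
  rep <- structure(list(tp = tp, tn = tn, fp = fp, fn = fn,
                        accuracy = accuracy, per_class = per_class,
                        confusion = confusion, n = n),
                   class = "evaluation_report")
  if (!is.null(scores)) {
    roc <- roc_auc(y_true, scores)
    rep$roc_points <- roc$roc_points
    rep$auc <- roc$auc
  }
  rep
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report> n = %d, accuracy = %.4f%s\n", x$n, x$accuracy,
              if (!is.null(x$auc)) sprintf(", AUC = %.4f", x$auc) else ""))
  print(x$per_class, row.names = FALSE)
  invisible(x)
}

#' ROC curve and AUC by threshold sweep
#'
#' Sweeps the decision threshold over the unique scores (ties grouped into a
#' single step), yielding (FPR, TPR) points from (0, 0) to (1, 1), and
#' integrates the area under the curve by the trapezoidal rule. With grouped
#' ties this equals the Mann-Whitney U statistic divided by `n0 * n1`.
#'
#' @param y_true integer labels in `{0, 1}`; both classes must be present.
#' @param scores continuous class-1 scores, one per label.
#' @return `list(roc_points = data.frame(threshold, fpr, tpr), auc)`.
#' @export
roc_auc <- function(y_true, scores) {
  y_true <- as.integer(y_true)
  if (length(scores) != length(y_true)) stop("one score per label required")
  n1 <- sum(y_true == 1L)
  n0 <- sum(y_true == 0L)
  if (n1 == 0L || n0 == 0L) stop("undefined AUC: a single class in y_true")
  ord <- order(scores, decreasing = TRUE)
  ys <- y_true[ord]
  ss <- scores[ord]
  cum_tp <- cumsum(ys == 1L)
  cum_fp <- cumsum(ys == 0L)
  last_of_tie <- c(ss[-1L] != ss[-length(ss)], TRUE)
  tpr <- c(0, cum_tp[last_of_tie] / n1)
  fpr <- c(0, cum_fp[last_of_tie] / n0)
  thr <- c(Inf, ss[last_of_tie])
  auc <- sum(diff(fpr) * (utils::head(tpr, -1L) + utils::tail(tpr, -1L)) / 2)
  list(roc_points = data.frame(threshold = thr, fpr = fpr, tpr = tpr), auc = auc)
}

#' Paired t-test on per-fold accuracy vectors
#'
#' Two-sided paired Student's t-test comparing two classifiers' or two
#' features' per-fold accuracies: `t = mean(d) / (sd(d) / sqrt(n))` on the
#' differences `d = a - b`, with `n - 1` degrees of freedom. When the
#' differences have zero variance the statistic degenerates: all-zero
#' differences give `t = 0, p = 1`; a constant nonzero difference is
#' reported with a numerically floored p-value and `degenerate = TRUE`. To
#' reach finer p-value resolution than `n` folds allow, pool per-fold
#' accuracies across repeated CV runs with different seeds before calling.
#'
#' @param acc_a,acc_b numeric accuracy vectors of equal length >= 2, paired
#'   by fold.
#' @return an object of class `t_test_result`: `t_stat`, `p_value`, `df`,
#'   `mean_a`, `mean_b`, `sd_a`, `sd_b`, `degenerate`.
#' @export
paired_accuracy_ttest <- function(acc_a, acc_b) {
  if (length(acc_a) != length(acc_b)) stop("paired vectors must have equal length")
  n <- length(acc_a)
  if (n < 2L) stop("need at least 2 pairs (df = n - 1 >= 1)")
  d <- acc_a - acc_b
  sdd <- stats::sd(d)
  degenerate <- FALSE
  if (sdd == 0) {
    if (mean(d) == 0) {
      t_stat <- 0
      p <- 1
    } else {
      t_stat <- sign(mean(d)) * Inf
      p <- .Machine$double.xmin
      degenerate <- TRUE
    }
  } else {
    t_stat <- mean(d) / (sdd / sqrt(n))
    p <- 2 * stats::pt(-abs(t_stat), df = n - 1L)
  }
  structure(list(t_stat = t_stat, p_value = p, df = n - 1L,
                 mean_a = mean(acc_a), mean_b = mean(acc_b),
                 sd_a = stats::sd(acc_a), sd_b = stats::sd(acc_b),
                 degenerate = degenerate),
            class = "t_test_result")
}

#' @export
print.t_test_result <- function(x, ...) {
  cat(sprintf("<t_test_result> t = %.4f, df = %d, p = %.3g (means %.4f vs %.4f)\n",
              x$t_stat, x$df, x$p_value, x$mean_a, x$mean_b))
  invisible(x)
}

#' Render cross-validation results as a per-class table
#'
#' One row per (model, feature, dimension, class) with accuracy, precision,
#' recall, F1 and support from the pooled report. Values are kept at full
#' precision internally; rounding (default 2 decimals) happens only here, at
#' render time.
#'
#' @param results list of entries, each
#'   `list(model =, feature =, dimension =, cv = cv_result or
#'   evaluation_report)`.
#' @param digits decimals for the rendered numbers (`NULL` to keep full
#'   precision).
#' @return a data frame.
#' @export
render_report <- function(results, digits = 2) {
  if (length(results) == 0L) stop("no results to render")
  rows <- lapply(results, function(entry) {
    rep <- if (inherits(entry$cv, "cv_result")) entry$cv$pooled else entry$cv
    pc <- rep$per_class
    data.frame(model = entry$model, feature = entry$feature,
               dimension = entry$dimension,
               accuracy = rep$accuracy, class = pc$label,
               precision = pc$precision, recall = pc$recall, f1 = pc$f1,
               support = pc$support,
               auc = if (!is.null(rep$auc)) rep$auc else NA_real_)
  })
  out <- do.call(rbind, rows)
  if (!is.null(digits)) {
    num <- c("accuracy", "precision", "recall", "f1", "auc")
    out[num] <- lapply(out[num], round, digits = digits)
  }
  out
}

#' Write evaluation results to JSON
#'
#' Serializes each entry as
#' `{model, feature, dimension, accuracy, classes: [{label, precision,
#' recall, f1, support}], auc, confusion}` at full numeric precision.
#'
#' @param results as in [render_report()].
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(results, path) {
  payload <- lapply(results, function(entry) {
    rep <- if (inherits(entry$cv, "cv_result")) entry$cv$pooled else entry$cv
    list(model = entry$model, feature = entry$feature,
         dimension = entry$dimension, accuracy = rep$accuracy,
         classes = lapply(seq_len(nrow(rep$per_class)), function(i) {
           pc <- rep$per_class[i, ]
           list(label = pc$label, precision = pc$precision, recall = pc$recall,
                f1 = pc$f1, support = pc$support)
         }),
         auc = if (!is.null(rep$auc)) rep$auc else NULL,
         confusion = unname(apply(rep$confusion, 1L, as.list)))
  })
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
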