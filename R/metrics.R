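# Classification metric suite computed from first principles: confusion
# matrix, accuracy, precision, recall/sensitivity, F1, specificity, MCC,
# balanced accuracy, Cohen's kappa, and macro one-vs-rest AUC. Binary
# metrics follow the standard TP/TN/FP/FN formulas; multi-class scalars are
# macro-averaged one-vs-rest. McNemar and paired t tests compare
# classifiers.

# Per-class one-vs-rest counts from a confusion matrix (rows = truth).
ovr_counts <- function(cm) {
  n <- sum(cm)
  t(vapply(seq_len(nrow(cm)), function(c) {
    tp <- cm[c, c]
    fn <- sum(cm[c, ]) - tp
    fp <- sum(cm[, c]) - tp
    tn <- n - tp - fn - fp
    c(tp = tp, tn = tn, fp = fp, fn = fn)
  }, numeric(4)))
}

safe_div <- function(a, b) ifelse(b == 0, 0, a / b)

binary_metric_row <- function(tp, tn, fp, fn) {
  acc <- safe_div(tp + tn, tp + tn + fp + fn)
  prec <- safe_div(tp, tp + fp)
  rec <- safe_div(tp, tp + fn)
  f1 <- safe_div(2 * prec * rec, prec + rec)
  spec <- safe_div(tn, tn + fp)
  mcc_den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  mcc <- if (mcc_den == 0) 0 else (tp * tn - fp * fn) / mcc_den
  bal <- (rec + spec) / 2
  c(accuracy = acc, precision = prec, recall = rec, f1 = f1,
    specificity = spec, mcc = mcc, balanced_accuracy = bal)
}

# Trapezoidal one-vs-rest ROC AUC for one class's scores.
ovr_auc <- function(score, is_pos) {
  if (all(is_pos) || !any(is_pos)) return(NA_real_)
  ord <- order(score, decreasing = TRUE)
  pos <- is_pos[ord]
  tpr <- c(0, cumsum(pos) / sum(pos))
  fpr <- c(0, cumsum(!pos) / sum(!pos))
  # Collapse tied scores: keep the origin plus the cumulative point after
  # the last member of each tie group.
  s_ord <- score[ord]
  keep <- c(TRUE, !duplicated(s_ord, fromLast = TRUE))
  tpr <- tpr[keep]; fpr <- fpr[keep]
  sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
}

#' Confusion matrix and full metric report
#'
#' Builds the C x C confusion matrix (rows = truth, columns = prediction)
#' and computes accuracy, precision, recall (sensitivity), F1, specificity,
#' MCC, balanced accuracy, Cohen's kappa and (when scores are supplied)
#' ROC AUC. For two classes the scalars are the standard TP/TN/FP/FN
#' formulas with the larger label as the positive class; for more classes
#' they are macro-averaged one-vs-rest. AUC is always macro one-vs-rest by
#' the trapezoidal rule. Kappa is `(Po - Pe) / (1 - Pe)` from the full
#' confusion matrix.
#'
#' @param y_true True labels.
#' @param y_pred Predicted labels; every predicted class must occur in the
#'   label universe.
#' @param scores Optional score matrix (n x C, columns in class order; a
#'   vector is accepted for two classes as the positive-class score).
#' @param classes Optional explicit class universe.
#' @return An object of class `metrics_report`.
#' @export
confusion_metrics <- function(y_true, y_pred, scores = NULL,
                              classes = NULL) {
  if (length(y_true) != length(y_pred))
    stop_bad_arg("y_true and y_pred must have equal length")
  if (is.null(classes)) classes <- sort(unique(y_true))
  if (!all(y_pred %in% classes))
    stop_bad_arg("y_pred contains classes absent from the label universe")
  tf <- factor(y_true, levels = classes)
  pf <- factor(y_pred, levels = classes)
  cm <- table(truth = tf, prediction = pf)
  cm <- matrix(as.numeric(cm), nrow(cm), ncol(cm),
               dimnames = dimnames(cm))
  n <- sum(cm)
  C <- length(classes)
  counts <- ovr_counts(cm)
  per_class <- as.data.frame(t(apply(counts, 1L, function(r)
    binary_metric_row(r[["tp"]], r[["tn"]], r[["fp"]], r[["fn"]]))))
  per_class$class <- classes
  per_class <- per_class[, c("class", setdiff(names(per_class), "class"))]

  overall_acc <- sum(diag(cm)) / n
  po <- overall_acc
  pe <- sum(rowSums(cm) * colSums(cm)) / n^2
  kappa <- if (pe == 1) 0 else (po - pe) / (1 - pe)

  auc_per_class <- rep(NA_real_, C)
  if (!is.null(scores)) {
    if (is.null(dim(scores))) {
      if (C != 2L)
        stop_bad_arg("vector `scores` only supported for two classes")
      scores <- cbind(1 - scores, scores)
    }
    if (nrow(scores) != length(y_true) || ncol(scores) != C)
      stop_bad_arg("`scores` must be %d x %d", length(y_true), C)
    for (c in seq_len(C))
      auc_per_class[c] <- ovr_auc(scores[, c], tf == classes[c])
  }
  per_class$auc <- auc_per_class

  if (C == 2L) {
    r <- binary_metric_row(counts[2L, "tp"], counts[2L, "tn"],
                           counts[2L, "fp"], counts[2L, "fn"])
    scalars <- as.list(r)
    scalars$auc <- auc_per_class[2L]
  } else {
    scalars <- as.list(colMeans(per_class[, c("accuracy", "precision",
                                              "recall", "f1", "specificity",
                                              "mcc", "balanced_accuracy")]))
    scalars$auc <- if (all(is.na(auc_per_class))) NA_real_
                   else mean(auc_per_class, na.rm = TRUE)
  }
  structure(list(confusion = cm,
                 accuracy = overall_acc,
                 precision = scalars$precision,
                 recall = scalars$recall,
                 sensitivity = scalars$recall,
                 f1 = scalars$f1,
                 auc = scalars$auc,
                 specificity = scalars$specificity,
                 mcc = scalars$mcc,
                 balanced_accuracy = scalars$balanced_accuracy,
                 kappa = kappa,
                 per_class = per_class,
                 n = n, classes = classes),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, digits = 4, ...) {
  cat(sprintf("Metrics over %d samples, %d classes\n", x$n,
              length(x$classes)))
  s <- c(accuracy = x$accuracy, precision = x$precision, recall = x$recall,
         f1 = x$f1, auc = x$auc, specificity = x$specificity, mcc = x$mcc,
         balanced_accuracy = x$balanced_accuracy, kappa = x$kappa)
  print(round(s, digits))
  invisible(x)
}

#' McNemar's test for two classifiers on the same samples
#'
#' Counts discordant pairs `b` (A right, B wrong) and `c` (A wrong,
#' B right). For `b + c < 25` the exact two-sided binomial p-value
#' `min(1, 2 P(Bin(b+c, 1/2) >= max(b, c)))` is used; otherwise the
#' continuity-corrected chi-square `(|b - c| - 1)^2 / (b + c)` on 1 df.
#' When `b + c = 0` the test is degenerate and `p = 1` is reported with a
#' flag.
#'
#' @param y_true True labels.
#' @param pred_a,pred_b Predictions of the two classifiers.
#' @return List with `b`, `c`, `statistic`, `p_value`, `method`,
#'   `degenerate`.
#' @export
mcnemar_test <- function(y_true, pred_a, pred_b) {
  if (length(y_true) != length(pred_a) ||
      length(y_true) != length(pred_b))
    stop_bad_arg("all three label vectors must have equal length")
  a_ok <- pred_a == y_true
  b_ok <- pred_b == y_true
  b <- sum(a_ok & !b_ok)
  c <- sum(!a_ok & b_ok)
  if (b + c == 0)
    return(list(b = b, c = c, statistic = NA_real_, p_value = 1,
                method = "degenerate (no discordant pairs)",
                degenerate = TRUE))
  if (b + c < 25) {
    m <- max(b, c)
    p <- min(1, 2 * stats::pbinom(m - 1, b + c, 0.5,
                                  lower.tail = FALSE))
    list(b = b, c = c, statistic = NA_real_, p_value = p,
         method = "exact binomial", degenerate = FALSE)
  } else {
    stat <- (abs(b - c) - 1)^2 / (b + c)
    p <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
    list(b = b, c = c, statistic = stat, p_value = p,
         method = "continuity-corrected chi-square", degenerate = FALSE)
  }
}

#' Paired t-test on per-fold metrics
#'
#' Classical paired t on the fold-wise differences with a 95% confidence
#' interval for the mean difference. Zero-variance differences are flagged
#' degenerate (no p-value).
#'
#' @param fold_metrics_a,fold_metrics_b Equal-length paired metric vectors
#'   (k >= 2 folds).
#' @param conf_level Confidence level of the interval.
#' @return List with `t`, `p_value`, `ci`, `mean_diff`, `degenerate`.
#' @export
paired_ttest <- function(fold_metrics_a, fold_metrics_b,
                         conf_level = 0.95) {
  a <- as.numeric(fold_metrics_a); b <- as.numeric(fold_metrics_b)
  if (length(a) != length(b)) stop_bad_arg("paired vectors differ in length")
  if (length(a) < 2L) stop_bad_arg("need k >= 2 folds")
  d <- a - b
  if (stats::sd(d) == 0)
    return(list(t = NA_real_, p_value = NA_real_,
                ci = c(mean(d), mean(d)), mean_diff = mean(d),
                degenerate = TRUE))
  tt <- stats::t.test(a, b, paired = TRUE, conf.level = conf_level)
  list(t = unname(tt$statistic), p_value = tt$p.value,
       ci = as.numeric(tt$conf.int), mean_diff = mean(d),
       degenerate = FALSE)
}
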