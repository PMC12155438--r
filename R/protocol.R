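# Evaluation protocol: stratified k-fold plans, cross-validation with
# SMOTE applied strictly inside the training portion of each fold, a hard
# leakage guard, and fold-wise aggregation with t-based confidence
# intervals.

#' Stratified k-fold plan
#'
#' Partitions sample indices into k folds preserving the class distribution
#' (per-fold class counts within one sample of n_c / k for every class);
#' overall fold sizes differ by at most one when the per-class remainders
#' allow it. Deterministic under `seed`.
#'
#' @param labels Class labels.
#' @param k Number of folds (every class must have at least k members).
#' @param seed Integer seed.
#' @return An object of class `fold_plan`: list with `folds` (list of index
#'   vectors partitioning `seq_along(labels)`), `k`, `seed`, `stratified`.
#' @export
make_folds <- function(labels, k = 5L, seed = 1L) {
  check_number(k, "k", lower = 2, integer = TRUE)
  n <- length(labels)
  counts <- table(labels)
  small <- names(counts)[counts < k]
  if (length(small))
    stop_bad_arg("class '%s' has %d sample(s), fewer than k = %d",
                 small[1L], counts[[small[1L]]], k)
  with_seed(seed, {
    assign_fold <- integer(n)
    off <- 0L
    for (cl in names(counts)) {
      idx <- which(labels == cl)
      idx <- idx[sample.int(length(idx))]
      fl <- ((seq_along(idx) - 1L + off) %% k) + 1L
      assign_fold[idx] <- fl
      off <- (off + length(idx)) %% k
    }
    folds <- split(seq_len(n), assign_fold)
    names(folds) <- NULL
    structure(list(folds = folds, k = as.integer(k),
                   seed = as.integer(seed), stratified = TRUE),
              class = "fold_plan")
  })
}

# Hard leakage guard. `train_origin_ids` are the global sample ids every
# (original or SMOTE-interpolated) training row traces back to; `NA` marks a
# synthetic row whose provenance was lost, which is itself a violation.
# The evaluation fold must consist of original ids only and share nothing
# with the training provenance.
assert_no_leakage <- function(eval_ids, train_origin_ids) {
  if (any(is.na(eval_ids)))
    stop("leakage detected: a synthetic sample reached the evaluation fold",
         call. = FALSE)
  if (length(intersect(eval_ids, train_origin_ids[!is.na(train_origin_ids)])))
    stop("leakage detected: evaluation fold overlaps training provenance",
         call. = FALSE)
  invisible(TRUE)
}

# Aggregate fold-wise scalars: mean, SD and t-based CI.
aggregate_folds <- function(reports, conf_level = 0.95) {
  metrics <- c("accuracy", "precision", "recall", "f1", "auc",
               "specificity", "mcc", "balanced_accuracy", "kappa")
  k <- length(reports)
  rows <- lapply(metrics, function(m) {
    v <- vapply(reports, function(r) r[[m]], numeric(1))
    mu <- mean(v, na.rm = TRUE)
    s <- stats::sd(v, na.rm = TRUE)
    half <- if (k > 1 && is.finite(s))
      stats::qt(1 - (1 - conf_level) / 2, df = k - 1) * s / sqrt(k)
    else NA_real_
    data.frame(metric = m, mean = mu, sd = s, ci_lo = mu - half,
               ci_hi = mu + half)
  })
  do.call(rbind, rows)
}

#' Leakage-guarded cross-validation
#'
#' For every fold: SMOTE is applied to the training portion only, the
#' supplied pipeline (e.g. feature selection + classifier) is fit on the
#' augmented training rows, and the untouched held-out fold is scored. A
#' hard guard verifies on every fold that no synthetic sample and no
#' training row reaches the evaluation set. Fold metrics are aggregated as
#' mean, SD and a t-based 95% confidence interval.
#'
#' @param pipeline_fn `function(x_train, y_train)` returning a predictor:
#'   either `function(x_new)` or an object whose [predict] method accepts a
#'   matrix; the predictor returns a label vector or
#'   `list(class = , prob = )`.
#' @param x Feature matrix.
#' @param y Labels.
#' @param plan A [make_folds()] plan over `seq_along(y)`.
#' @param smote Optional [smote_params()]; `NULL` disables oversampling.
#' @return An object of class `cv_result`: `fold_reports` (per-fold
#'   `metrics_report`), `fold_predictions`, `summary` (aggregated data
#'   frame), `plan` and `leakage_checked = TRUE`.
#' @export
cross_validate <- function(pipeline_fn, x, y, plan, smote = NULL) {
  if (!inherits(plan, "fold_plan")) stop_bad_arg("`plan` must be a fold_plan")
  if (!is.matrix(x)) x <- as.matrix(x)
  if (nrow(x) != length(y)) stop_bad_arg("`x` rows must match `y`")
  classes <- sort(unique(y))
  fold_reports <- vector("list", plan$k)
  fold_preds <- vector("list", plan$k)
  for (f in seq_len(plan$k)) {
    te <- plan$folds[[f]]
    tr <- setdiff(seq_along(y), te)
    x_tr <- x[tr, , drop = FALSE]; y_tr <- y[tr]
    train_origin <- tr
    if (!is.null(smote)) {
      sm <- smote_oversample(x_tr, y_tr, smote)
      x_tr <- sm$x; y_tr <- sm$y
      # Map each training row (original or synthetic base) to its global id;
      # synthetic rows keep NA provenance and must never be scored.
      train_origin <- ifelse(is.na(sm$origin), NA_integer_, tr[sm$origin])
    }
    assert_no_leakage(te, train_origin)
    fitted <- pipeline_fn(x_tr, y_tr)
    pred <- if (is.function(fitted)) fitted(x[te, , drop = FALSE])
            else predict(fitted, x[te, , drop = FALSE])
    if (!is.list(pred)) pred <- list(class = pred, prob = NULL)
    fold_reports[[f]] <- confusion_metrics(y[te], pred$class,
                                           scores = pred$prob,
                                           classes = classes)
    fold_preds[[f]] <- list(ids = te, class = pred$class,
                            prob = pred$prob)
  }
  structure(list(fold_reports = fold_reports,
                 fold_predictions = fold_preds,
                 summary = aggregate_folds(fold_reports),
                 plan = plan, leakage_checked = TRUE),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, digits = 4, ...) {
  cat(sprintf("Stratified %d-fold cross-validation (leakage guard: %s)\n",
              x$plan$k, if (x$leakage_checked) "passed" else "NOT CHECKED"))
  s <- x$summary
  s[, -1L] <- round(s[, -1L], digits)
  print(s, row.names = FALSE)
  invisible(x)
}

#' Extract a fold-wise metric vector from a `cv_result`
#'
#' @param cv A `cv_result`.
#' @param metric Metric name (e.g. `"accuracy"`).
#' @return Numeric vector with one value per fold.
#' @export
fold_metric <- function(cv, metric = "accuracy") {
  vapply(cv$fold_reports, function(r) r[[metric]], numeric(1))
}
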