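# Gradient-boosted classification back end plus the pluggable alternatives
# (L1-logistic, random forest) used by the ablation harness.

#' Gradient-boosting configuration
#'
#' Defaults are the tuned mammography settings: learning rate 0.03, depth 8,
#' 150 trees, min child weight 2, subsample 0.7, column subsample 0.8, L2
#' regularization lambda 15, multi-class log loss.
#'
#' @param learning_rate Shrinkage eta (> 0).
#' @param max_depth Maximum tree depth (>= 1).
#' @param n_trees Number of boosting rounds K (>= 1).
#' @param min_child_weight Minimum child weight.
#' @param subsample Row subsample ratio.
#' @param colsample Column subsample ratio per tree.
#' @param reg_lambda L2 regularization lambda.
#' @param objective Objective; `"multi:softprob"` (multi-class log loss).
#' @param early_stopping Early-stopping rounds when a validation set is
#'   passed to [fit_classifier()] (NULL disables).
#' @param seed Seed for the (single-threaded, deterministic) booster.
#' @return An object of class `booster_config`.
#' @export
booster_config <- function(learning_rate = 0.03, max_depth = 8L,
                           n_trees = 150L, min_child_weight = 2,
                           subsample = 0.7, colsample = 0.8,
                           reg_lambda = 15, objective = "multi:softprob",
                           early_stopping = NULL, seed = 1L) {
  check_number(learning_rate, "learning_rate", lower = 0,
               strict_lower = TRUE)
  check_number(max_depth, "max_depth", lower = 1, integer = TRUE)
  check_number(n_trees, "n_trees", lower = 1, integer = TRUE)
  check_number(min_child_weight, "min_child_weight", lower = 0)
  check_number(subsample, "subsample", lower = 0, upper = 1,
               strict_lower = TRUE)
  check_number(colsample, "colsample", lower = 0, upper = 1,
               strict_lower = TRUE)
  check_number(reg_lambda, "reg_lambda", lower = 0)
  structure(list(learning_rate = learning_rate,
                 max_depth = as.integer(max_depth),
                 n_trees = as.integer(n_trees),
                 min_child_weight = min_child_weight,
                 subsample = subsample, colsample = colsample,
                 reg_lambda = reg_lambda, objective = objective,
                 early_stopping = early_stopping,
                 seed = as.integer(seed)),
            class = "booster_config")
}

#' Fit the gradient-boosted classifier
#'
#' Trains an xgboost ensemble configured by [booster_config()]
#' (single-threaded so runs are deterministic under the seed). When a
#' validation set and `early_stopping` are given, training halts once the
#' validation loss has not improved for that many rounds.
#'
#' @param x Numeric feature matrix.
#' @param y Class labels (>= 2 distinct values).
#' @param cfg A [booster_config()].
#' @param x_val,y_val Optional validation set for early stopping.
#' @return An object of class `mammo_booster` with a [predict] method
#'   returning `list(class, prob)`.
#' @export
fit_classifier <- function(x, y, cfg = booster_config(), x_val = NULL,
                           y_val = NULL) {
  if (!inherits(cfg, "booster_config"))
    stop_bad_arg("`cfg` must be a booster_config")
  if (!is.matrix(x)) x <- as.matrix(x)
  yf <- factor(y)
  classes <- levels(yf)
  if (length(classes) < 2L)
    stop_bad_arg("labels are degenerate: %d class(es)", length(classes))
  yi <- as.integer(yf) - 1L
  params <- list(objective = cfg$objective,
                 num_class = length(classes),
                 eta = cfg$learning_rate,
                 max_depth = cfg$max_depth,
                 min_child_weight = cfg$min_child_weight,
                 subsample = cfg$subsample,
                 colsample_bytree = cfg$colsample,
                 lambda = cfg$reg_lambda,
                 nthread = 1L,
                 seed = cfg$seed)
  dtrain <- xgboost::xgb.DMatrix(x, label = yi)
  evals <- list(train = dtrain)
  esr <- NULL
  if (!is.null(x_val) && !is.null(cfg$early_stopping)) {
    dval <- xgboost::xgb.DMatrix(as.matrix(x_val),
                                 label = as.integer(factor(y_val,
                                                           levels = classes)) - 1L)
    evals <- list(train = dtrain, val = dval)
    esr <- cfg$early_stopping
  }
  bst <- xgboost::xgb.train(params = params, data = dtrain,
                            nrounds = cfg$n_trees, evals = evals,
                            early_stopping_rounds = esr, verbose = 0)
  structure(list(booster = bst, classes = classes, n_features = ncol(x)),
            class = "mammo_booster")
}

#' @export
predict.mammo_booster <- function(object, x, ...) {
  if (!is.matrix(x)) x <- as.matrix(x)
  p <- predict(object$booster, xgboost::xgb.DMatrix(x))
  if (is.null(dim(p)))
    p <- matrix(p, nrow = nrow(x), byrow = TRUE)
  colnames(p) <- object$classes
  cls <- object$classes[max.col(p)]
  if (!anyNA(suppressWarnings(as.numeric(object$classes))))
    cls <- as.numeric(cls)
  list(class = cls, prob = p)
}

# --- pluggable alternatives for the ablation harness -----------------------

# L1-penalized multinomial logistic selection: returns the indices of
# features with any nonzero coefficient at a cross-validated lambda.
l1_select <- function(x, y, seed = 1L, nfolds = 3L) {
  y <- factor(y)
  fam <- if (nlevels(y) == 2L) "binomial" else "multinomial"
  cvfit <- with_seed(seed,
    glmnet::cv.glmnet(x, y, family = fam, alpha = 1, nfolds = nfolds,
                      type.measure = "class"))
  co <- glmnet::coef.glmnet(cvfit, s = "lambda.min")
  nz <- if (is.list(co)) {
    Reduce(union, lapply(co, function(m) which(as.vector(m[-1L, 1L]) != 0)))
  } else which(as.vector(co[-1L, 1L]) != 0)
  nz <- sort(nz)
  if (!length(nz)) nz <- order(-apply(x, 2L, stats::var))[1L]
  nz
}

# Ridge multinomial logistic classifier; returns a predict closure.
fit_logistic_clf <- function(x, y, seed = 1L) {
  yf <- factor(y)
  classes <- levels(yf)
  fam <- if (nlevels(yf) == 2L) "binomial" else "multinomial"
  fit <- with_seed(seed,
    glmnet::glmnet(x, yf, family = fam, alpha = 0, lambda = 0.01))
  function(newx) {
    pr <- predict(fit, as.matrix(newx), type = "response")
    prob <- if (length(dim(pr)) == 3L) pr[, , 1L]
            else cbind(1 - pr[, 1L], pr[, 1L])
    colnames(prob) <- classes
    cls <- classes[max.col(prob)]
    if (!anyNA(suppressWarnings(as.numeric(classes))))
      cls <- as.numeric(cls)
    list(class = cls, prob = prob)
  }
}

# Random-forest classifier; returns a predict closure.
fit_forest_clf <- function(x, y, seed = 1L, num_trees = 300L) {
  df <- data.frame(x)
  df$.y <- factor(y)
  fit <- ranger::ranger(dependent.variable.name = ".y", data = df,
                        num.trees = num_trees, probability = TRUE,
                        seed = seed, num.threads = 1L)
  classes <- levels(df$.y)
  function(newx) {
    prob <- predict(fit, data.frame(as.matrix(newx)),
                    num.threads = 1L)$predictions
    colnames(prob) <- classes
    cls <- classes[max.col(prob)]
    if (!anyNA(suppressWarnings(as.numeric(classes))))
      cls <- as.numeric(cls)
    list(class = cls, prob = prob)
  }
}
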