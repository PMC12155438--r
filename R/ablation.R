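# Ablation harness: compares fusion (GAFM vs concatenation), selection
# (HHO vs L1 vs none) and classifier (boosted vs logistic vs forest)
# variants on shared folds and seeds, plus the SMOTE-ordering experiment.

#' Define an ablation variant
#'
#' @param fusion `"gafm"` or `"concat"`.
#' @param selection `"hho"`, `"l1"` or `"none"`.
#' @param classifier `"boosted"`, `"logistic"` or `"forest"`.
#' @return A named list of class `ablation_variant`.
#' @export
ablation_variant <- function(fusion = c("gafm", "concat"),
                             selection = c("hho", "l1", "none"),
                             classifier = c("boosted", "logistic",
                                            "forest")) {
  v <- list(fusion = match.arg(fusion), selection = match.arg(selection),
            classifier = match.arg(classifier))
  class(v) <- "ablation_variant"
  v
}

variant_label <- function(v)
  sprintf("%s+%s+%s", v$fusion, v$selection, v$classifier)

# Build the per-fold pipeline function for one variant.
variant_pipeline_fn <- function(v, config, seed) {
  function(x_tr, y_tr) {
    sel <- switch(v$selection,
      hho = run_hho(x_tr, y_tr, cfg_hho(config, seed))$selected,
      l1 = l1_select(x_tr, y_tr, seed = seed),
      none = seq_len(ncol(x_tr)))
    xs <- x_tr[, sel, drop = FALSE]
    pred <- switch(v$classifier,
      boosted = {
        m <- fit_classifier(xs, y_tr, cfg_booster(config, seed))
        function(x) predict(m, x)
      },
      logistic = fit_logistic_clf(xs, y_tr, seed = seed),
      forest = fit_forest_clf(xs, y_tr, seed = seed))
    function(x_new) pred(x_new[, sel, drop = FALSE])
  }
}

#' Run the ablation harness
#'
#' Prepares the data and trained feature extractor once, then
#' cross-validates every variant on the same stratified fold plan with the
#' same seeds (fold sharing is recorded as a hash in the result). Each row
#' reports mean +/- SD metrics; paired t-tests compare every variant
#' against the first (reference) variant's fold accuracies.
#'
#' @param config A `pipeline_config`.
#' @param variants List of [ablation_variant()] (>= 2).
#' @param verbose Print progress.
#' @return An object of class `ablation_result`: `table` (one row per
#'   variant), `cv` (per-variant `cv_result`s), `plan_hash`.
#' @export
run_ablation <- function(config = default_pipeline_config("smoke"),
                         variants = list(
                           ablation_variant("gafm", "hho", "boosted"),
                           ablation_variant("concat", "l1", "boosted")),
                         verbose = FALSE) {
  if (length(variants) < 2L) stop_bad_arg("need at least 2 variants")
  validate_pipeline_config(config)
  seed <- config$seed
  if (identical(config$data$source, "synthetic")) {
    spec <- synthetic_image_spec(config$data$n_per_class,
                                 classes = config$data$classes,
                                 image_size = config$data$image_size,
                                 noise_sd = config$data$noise_sd,
                                 salt_prob = config$data$salt_prob,
                                 seed = seed)
    ds <- gen_images(spec)
  } else {
    ds <- read_image_set(config$data$dir)
  }
  proc <- preprocess_all(ds$images, config)
  y <- ds$labels
  bb <- train_backbone(proc, y, cfg_backbone(config),
                       epochs = config$backbone$epochs,
                       lr = config$backbone$lr,
                       batch_size = config$backbone$batch_size,
                       val_frac = config$backbone$val_frac,
                       patience = config$backbone$patience,
                       seed = seed + 11L)
  maps <- extract_features_all(proc, bb)
  gf <- train_gafm(maps, y, fusion_dim = config$gafm$fusion_dim,
                   mode = config$gafm$mode, epochs = config$gafm$epochs,
                   lr = config$gafm$lr, val_frac = config$gafm$val_frac,
                   seed = seed + 23L)
  feats <- list(gafm = gafm_apply(gf, maps),
                concat = do.call(cbind, maps))

  plan <- make_folds(y, k = config$evaluation$k_folds, seed = seed + 5L)
  plan_hash <- sum(vapply(seq_along(plan$folds), function(i)
    sum(plan$folds[[i]] * i), numeric(1)))
  smote_p <- if (config$evaluation$smote_point == "none") NULL
             else smote_params(config$evaluation$smote_k, seed + 41L)

  cvs <- vector("list", length(variants))
  rows <- vector("list", length(variants))
  for (i in seq_along(variants)) {
    v <- variants[[i]]
    if (verbose) message("variant ", variant_label(v))
    cvs[[i]] <- cross_validate(variant_pipeline_fn(v, config, seed + 31L),
                               feats[[v$fusion]], y, plan,
                               smote = smote_p)
    s <- cvs[[i]]$summary
    g <- function(m, col) s[s$metric == m, col]
    rows[[i]] <- data.frame(
      variant = variant_label(v),
      accuracy = g("accuracy", "mean"), accuracy_sd = g("accuracy", "sd"),
      auc = g("auc", "mean"), f1 = g("f1", "mean"),
      mcc = g("mcc", "mean"), kappa = g("kappa", "mean"))
  }
  tab <- do.call(rbind, rows)
  ref_acc <- fold_metric(cvs[[1L]], "accuracy")
  tab$t_vs_ref <- NA_real_; tab$p_vs_ref <- NA_real_
  for (i in seq_along(cvs)[-1L]) {
    tt <- paired_ttest(ref_acc, fold_metric(cvs[[i]], "accuracy"))
    tab$t_vs_ref[i] <- if (isTRUE(tt$degenerate)) NA_real_ else tt$t
    tab$p_vs_ref[i] <- tt$p_value
  }
  structure(list(table = tab, cv = cvs, plan_hash = plan_hash,
                 plan = plan),
            class = "ablation_result")
}

#' @export
print.ablation_result <- function(x, digits = 3, ...) {
  cat("Ablation study (shared folds, mean +/- SD over folds)\n")
  t <- x$table
  t[, -1L] <- round(t[, -1L], digits)
  print(t, row.names = FALSE)
  invisible(x)
}

#' SMOTE-ordering experiment
#'
#' Compares three oversampling protocols on a feature matrix: (a) SMOTE
#' applied to the whole dataset before splitting (the leaky protocol —
#' synthetic points derived from future test rows contaminate training),
#' (b) SMOTE applied inside each training fold on the raw features, and
#' (c) HHO selection first, then SMOTE inside each training fold on the
#' selected features. Settings (b) and (c) run through the leakage-guarded
#' [cross_validate()]; (a) is computed outside it (the guard would —
#' correctly — refuse it) with evaluation restricted to original rows.
#'
#' @param x Feature matrix.
#' @param y Labels.
#' @param config A `pipeline_config` (supplies fold count, SMOTE k, HHO and
#'   booster settings).
#' @return Data frame with one row per protocol: mean accuracy, accuracy
#'   SD, minority-class F1 and MCC.
#' @export
smote_ordering_experiment <- function(x, y,
                                      config = default_pipeline_config("smoke")) {
  seed <- config$seed
  plan <- make_folds(y, k = config$evaluation$k_folds, seed = seed + 5L)
  smote_p <- smote_params(config$evaluation$smote_k, seed + 41L)
  minority <- names(which.min(table(y)))
  min_f1 <- function(rep) {
    pc <- rep$per_class
    pc$f1[as.character(pc$class) == minority]
  }

  # (a) leaky: oversample everything, then cross-validate on the original
  # rows while training folds also contain synthetic points derived from
  # evaluation rows.
  sm_all <- smote_oversample(x, y, smote_p)
  fold_of <- integer(length(y))
  for (f in seq_len(plan$k)) fold_of[plan$folds[[f]]] <- f
  reports_a <- vector("list", plan$k)
  for (f in seq_len(plan$k)) {
    te <- plan$folds[[f]]
    keep <- is.na(sm_all$origin) | !(sm_all$origin %in% te)
    tr_rows <- which(keep & !(seq_len(nrow(sm_all$x)) %in% te))
    m <- fit_classifier(sm_all$x[tr_rows, , drop = FALSE],
                        sm_all$y[tr_rows], cfg_booster(config, seed + 43L))
    pr <- predict(m, x[te, , drop = FALSE])
    reports_a[[f]] <- confusion_metrics(y[te], pr$class, scores = pr$prob,
                                        classes = sort(unique(y)))
  }

  # (b) guarded, raw features.
  fn_raw <- function(x_tr, y_tr) {
    m <- fit_classifier(x_tr, y_tr, cfg_booster(config, seed + 43L))
    function(x_new) predict(m, x_new)
  }
  cv_b <- cross_validate(fn_raw, x, y, plan, smote = smote_p)

  # (c) guarded, selection before SMOTE (SMOTE inside the pipeline).
  fn_sel <- function(x_tr, y_tr) {
    sel <- run_hho(x_tr, y_tr, cfg_hho(config, seed + 31L))$selected
    sm <- smote_oversample(x_tr[, sel, drop = FALSE], y_tr, smote_p)
    m <- fit_classifier(sm$x, sm$y, cfg_booster(config, seed + 43L))
    function(x_new) predict(m, x_new[, sel, drop = FALSE])
  }
  cv_c <- cross_validate(fn_sel, x, y, plan, smote = NULL)

  summarize <- function(reports, label) {
    acc <- vapply(reports, function(r) r$accuracy, numeric(1))
    data.frame(protocol = label,
               accuracy = mean(acc), accuracy_sd = stats::sd(acc),
               minority_f1 = mean(vapply(reports, min_f1, numeric(1))),
               mcc = mean(vapply(reports, function(r) r$mcc, numeric(1))))
  }
  rbind(summarize(reports_a, "smote_before_split"),
        summarize(cv_b$fold_reports, "smote_after_split_raw"),
        summarize(cv_c$fold_reports, "smote_after_selection"))
}
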