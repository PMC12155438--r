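# End-to-end pipeline: configuration, the top-level fitting function
# (preprocess -> backbone -> GAFM -> HHO -> booster) returning a classed
# model object, and the run orchestrator with artifact/manifest output.

#' Default pipeline configuration
#'
#' A nested configuration covering every stage. The `"desk"` preset mirrors
#' the published hyperparameter tables at desk scale (patch 32, ten
#' multi-axis blocks over two stages, dropout 0.2, AdamW lr 1e-4, batch 8,
#' 150 HHO iterations, booster with eta 0.03 / depth 8 / 150 trees /
#' lambda 15); the `"smoke"` preset shrinks image size, backbone and search
#' budgets so a full run completes in seconds on one CPU.
#'
#' @param preset `"desk"` or `"smoke"`.
#' @param seed Global integer seed; all stage seeds derive from it.
#' @param out_dir Optional output directory for artifacts.
#' @return A nested list of class `pipeline_config`.
#' @export
default_pipeline_config <- function(preset = c("desk", "smoke"), seed = 1L,
                                    out_dir = NULL) {
  preset <- match.arg(preset)
  smoke <- preset == "smoke"
  cfg <- list(
    seed = as.integer(seed),
    out_dir = out_dir,
    data = list(source = "synthetic", dir = NULL,
                n_per_class = if (smoke) 40L else 60L,
                classes = 4L,
                image_size = if (smoke) 64L else 128L,
                noise_sd = 0.02, salt_prob = 0.002),
    preprocess = list(clahe_tiles = 8L, clahe_clip = 2.0,
                      gauss_sigma = 1.0, gauss_radius = 3L,
                      segment = TRUE, mask_radius = 5L,
                      augment_per_image = 0L),
    backbone = list(patch_size = if (smoke) 16L else 32L,
                    embed_dim = if (smoke) 16L else 64L,
                    n_stages = 2L,
                    blocks_per_stage = if (smoke) 1L else 5L,
                    heads = 4L, window = 2L, dropout = 0.2,
                    ffn_mult = 2L,
                    epochs = if (smoke) 3L else 8L,
                    lr = 1e-4, batch_size = 8L,
                    val_frac = 0.2, patience = 10L),
    gafm = list(fusion_dim = if (smoke) 16L else 32L,
                mode = "channel",
                epochs = if (smoke) 80L else 150L,
                lr = 0.01, val_frac = 0),
    hho = list(pop_size = if (smoke) 6L else 10L,
               iterations = if (smoke) 10L else 150L,
               binarize_threshold = 0.5, fitness_cv_folds = 3L,
               fitness_nrounds = if (smoke) 20L else 30L,
               fitness_depth = 3L, fitness_eta = 0.3),
    classifier = list(learning_rate = 0.03, max_depth = 8L,
                      n_trees = 150L, min_child_weight = 2,
                      subsample = 0.7, colsample = 0.8, reg_lambda = 15,
                      early_stopping = NULL),
    evaluation = list(k_folds = 5L, test_frac = 0.2, smote_k = 5L,
                      smote_point = "after_selection"))
  class(cfg) <- c("pipeline_config", "list")
  cfg
}

#' Load a pipeline configuration from YAML, merged over the defaults
#'
#' @param path YAML file with any subset of the configuration blocks.
#' @param preset Preset supplying the unspecified values.
#' @return A `pipeline_config`.
#' @export
load_pipeline_config <- function(path, preset = "desk") {
  user <- yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  cfg <- utils::modifyList(default_pipeline_config(preset), user)
  class(cfg) <- c("pipeline_config", "list")
  validate_pipeline_config(cfg)
  cfg
}

#' Validate a pipeline configuration
#'
#' Checks types/ranges of every block before a run starts.
#'
#' @param cfg A `pipeline_config`.
#' @return Invisibly `cfg`; errors on the first violation.
#' @export
validate_pipeline_config <- function(cfg) {
  check_number(cfg$seed, "seed", integer = TRUE)
  check_number(cfg$data$image_size, "data$image_size", lower = 32,
               integer = TRUE)
  check_number(cfg$data$classes, "data$classes", lower = 2, integer = TRUE)
  clahe_params(cfg$preprocess$clahe_tiles, cfg$preprocess$clahe_clip)
  gauss_params(cfg$preprocess$gauss_sigma, cfg$preprocess$gauss_radius)
  bb <- cfg$backbone
  backbone_config(bb$patch_size, bb$embed_dim, bb$n_stages,
                  bb$blocks_per_stage, bb$heads, bb$window, bb$dropout,
                  bb$ffn_mult)
  if (cfg$data$image_size %% bb$patch_size != 0L)
    stop_bad_arg("image_size must be divisible by backbone$patch_size")
  hho_config(cfg$hho$pop_size, cfg$hho$iterations, cfg$seed,
             cfg$hho$binarize_threshold, cfg$hho$fitness_cv_folds)
  booster_config(cfg$classifier$learning_rate, cfg$classifier$max_depth,
                 cfg$classifier$n_trees, cfg$classifier$min_child_weight,
                 cfg$classifier$subsample, cfg$classifier$colsample,
                 cfg$classifier$reg_lambda)
  check_number(cfg$evaluation$k_folds, "evaluation$k_folds", lower = 2,
               integer = TRUE)
  if (!cfg$evaluation$smote_point %in%
      c("none", "before_split", "after_split_raw", "after_selection"))
    stop_bad_arg("unknown evaluation$smote_point '%s'",
                 cfg$evaluation$smote_point)
  invisible(cfg)
}

cfg_backbone <- function(cfg) {
  bb <- cfg$backbone
  backbone_config(bb$patch_size, bb$embed_dim, bb$n_stages,
                  bb$blocks_per_stage, bb$heads, bb$window, bb$dropout,
                  bb$ffn_mult)
}

cfg_hho <- function(cfg, seed) {
  h <- cfg$hho
  hho_config(h$pop_size, h$iterations, seed, h$binarize_threshold,
             h$fitness_cv_folds, fitness_nrounds = h$fitness_nrounds,
             fitness_depth = h$fitness_depth, fitness_eta = h$fitness_eta)
}

cfg_booster <- function(cfg, seed) {
  cl <- cfg$classifier
  booster_config(cl$learning_rate, cl$max_depth, cl$n_trees,
                 cl$min_child_weight, cl$subsample, cl$colsample,
                 cl$reg_lambda, early_stopping = cl$early_stopping,
                 seed = seed)
}

preprocess_all <- function(images, cfg) {
  cp <- clahe_params(cfg$preprocess$clahe_tiles, cfg$preprocess$clahe_clip)
  gp <- gauss_params(cfg$preprocess$gauss_sigma,
                     cfg$preprocess$gauss_radius)
  lapply(images, function(im)
    preprocess_image(im, cp, gp, segment = cfg$preprocess$segment,
                     mask_radius = cfg$preprocess$mask_radius)$final)
}

extract_features_all <- function(images, backbone) {
  fms <- lapply(images, extract_multiscale, model = backbone)
  stack_feature_maps(fms)
}

#' Fit the full classification pipeline
#'
#' Runs the complete training chain on labeled images: preprocessing
#' (normalize, CLAHE, Gaussian filter, Otsu segmentation), optional seeded
#' augmentation, from-scratch training of the miniature multi-axis
#' transformer, GAFM fusion training, binary HHO feature selection on the
#' fused features, SMOTE class balancing (at the configured insertion
#' point) and gradient-boosted classification.
#'
#' @param images List of grayscale matrices.
#' @param labels Integer class labels.
#' @param config A `pipeline_config` (see [default_pipeline_config()]).
#' @param verbose Print stage progress.
#' @return An object of class `mammo_model` with [predict], [print],
#'   [summary] and [plot] methods.
#' @export
mammo_train <- function(images, labels, config = default_pipeline_config(),
                        verbose = FALSE) {
  validate_pipeline_config(config)
  labels <- as.integer(labels)
  seed <- config$seed
  say <- function(...) if (verbose) message(sprintf(...))

  say("preprocessing %d images", length(images))
  proc <- preprocess_all(images, config)
  aug_n <- config$preprocess$augment_per_image
  if (aug_n > 0) {
    extra <- list(); extra_y <- integer(0)
    for (a in seq_len(aug_n)) {
      for (i in seq_along(proc)) {
        extra[[length(extra) + 1L]] <-
          augment(proc[[i]], seed = seed + 1000L * a + i)
        extra_y <- c(extra_y, labels[i])
      }
    }
    proc <- c(proc, lapply(extra, function(m) { attr(m, "draws") <- NULL; m }))
    labels <- c(labels, extra_y)
  }

  say("training backbone")
  bb <- train_backbone(proc, labels, cfg_backbone(config),
                       epochs = config$backbone$epochs,
                       lr = config$backbone$lr,
                       batch_size = config$backbone$batch_size,
                       val_frac = config$backbone$val_frac,
                       patience = config$backbone$patience,
                       seed = seed + 11L)

  say("extracting multi-scale features")
  maps <- extract_features_all(proc, bb)

  say("training GAFM")
  gf <- train_gafm(maps, labels, fusion_dim = config$gafm$fusion_dim,
                   mode = config$gafm$mode, epochs = config$gafm$epochs,
                   lr = config$gafm$lr, val_frac = config$gafm$val_frac,
                   seed = seed + 23L)
  fused <- gafm_apply(gf, maps)

  say("HHO feature selection")
  hho_res <- run_hho(fused, labels, cfg_hho(config, seed + 31L))
  x_sel <- fused[, hho_res$selected, drop = FALSE]

  x_fit <- x_sel; y_fit <- labels
  if (config$evaluation$smote_point != "none") {
    sm <- smote_oversample(x_sel, labels,
                           smote_params(config$evaluation$smote_k,
                                        seed + 41L))
    x_fit <- sm$x; y_fit <- sm$y
  }

  say("fitting gradient-boosted classifier")
  booster <- fit_classifier(x_fit, y_fit, cfg_booster(config, seed + 43L))

  structure(list(config = config, backbone = bb, gafm = gf,
                 hho = hho_res, booster = booster,
                 classes = sort(unique(labels)),
                 n_train = length(images)),
            class = "mammo_model")
}

#' Predict classes for new images
#'
#' @param object A `mammo_model`.
#' @param images List of grayscale matrices (same size as training images).
#' @param ... Unused.
#' @return List with `class` (predicted labels) and `prob` (probability
#'   matrix).
#' @export
predict.mammo_model <- function(object, images, ...) {
  proc <- preprocess_all(images, object$config)
  maps <- extract_features_all(proc, object$backbone)
  fused <- gafm_apply(object$gafm, maps)
  x_sel <- fused[, object$hho$selected, drop = FALSE]
  predict(object$booster, x_sel)
}

#' @export
print.mammo_model <- function(x, ...) {
  cat("Mammography classification pipeline\n")
  cat(sprintf("  classes: %s; trained on %d images\n",
              paste(x$classes, collapse = ", "), x$n_train))
  cat(sprintf("  backbone: %d stage(s), dims %s\n",
              x$backbone$cfg$n_stages,
              paste(x$backbone$dims, collapse = "/")))
  cat(sprintf("  GAFM fusion dim %d; HHO kept %d/%d features (fitness %.3f)\n",
              x$gafm$params$fusion_dim, length(x$hho$selected),
              length(x$hho$best_mask), x$hho$best_fitness))
  invisible(x)
}

#' @export
summary.mammo_model <- function(object, ...) {
  print(object)
  cat("  mean |gate| per scale:",
      paste(sprintf("%.3f", object$gafm$gate_summary), collapse = ", "),
      "\n")
  cat(sprintf("  backbone epochs run: %d (final train loss %.4f)\n",
              nrow(object$backbone$history),
              utils::tail(object$backbone$history$train_loss, 1)))
  invisible(object)
}

#' @export
plot.mammo_model <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  h <- x$backbone$history
  graphics::plot(h$epoch, h$train_loss, type = "b", xlab = "epoch",
                 ylab = "cross-entropy", main = "Backbone training")
  if (any(is.finite(h$val_loss)))
    graphics::lines(h$epoch, h$val_loss, type = "b", lty = 2)
  graphics::barplot(x$gafm$gate_summary,
                    names.arg = paste0("scale ", seq_along(x$gafm$gate_summary)),
                    ylab = "mean |gate|", main = "GAFM gates")
  invisible(x)
}

# Stratified train/test split: fold 1 of a k = 1/test_frac plan is the test
# set.
split_test <- function(labels, test_frac, seed) {
  k <- max(2L, round(1 / test_frac))
  plan <- make_folds(labels, k = k, seed = seed)
  te <- plan$folds[[1L]]
  list(train = setdiff(seq_along(labels), te), test = te)
}

#' Run the full pipeline end to end
#'
#' Generates (or reads) the image set, holds out a stratified test split,
#' trains the feature extractor and fusion on the training pool, runs the
#' leakage-guarded cross-validation protocol (per-fold HHO selection +
#' SMOTE on the training portion + booster), fits the final model, scores
#' the held-out test set and writes all artifacts plus a manifest. Fully
#' reproducible under `config$seed`.
#'
#' @param config A `pipeline_config`.
#' @param verbose Print stage progress.
#' @return An object of class `mammo_run`: `model`, `cv` (a `cv_result`),
#'   `test_report` (a `metrics_report`), `manifest`, `timings`.
#' @export
run_pipeline <- function(config = default_pipeline_config("smoke"),
                         verbose = FALSE) {
  validate_pipeline_config(config)
  seed <- config$seed
  t_start <- proc.time()[["elapsed"]]
  timings <- c()
  tic <- function() proc.time()[["elapsed"]]
  stage_time <- function(nm, t0) timings <<- c(timings,
                                               stats::setNames(tic() - t0, nm))

  t0 <- tic()
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
  stage_time("data", t0)

  sp <- split_test(ds$labels, config$evaluation$test_frac, seed + 3L)
  tr_imgs <- ds$images[sp$train]; tr_y <- ds$labels[sp$train]
  te_imgs <- ds$images[sp$test]; te_y <- ds$labels[sp$test]

  # Feature extractor + fusion trained once on the training pool; the CV
  # protocol below cross-validates selection + classification on its
  # features with SMOTE strictly inside each training fold.
  t0 <- tic()
  proc_tr <- preprocess_all(tr_imgs, config)
  stage_time("preprocess", t0)
  t0 <- tic()
  bb <- train_backbone(proc_tr, tr_y, cfg_backbone(config),
                       epochs = config$backbone$epochs,
                       lr = config$backbone$lr,
                       batch_size = config$backbone$batch_size,
                       val_frac = config$backbone$val_frac,
                       patience = config$backbone$patience,
                       seed = seed + 11L)
  stage_time("backbone", t0)
  t0 <- tic()
  maps_tr <- extract_features_all(proc_tr, bb)
  gf <- train_gafm(maps_tr, tr_y, fusion_dim = config$gafm$fusion_dim,
                   mode = config$gafm$mode, epochs = config$gafm$epochs,
                   lr = config$gafm$lr, val_frac = config$gafm$val_frac,
                   seed = seed + 23L)
  fused_tr <- gafm_apply(gf, maps_tr)
  stage_time("fusion", t0)

  t0 <- tic()
  plan <- make_folds(tr_y, k = config$evaluation$k_folds, seed = seed + 5L)
  smote_p <- if (config$evaluation$smote_point == "none") NULL
             else smote_params(config$evaluation$smote_k, seed + 41L)
  pipeline_fn <- function(x_tr, y_tr) {
    sel <- run_hho(x_tr, y_tr, cfg_hho(config, seed + 31L))$selected
    m <- fit_classifier(x_tr[, sel, drop = FALSE], y_tr,
                        cfg_booster(config, seed + 43L))
    function(x_new) predict(m, x_new[, sel, drop = FALSE])
  }
  cv <- cross_validate(pipeline_fn, fused_tr, tr_y, plan, smote = smote_p)
  stage_time("cross_validation", t0)

  t0 <- tic()
  hho_res <- run_hho(fused_tr, tr_y, cfg_hho(config, seed + 31L))
  x_sel <- fused_tr[, hho_res$selected, drop = FALSE]
  x_fit <- x_sel; y_fit <- tr_y
  if (!is.null(smote_p)) {
    sm <- smote_oversample(x_sel, tr_y, smote_p)
    x_fit <- sm$x; y_fit <- sm$y
  }
  booster <- fit_classifier(x_fit, y_fit, cfg_booster(config, seed + 43L))
  model <- structure(list(config = config, backbone = bb, gafm = gf,
                          hho = hho_res, booster = booster,
                          classes = sort(unique(tr_y)),
                          n_train = length(tr_imgs)),
                     class = "mammo_model")
  stage_time("final_fit", t0)

  t0 <- tic()
  pred_te <- predict(model, te_imgs)
  test_report <- confusion_metrics(te_y, pred_te$class,
                                   scores = pred_te$prob,
                                   classes = sort(unique(ds$labels)))
  stage_time("test_eval", t0)

  manifest <- list(
    package_version = as.character(utils::packageVersion("mammopipe")),
    seed = seed,
    config = unclass(config),
    n_images = length(ds$images),
    n_train = length(tr_imgs), n_test = length(te_imgs),
    selected_features = hho_res$selected,
    total_elapsed_s = tic() - t_start)

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(data.frame(fused_tr, label = tr_y),
                     file.path(config$out_dir, "fused_features.csv"),
                     row.names = FALSE)
    utils::write.csv(data.frame(selected = hho_res$selected),
                     file.path(config$out_dir, "selected_features.csv"),
                     row.names = FALSE)
    utils::write.csv(data.frame(iteration = seq_along(hho_res$trace),
                                best_fitness = hho_res$trace),
                     file.path(config$out_dir, "hho_trace.csv"),
                     row.names = FALSE)
    utils::write.csv(cv$summary,
                     file.path(config$out_dir, "cv_summary.csv"),
                     row.names = FALSE)
    utils::write.csv(as.data.frame(test_report$confusion),
                     file.path(config$out_dir, "test_confusion.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      list(test = test_report[c("accuracy", "precision", "recall", "f1",
                                "auc", "specificity", "mcc",
                                "balanced_accuracy", "kappa")],
           manifest = manifest),
      file.path(config$out_dir, "report.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }

  structure(list(model = model, cv = cv, test_report = test_report,
                 manifest = manifest, timings = timings),
            class = "mammo_run")
}

#' @export
print.mammo_run <- function(x, ...) {
  cat("Pipeline run\n")
  acc <- x$cv$summary[x$cv$summary$metric == "accuracy", ]
  cat(sprintf("  CV accuracy %.3f +/- %.3f; test accuracy %.3f (MCC %.3f)\n",
              acc$mean, acc$sd, x$test_report$accuracy, x$test_report$mcc))
  cat(sprintf("  %d/%d features kept; total %.1fs\n",
              length(x$manifest$selected_features),
              length(x$model$hho$best_mask),
              x$manifest$total_elapsed_s))
  invisible(x)
}
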