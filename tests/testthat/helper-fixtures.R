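# Shared fixtures, built in code and cached per test run.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixture_env[[name]])) .fixture_env[[name]] <- builder()
  .fixture_env[[name]]
}

# A tiny balanced two-class image set with zero noise and a strong
# lesion-brightness gap: the easiest conditions under which the chain must
# demonstrably learn.
tiny_image_set <- function() fixture("tiny_images", function() {
  gen_images(synthetic_image_spec(
    30, classes = 2, image_size = 64, noise_sd = 0,
    lesion_intensity_by_class = c(0.5, 0.95),
    imbalance_ratios = c(1, 1), seed = 7))
})

# A tiny trained backbone on those images (used by several backbone tests).
tiny_backbone <- function() fixture("tiny_backbone", function() {
  d <- tiny_image_set()
  proc <- lapply(d$images, minmax_normalize)
  suppressWarnings(train_backbone(
    proc, d$labels,
    backbone_config(patch_size = 16, embed_dim = 16, n_stages = 2,
                    blocks_per_stage = 1, heads = 4, window = 2,
                    dropout = 0),
    epochs = 5, lr = 1e-3, batch_size = 8, val_frac = 0, seed = 1))
})

# Independent formula oracle for the binary metric suite, written
# separately from the package implementation.
oracle_binary_metrics <- function(tp, tn, fp, fn) {
  prec <- if (tp + fp == 0) 0 else tp / (tp + fp)
  rec <- if (tp + fn == 0) 0 else tp / (tp + fn)
  spec <- if (tn + fp == 0) 0 else tn / (tn + fp)
  den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  list(
    accuracy = (tp + tn) / (tp + tn + fp + fn),
    precision = prec,
    recall = rec,
    f1 = if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec),
    specificity = spec,
    mcc = if (den == 0) 0 else (tp * tn - fp * fn) / den,
    balanced_accuracy = (rec + spec) / 2)
}

# Exhaustive 256-level Otsu oracle: brute-force between-class variance.
oracle_otsu <- function(img) {
  rng <- range(img)
  q <- floor((img - rng[1]) / (rng[2] - rng[1]) * 256)
  q[q > 255] <- 255
  n <- length(q)
  best_t <- NA_integer_; best_v <- -Inf
  for (t in 0:255) {
    lo <- q <= t
    w0 <- sum(lo) / n; w1 <- 1 - w0
    if (w0 == 0 || w1 == 0) v <- 0
    else v <- w0 * w1 * (mean(q[lo]) - mean(q[!lo]))^2
    if (v > best_v + 1e-12) { best_v <- v; best_t <- t }
  }
  list(level = best_t, between_var = best_v)
}
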