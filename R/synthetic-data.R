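# Synthetic mammogram-like images and planted feature matrices.
#
# The generators are the testbed for every downstream stage: images carry a
# bright breast-shaped region on a dark background with small high-intensity
# lesion blobs whose count and peak brightness grow with the class index;
# feature matrices carry an exactly known informative column subset at a
# requested standardized effect size.

#' Specification for synthetic mammogram-like images
#'
#' @param n_per_class Base number of images per class (before imbalance
#'   weighting).
#' @param classes Number of classes (BI-RADS-like grades), default 4.
#' @param image_size Side of the square image in pixels (>= 32).
#' @param lesion_intensity_by_class Per-class mean peak lesion brightness on
#'   the [0, 1] scale; default ramps linearly from 0.55 to 0.95 so lesion
#'   conspicuity is monotone in class index.
#' @param noise_sd Standard deviation of additive Gaussian pixel noise.
#' @param salt_prob Probability that a pixel is replaced by a bright salt
#'   impulse (sparse acquisition artifacts).
#' @param imbalance_ratios Per-class sampling weights, normalized to sum to 1.
#'   Default mimics a screening population: lower grades more frequent.
#' @param seed Integer seed; the generator is bit-reproducible under it.
#'
#' @return An object of class `synthetic_image_spec`.
#' @export
synthetic_image_spec <- function(n_per_class,
                                 classes = 4L,
                                 image_size = 128L,
                                 lesion_intensity_by_class = NULL,
                                 noise_sd = 0.02,
                                 salt_prob = 0.002,
                                 imbalance_ratios = NULL,
                                 seed = 1L) {
  check_number(n_per_class, "n_per_class", lower = 1, integer = TRUE)
  check_number(classes, "classes", lower = 2, integer = TRUE)
  check_number(image_size, "image_size", lower = 32, integer = TRUE)
  check_number(noise_sd, "noise_sd", lower = 0)
  check_number(salt_prob, "salt_prob", lower = 0, upper = 1)
  check_number(seed, "seed", integer = TRUE)
  if (is.null(lesion_intensity_by_class))
    lesion_intensity_by_class <- seq(0.55, 0.95, length.out = classes)
  if (length(lesion_intensity_by_class) != classes)
    stop_bad_arg("`lesion_intensity_by_class` must have one entry per class")
  if (is.null(imbalance_ratios))
    imbalance_ratios <- rev(seq_len(classes)) + 1
  if (length(imbalance_ratios) != classes || any(imbalance_ratios <= 0))
    stop_bad_arg("`imbalance_ratios` must be %d positive weights", classes)
  imbalance_ratios <- imbalance_ratios / sum(imbalance_ratios)
  structure(
    list(n_per_class = as.integer(n_per_class),
         classes = as.integer(classes),
         image_size = as.integer(image_size),
         lesion_intensity_by_class = as.numeric(lesion_intensity_by_class),
         noise_sd = noise_sd,
         salt_prob = salt_prob,
         imbalance_ratios = imbalance_ratios,
         seed = as.integer(seed)),
    class = "synthetic_image_spec")
}

# One image: elliptical breast region + class-dependent Gaussian lesion blobs.
render_synthetic_image <- function(spec, class_idx) {
  s <- spec$image_size
  xy <- seq_len(s)
  gx <- matrix(xy, s, s)                 # column index
  gy <- matrix(xy, s, s, byrow = TRUE)   # row index

  # Breast: bright ellipse anchored to the left edge, mildly jittered.
  cx <- s * stats::runif(1, 0.05, 0.15)
  cy <- s * stats::runif(1, 0.45, 0.55)
  ax <- s * stats::runif(1, 0.55, 0.70)
  ay <- s * stats::runif(1, 0.38, 0.48)
  d2 <- ((gx - cx) / ax)^2 + ((gy - cy) / ay)^2
  base <- 0.05 + 0.40 * pmax(1 - d2, 0)    # smooth falloff toward the skin line
  inside <- d2 <= 1

  # Lesions: count grows with class (class 1 has none), brightness from spec.
  n_lesions <- class_idx - 1L +
    stats::rbinom(1, 1, if (class_idx > 1) 0.5 else 0)
  peak <- spec$lesion_intensity_by_class[class_idx]
  lesion_mask <- matrix(FALSE, s, s)
  if (n_lesions > 0) {
    inside_idx <- which(inside & d2 < 0.6)
    for (i in seq_len(n_lesions)) {
      ctr <- inside_idx[sample.int(length(inside_idx), 1L)]
      lx <- ((ctr - 1L) %/% s) + 1L
      ly <- ((ctr - 1L) %% s) + 1L
      sigma <- s * stats::runif(1, 0.02, 0.04)
      amp <- peak * stats::runif(1, 0.9, 1.1)
      blob <- amp * exp(-(((gx - lx)^2 + (gy - ly)^2) / (2 * sigma^2)))
      base <- pmax(base, blob)
      lesion_mask <- lesion_mask | (blob > amp * exp(-2))
    }
  }

  img <- base
  if (spec$noise_sd > 0)
    img <- img + matrix(stats::rnorm(s * s, 0, spec$noise_sd), s, s)
  if (spec$salt_prob > 0) {
    salt <- stats::runif(s * s) < spec$salt_prob
    img[salt] <- 1
  }
  img <- pmin(pmax(img, 0), 1)
  list(pixels = img, lesion_mask = lesion_mask)
}

#' Generate labeled synthetic mammogram-like images
#'
#' Produces a seeded set of grayscale images. Each image is a dark background
#' with a bright elliptical "breast" region; class `k` carries roughly `k - 1`
#' Gaussian lesion blobs whose peak brightness follows
#' `lesion_intensity_by_class`, so lesion load is monotone in the class index
#' and a simple brightness rule is already above chance. Gaussian noise plus
#' sparse salt impulses make denoising measurable. Class frequencies follow
#' `imbalance_ratios`.
#'
#' @param spec A [synthetic_image_spec()].
#' @return A list with `images` (list of matrices in [0, 1]), `labels`
#'   (integer classes 1..classes), and `lesion_masks` (list of logical
#'   matrices marking planted lesion support).
#' @export
gen_images <- function(spec) {
  if (!inherits(spec, "synthetic_image_spec"))
    stop_bad_arg("`spec` must be a synthetic_image_spec")
  with_seed(spec$seed, {
    total <- spec$n_per_class * spec$classes
    counts <- pmax(1L, round(total * spec$imbalance_ratios))
    labels <- rep(seq_len(spec$classes), times = counts)
    images <- vector("list", length(labels))
    masks <- vector("list", length(labels))
    for (i in seq_along(labels)) {
      r <- render_synthetic_image(spec, labels[i])
      images[[i]] <- r$pixels
      masks[[i]] <- r$lesion_mask
    }
    list(images = images, labels = labels, lesion_masks = masks)
  })
}

#' Specification for planted-signal feature matrices
#'
#' @param n_samples Number of rows.
#' @param d_features Number of columns.
#' @param k_informative Number of columns carrying class signal
#'   (`k_informative <= d_features`).
#' @param effect_size Standardized separation between adjacent class means in
#'   the informative columns (Cohen's d units; noise SD is 1).
#' @param classes Number of classes.
#' @param class_proportions Class sampling probabilities; normalized to sum
#'   to 1. Default equal.
#' @param seed Integer seed.
#' @return An object of class `synthetic_feature_spec`.
#' @export
synthetic_feature_spec <- function(n_samples,
                                   d_features,
                                   k_informative,
                                   effect_size = 1,
                                   classes = 4L,
                                   class_proportions = NULL,
                                   seed = 1L) {
  check_number(n_samples, "n_samples", lower = 2, integer = TRUE)
  check_number(d_features, "d_features", lower = 1, integer = TRUE)
  check_number(k_informative, "k_informative", lower = 0, integer = TRUE)
  check_number(effect_size, "effect_size", lower = 0)
  check_number(classes, "classes", lower = 2, integer = TRUE)
  check_number(seed, "seed", integer = TRUE)
  if (k_informative > d_features)
    stop_bad_arg("`k_informative` (%d) must be <= `d_features` (%d)",
                 k_informative, d_features)
  if (is.null(class_proportions)) class_proportions <- rep(1, classes)
  if (length(class_proportions) != classes || any(class_proportions <= 0))
    stop_bad_arg("`class_proportions` must be %d positive values", classes)
  class_proportions <- class_proportions / sum(class_proportions)
  structure(
    list(n_samples = as.integer(n_samples),
         d_features = as.integer(d_features),
         k_informative = as.integer(k_informative),
         effect_size = effect_size,
         classes = as.integer(classes),
         class_proportions = class_proportions,
         seed = as.integer(seed)),
    class = "synthetic_feature_spec")
}

#' Generate a feature matrix with a planted informative subset
#'
#' Labels are drawn from `class_proportions`; the `k_informative` planted
#' columns each carry a one-vs-rest mean shift — column j is elevated by
#' `effect_size` (in units of the unit noise SD) exactly for samples of its
#' assigned class (classes are assigned to planted columns round-robin).
#' This makes the planted columns complementary rather than redundant: each
#' contributes the signature of one class, so a feature-selection wrapper
#' needs (essentially) all of them for full multi-class accuracy. The
#' remaining columns are exchangeable standard normal noise. Which columns
#' are informative is randomized and reported in the planted mask.
#'
#' @param spec A [synthetic_feature_spec()].
#' @return A list with `x` (numeric matrix `n x d`), `y` (integer labels
#'   1..classes), `informative` (logical length-d planted-truth mask), and
#'   `informative_class` (the class each planted column marks; NA for noise
#'   columns).
#' @export
gen_features <- function(spec) {
  if (!inherits(spec, "synthetic_feature_spec"))
    stop_bad_arg("`spec` must be a synthetic_feature_spec")
  with_seed(spec$seed, {
    n <- spec$n_samples; d <- spec$d_features
    y <- sample.int(spec$classes, n, replace = TRUE,
                    prob = spec$class_proportions)
    x <- matrix(stats::rnorm(n * d), n, d)
    informative <- rep(FALSE, d)
    col_class <- rep(NA_integer_, d)
    if (spec$k_informative > 0) {
      cols <- sample.int(d, spec$k_informative)
      informative[cols] <- TRUE
      marked <- ((seq_len(spec$k_informative) - 1L) %% spec$classes) + 1L
      col_class[cols] <- marked
      for (j in seq_along(cols))
        x[, cols[j]] <- x[, cols[j]] + spec$effect_size * (y == marked[j])
    }
    colnames(x) <- sprintf("f%03d", seq_len(d))
    list(x = x, y = y, informative = informative,
         informative_class = col_class)
  })
}

#' Write a synthetic image set to disk
#'
#' Writes each image as a PNG plus a `labels.csv` (filename, label) sidecar,
#' the on-disk layout the CLI consumes.
#'
#' @param imgset Result of [gen_images()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, the labels data frame.
#' @export
write_image_set <- function(imgset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- sprintf("img%04d.png", seq_along(imgset$images))
  for (i in seq_along(imgset$images))
    png::writePNG(t(imgset$images[[i]]), file.path(dir, files[i]))
  df <- data.frame(filename = files, label = imgset$labels)
  utils::write.csv(df, file.path(dir, "labels.csv"), row.names = FALSE)
  invisible(df)
}

#' Read a PNG image set written by [write_image_set()]
#'
#' @param dir Directory containing PNGs and `labels.csv`.
#' @return A list with `images` and `labels` as in [gen_images()].
#' @export
read_image_set <- function(dir) {
  df <- utils::read.csv(file.path(dir, "labels.csv"))
  images <- lapply(file.path(dir, df$filename), function(f) {
    m <- png::readPNG(f)
    if (length(dim(m)) == 3L) m <- m[, , 1L]
    t(m)
  })
  list(images = images, labels = as.integer(df$label))
}

#' Write a feature matrix as CSV with a label column and planted-mask sidecar
#'
#' @param feats Result of [gen_features()].
#' @param path Output CSV path; the planted mask (if present) goes to
#'   `<path>_mask.csv`.
#' @return Invisibly, `path`.
#' @export
write_feature_matrix <- function(feats, path) {
  df <- as.data.frame(feats$x)
  df$label <- feats$y
  utils::write.csv(df, path, row.names = FALSE)
  if (!is.null(feats$informative)) {
    mask_path <- sub("\\.csv$", "_mask.csv", path)
    utils::write.csv(
      data.frame(feature = colnames(feats$x),
                 informative = feats$informative),
      mask_path, row.names = FALSE)
  }
  invisible(path)
}

#' Read a feature matrix CSV (final `label` column)
#'
#' @param path CSV path.
#' @return A list with `x` and `y`.
#' @export
read_feature_matrix <- function(path) {
  df <- utils::read.csv(path)
  if (!"label" %in% names(df)) stop_bad_arg("no `label` column in %s", path)
  y <- as.integer(df$label)
  x <- as.matrix(df[, setdiff(names(df), "label"), drop = FALSE])
  list(x = x, y = y)
}
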