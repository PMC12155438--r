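test_that("min-max normalization is an order-preserving affine map to [0,1]", {
  expect_equal(minmax_normalize(matrix(c(5, 10, 7.5, 5), 2)),
               matrix(c(0, 1, 0.5, 0), 2))
  already <- matrix(c(0, 1, 0.25, 0.75), 2)
  expect_identical(minmax_normalize(already), already)
  expect_error(minmax_normalize(matrix(3, 4, 4)), "constant")
})

test_that("CLAHE degenerates to global histogram equalization", {
  # two-level image
  img <- matrix(rep(c(0.1, 0.8), each = 128), 16)
  out <- apply_clahe(img, clahe_params(1, Inf))
  expect_equal(unique(as.vector(out[img == 0.1])), 0.5)
  expect_equal(unique(as.vector(out[img == 0.8])), 1)
  # random image vs an ecdf oracle
  set.seed(4)
  x <- matrix(stats::runif(900), 30)
  he <- apply_clahe(x, clahe_params(1, Inf))
  bins <- floor(x * 256); bins[bins > 255] <- 255
  oracle <- matrix(stats::ecdf(bins)(bins), 30)
  expect_equal(he, oracle, tolerance = 1e-12)
})

test_that("CLAHE keeps constants constant and stays in [0,1]", {
  cimg <- matrix(0.4, 16, 16)
  out <- apply_clahe(cimg, clahe_params(4, 2))
  expect_equal(length(unique(round(as.vector(out), 12))), 1L)
  set.seed(1)
  r <- apply_clahe(matrix(stats::runif(4096), 64), clahe_params(8, 2))
  expect_true(all(r >= 0 & r <= 1))
  expect_error(apply_clahe(matrix(c(0, 2), 8, 8), clahe_params()),
               "normalized")
})

test_that("default CLAHE does not reduce lesion contrast on synthetic mammograms", {
  d <- gen_images(synthetic_image_spec(5, classes = 4, image_size = 64,
                                       seed = 2))
  deltas <- c()
  for (i in seq_along(d$images)) {
    les <- d$lesion_masks[[i]]
    if (!any(les)) next
    n <- minmax_normalize(d$images[[i]])
    cl <- apply_clahe(n, clahe_params(8, 2))
    bg <- !les & n > 0.1
    deltas <- c(deltas, (mean(cl[les]) - mean(cl[bg])) -
                  (mean(n[les]) - mean(n[bg])))
  }
  expect_gte(mean(deltas), 0)
})

test_that("Gaussian filtering has a unit-sum kernel and denoises", {
  cimg <- matrix(0.37, 12, 12)
  expect_equal(gaussian_filter(cimg, gauss_params(2, 3)), cimg)
  # unit impulse reproduces the normalized kernel
  imp <- matrix(0, 9, 9); imp[5, 5] <- 1
  out <- gaussian_filter(imp, gauss_params(1, 3))
  expect_equal(out[2:8, 2:8], mammopipe:::gaussian_kernel(1, 3),
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(sum(mammopipe:::gaussian_kernel(1.7, 4)), 1)
  # iid noise variance is strictly reduced, across seeds
  for (s in 1:5) {
    set.seed(s)
    noise <- matrix(stats::rnorm(2500), 50)
    expect_lt(stats::var(as.vector(gaussian_filter(noise, gauss_params(1, 3)))),
              stats::var(as.vector(noise)))
  }
  expect_error(gauss_params(0, 3), "sigma")
})

test_that("Otsu matches the exhaustive between-class-variance oracle", {
  # half 20, half 200: perfect separation, agreed argmax
  img <- matrix(rep(c(20, 200), each = 50), 10)
  o <- otsu_segment(img)
  orc <- oracle_otsu(img)
  expect_equal(o$level, orc$level)
  expect_equal(o$between_var, orc$between_var, tolerance = 1e-9)
  expect_true(all(o$mask == (img == 200)))
  # two Gaussian modes: bright-mode recovery >= 99%
  set.seed(9)
  memb <- stats::runif(4096) < 0.4
  vals <- ifelse(memb, stats::rnorm(4096, 0.8, 0.05),
                 stats::rnorm(4096, 0.2, 0.05))
  m <- otsu_segment(matrix(vals, 64))
  expect_gte(sum(m$mask & matrix(memb, 64)) / sum(memb), 0.99)
  expect_error(otsu_segment(matrix(1, 5, 5)), "constant")
})

test_that("mask refinement keeps the main component and fills holes", {
  m <- matrix(FALSE, 40, 40)
  m[10:30, 10:30] <- TRUE          # big blob
  m[2, 2] <- TRUE; m[38, 3] <- TRUE  # isolated speckles
  r <- refine_mask(m, radius = 3)
  expect_false(r$mask[2, 2])
  expect_false(r$mask[38, 3])
  expect_true(all(r$mask[10:30, 10:30]))
  expect_gte(sum(r$mask), sum(m[10:30, 10:30]))
  # full mask is preserved
  expect_true(all(refine_mask(matrix(TRUE, 15, 15))$mask))
  # 3-px interior hole is closed
  h <- matrix(FALSE, 30, 30); h[5:25, 5:25] <- TRUE
  h[14:16, 14:16] <- FALSE
  expect_true(all(refine_mask(h, radius = 5)$mask[14:16, 14:16]))
  expect_error(refine_mask(matrix(FALSE, 5, 5)), "empty")
})

test_that("augmentation is seeded, identity-able, and calibrated", {
  set.seed(0)
  img <- matrix(stats::runif(1024), 32)
  expect_identical(augment(img, seed = 3), augment(img, seed = 3))
  idp <- augment_params(max_angle = 0, zoom_range = c(1, 1), flip_prob = 0,
                        elastic_alpha = 0)
  out <- augment(img, seed = 5, p = idp)
  expect_equal(unclass(out), img, ignore_attr = TRUE)
  # flip frequency over seeded draws
  flips <- vapply(1:1000, function(s)
    attr(augment(img, seed = s,
                 p = augment_params(elastic_alpha = 0)), "draws")$flip_h,
    logical(1))
  expect_gte(mean(flips), 0.45)
  expect_lte(mean(flips), 0.55)
  a <- augment(img, seed = 11)
  expect_equal(dim(a), dim(img))
  d <- attr(a, "draws")
  expect_true(abs(d$angle) <= 15 && d$zoom >= 1.10 && d$zoom <= 1.15)
})

test_that("SMOTE interpolates on same-class segments and balances counts", {
  set.seed(2)
  x <- matrix(stats::rnorm(240), ncol = 2)
  y <- rep(c(1, 2), c(100, 20))
  sm <- smote_oversample(x, y, smote_params(5, 1))
  expect_equal(as.vector(table(sm$y)), c(100, 100))
  expect_identical(sm$x[1:120, ], x)           # originals untouched
  expect_equal(which(sm$synthetic), 121:200)
  # every synthetic point lies on a segment between two same-class originals
  minor <- x[y == 2, ]
  for (i in which(sm$synthetic)) {
    p <- sm$x[i, ]
    on_seg <- FALSE
    for (a in 1:nrow(minor)) for (b in 1:nrow(minor)) {
      if (a == b) next
      v <- minor[b, ] - minor[a, ]; w <- p - minor[a, ]
      lam <- sum(w * v) / sum(v * v)
      if (lam >= -1e-9 && lam <= 1 + 1e-9 &&
          sqrt(sum((w - lam * v)^2)) < 1e-9) { on_seg <- TRUE; break }
    }
    expect_true(on_seg)
  }
  expect_identical(sm, smote_oversample(x, y, smote_params(5, 1)))
  expect_error(smote_oversample(x[1:104, ], y[1:104], smote_params(5, 1)),
               "class '2'")
})

test_that("the preprocessing chain keeps every intermediate in [0,1]", {
  d <- gen_images(synthetic_image_spec(2, classes = 2, image_size = 64,
                                       imbalance_ratios = c(1, 1), seed = 5))
  pp <- preprocess_image(d$images[[1]])
  for (stage in list(pp$norm, pp$clahe, pp$filtered, pp$final))
    expect_true(all(stage >= 0 & stage <= 1))
  expect_s3_class(pp$mask, "breast_mask")
  expect_equal(dim(pp$mask$mask), dim(pp$final))
})
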