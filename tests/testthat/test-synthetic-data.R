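test_that("image generator is deterministic and class-monotone in lesion brightness", {
  spec <- synthetic_image_spec(1, classes = 2, image_size = 64, noise_sd = 0,
                               salt_prob = 0, imbalance_ratios = c(1, 1),
                               seed = 1)
  d1 <- gen_images(spec)
  d2 <- gen_images(spec)
  expect_identical(d1, d2)
  expect_equal(d1$labels, c(1L, 2L))
  # zero noise, monotone lesion brightness: class-2 image has the brighter max
  expect_gt(max(d1$images[[2]]), max(d1$images[[1]]))
  expect_true(all(vapply(d1$images, function(m)
    is.matrix(m) && all(m >= 0 & m <= 1), logical(1))))
})

test_that("a brightness-threshold rule beats chance on 4-class images", {
  d <- gen_images(synthetic_image_spec(25, classes = 4, image_size = 64,
                                       seed = 7))
  # mean brightness of the top percentile approximates lesion-region
  # brightness; classify by the nearest class mean of that statistic
  feat <- vapply(d$images, function(m) mean(sort(m, decreasing = TRUE)[1:40]),
                 numeric(1))
  mu <- tapply(feat, d$labels, mean)
  pred <- as.integer(names(mu))[apply(abs(outer(feat, mu, "-")), 1,
                                      which.min)]
  acc <- mean(pred == d$labels)
  expect_gt(acc, 1 / 4 + 0.1)
})

test_that("invalid image specs are rejected", {
  expect_error(synthetic_image_spec(0), "n_per_class")
  expect_error(synthetic_image_spec(1, image_size = 16), "image_size")
  expect_error(synthetic_image_spec(1, classes = 3,
                                    lesion_intensity_by_class = c(1, 2)),
               "per class")
})

test_that("feature generator plants exactly the requested signal columns", {
  spec <- synthetic_feature_spec(400, 10, 3, effect_size = 5, seed = 3)
  f1 <- gen_features(spec)
  expect_identical(f1, gen_features(spec))
  expect_equal(sum(f1$informative), 3)
  # one-way F statistic ranks the planted columns first
  fstat <- apply(f1$x, 2, function(col)
    summary(stats::aov(col ~ factor(f1$y)))[[1]]$`F value`[1])
  expect_setequal(order(-fstat)[1:3], which(f1$informative))
})

test_that("zero effect size yields no detectable signal", {
  pvals <- c()
  for (s in 1:5) {
    f <- gen_features(synthetic_feature_spec(100, 8, 4, effect_size = 0,
                                             classes = 2, seed = s))
    pvals <- c(pvals, apply(f$x, 2, function(col)
      stats::t.test(col[f$y == 1], col[f$y == 2])$p.value))
  }
  # aggregate false-positive rate stays near the nominal level
  expect_lt(mean(pvals < 0.05), 0.15)
})

test_that("the effect-size dial is calibrated at large n", {
  f <- gen_features(synthetic_feature_spec(2000, 6, 4, effect_size = 2,
                                           classes = 4, seed = 11))
  cols <- which(f$informative)
  for (j in cols) {
    cl <- f$informative_class[j]
    smd <- (mean(f$x[f$y == cl, j]) - mean(f$x[f$y != cl, j])) /
      stats::sd(f$x[f$y != cl, j])
    expect_lt(abs(smd - 2) / 2, 0.1)
  }
})

test_that("feature spec validation rejects impossible requests", {
  expect_error(synthetic_feature_spec(10, 5, 6), "k_informative")
  expect_error(synthetic_feature_spec(10, 5, 2, effect_size = -1),
               "effect_size")
})

test_that("image and feature sets round-trip through their on-disk formats", {
  dir <- withr::local_tempdir()
  d <- gen_images(synthetic_image_spec(1, classes = 2, image_size = 32,
                                       imbalance_ratios = c(1, 1), seed = 2))
  write_image_set(d, dir)
  back <- read_image_set(dir)
  expect_equal(back$labels, d$labels)
  # PNG is 8/16-bit; round trip is exact to 16-bit quantization
  expect_lt(max(abs(back$images[[1]] - d$images[[1]])), 1 / 255)

  f <- gen_features(synthetic_feature_spec(20, 4, 2, seed = 1))
  path <- file.path(dir, "f.csv")
  write_feature_matrix(f, path)
  fb <- read_feature_matrix(path)
  expect_equal(fb$y, f$y)
  expect_equal(unname(fb$x), unname(f$x), tolerance = 1e-12)
  expect_true(file.exists(file.path(dir, "f_mask.csv")))
})
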