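test_that("booster defaults follow the tuned mammography configuration", {
  cfg <- booster_config()
  expect_equal(cfg$learning_rate, 0.03)
  expect_equal(cfg$max_depth, 8L)
  expect_equal(cfg$n_trees, 150L)
  expect_equal(cfg$reg_lambda, 15)
  expect_equal(cfg$min_child_weight, 2)
  expect_equal(cfg$subsample, 0.7)
  expect_equal(cfg$colsample, 0.8)
  expect_equal(cfg$objective, "multi:softprob")
})

test_that("the booster separates separable data and is deterministic", {
  set.seed(1)
  x <- rbind(matrix(stats::rnorm(200, 0), ncol = 2),
             matrix(stats::rnorm(200, 6), ncol = 2))
  y <- rep(1:2, each = 100)
  m <- fit_classifier(x, y, booster_config(n_trees = 50, seed = 1))
  expect_equal(mean(predict(m, x)$class == y), 1)
  m2 <- fit_classifier(x, y, booster_config(n_trees = 50, seed = 1))
  expect_identical(predict(m, x), predict(m2, x))
  expect_error(fit_classifier(x, rep(1, 200)), "degenerate")
})

test_that("the metric suite matches the formula oracle on random confusions", {
  # spec-style binary fixture: TP=45 TN=40 FP=10 FN=5 (positive class = 2)
  y <- c(rep(2, 50), rep(1, 50))
  yp <- c(rep(2, 45), rep(1, 5), rep(2, 10), rep(1, 40))
  m <- confusion_metrics(y, yp)
  o <- oracle_binary_metrics(45, 40, 10, 5)
  for (nm in names(o)) expect_equal(m[[nm]], o[[nm]], tolerance = 1e-12)
  # 500 random predictions, binary and multi-class, against the oracle
  set.seed(7)
  for (rep_i in 1:500) {
    C <- sample(2:5, 1)
    n <- sample(20:60, 1)
    yt <- sample.int(C, n, replace = TRUE)
    if (length(unique(yt)) < 2) next
    yp2 <- sample.int(C, n, replace = TRUE)
    yp2[!(yp2 %in% yt)] <- yt[1]   # keep predictions inside the universe
    mm <- confusion_metrics(yt, yp2, classes = sort(unique(yt)))
    cls <- sort(unique(yt))
    per <- lapply(cls, function(c) {
      tp <- sum(yt == c & yp2 == c); fn <- sum(yt == c & yp2 != c)
      fp <- sum(yt != c & yp2 == c); tn <- sum(yt != c & yp2 != c)
      oracle_binary_metrics(tp, tn, fp, fn)
    })
    scalars <- if (length(cls) == 2) per[[2]]
               else lapply(names(per[[1]]), function(nm)
                 mean(vapply(per, function(p) p[[nm]], numeric(1)))) |>
                 stats::setNames(names(per[[1]]))
    for (nm in c("precision", "recall", "f1", "specificity", "mcc",
                 "balanced_accuracy"))
      expect_equal(mm[[nm]], scalars[[nm]], tolerance = 1e-12)
    expect_equal(mm$accuracy, mean(yt == yp2), tolerance = 1e-12)
    # kappa from the full confusion matrix
    po <- mean(yt == yp2)
    pe <- sum(vapply(cls, function(c) mean(yt == c) * mean(yp2 == c),
                     numeric(1)))
    expect_equal(mm$kappa, (po - pe) / (1 - pe), tolerance = 1e-12)
  }
})

test_that("chance-level prediction scores zero MCC and kappa", {
  y <- rep(c(1, 2), c(90, 10))
  m <- confusion_metrics(y, rep(1, 100))
  expect_equal(m$accuracy, 0.9)
  expect_equal(m$mcc, 0)
  expect_equal(m$kappa, 0)
  # label-permuted predictions have ~0 MCC and kappa in expectation
  set.seed(3)
  yt <- sample.int(3, 400, replace = TRUE)
  mccs <- vapply(1:200, function(i)
    confusion_metrics(yt, sample(yt))$mcc, numeric(1))
  expect_lt(abs(mean(mccs)), 0.02)
  # perfect prediction maxes every chance-corrected metric
  mp <- confusion_metrics(yt, yt)
  expect_equal(c(mp$accuracy, mp$mcc, mp$kappa, mp$balanced_accuracy),
               rep(1, 4))
  expect_error(confusion_metrics(yt, rep(9, 400)), "absent")
})

test_that("one-vs-rest macro AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(11)
  y <- sample.int(3, 150, replace = TRUE)
  sc <- matrix(stats::runif(450), 150)
  sc <- sc / rowSums(sc)
  m <- confusion_metrics(y, y, scores = sc)
  ref <- mean(vapply(1:3, function(c)
    as.numeric(suppressMessages(pROC::auc(pROC::roc(y == c, sc[, c],
                                                    direction = "<")))),
    numeric(1)))
  expect_equal(m$auc, ref, tolerance = 1e-10)
})

test_that("McNemar handles exact, asymptotic and degenerate regimes", {
  # b = 15, c = 5: exact binomial two-sided p
  y <- rep(1, 40)
  pa <- c(rep(1, 20), rep(2, 20))
  pb <- c(rep(2, 15), rep(1, 5), rep(1, 5), rep(2, 15))
  mt <- mcnemar_test(y, pa, pb)
  expect_equal(c(mt$b, mt$c), c(15, 5))
  expect_equal(mt$p_value,
               min(1, 2 * stats::pbinom(14, 20, 0.5, lower.tail = FALSE)))
  # b = c: symmetric, p = 1
  pb2 <- c(rep(2, 10), rep(1, 10), rep(1, 10), rep(2, 10))
  expect_equal(mcnemar_test(y, pa, pb2)$p_value, 1)
  # identical predictions: degenerate flag
  md <- mcnemar_test(y, pa, pa)
  expect_true(md$degenerate)
  expect_equal(md$p_value, 1)
  # large-sample regime matches stats::mcnemar.test with correction
  set.seed(5)
  yt <- rep(1, 200)
  qa <- sample(1:2, 200, replace = TRUE)
  qb <- sample(1:2, 200, replace = TRUE)
  ml <- mcnemar_test(yt, qa, qb)
  tab <- table(factor(qa == yt, c(FALSE, TRUE)),
               factor(qb == yt, c(FALSE, TRUE)))
  ref <- stats::mcnemar.test(tab, correct = TRUE)
  expect_equal(ml$statistic, unname(ref$statistic))
  expect_equal(ml$p_value, ref$p.value)
})

test_that("paired t-test matches the textbook formula and flags zero variance", {
  set.seed(8)
  a <- stats::rnorm(8); b <- stats::rnorm(8)
  tt <- paired_ttest(a, b)
  d <- a - b
  tman <- mean(d) / (stats::sd(d) / sqrt(8))
  expect_equal(tt$t, tman, tolerance = 1e-12)
  expect_equal(tt$p_value, 2 * stats::pt(-abs(tman), 7), tolerance = 1e-12)
  half <- stats::qt(0.975, 7) * stats::sd(d) / sqrt(8)
  expect_equal(tt$ci, c(mean(d) - half, mean(d) + half), tolerance = 1e-12)
  z <- paired_ttest(a, a)
  expect_true(z$degenerate)
  expect_true(is.na(z$p_value))
  expect_true(paired_ttest(c(2, 2, 2, 2, 2), c(1, 1, 1, 1, 1))$degenerate)
})
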