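test_that("population initialization favors high-variance features", {
  cfg <- hho_config(pop_size = 2000, iterations = 1, seed = 1)
  # equal variances: per-bit inclusion uniform
  pop <- init_population(8, cfg, rep(1, 8))
  freq <- colMeans(pop)
  expect_lt(diff(range(freq)), 0.08)
  # dominant-variance feature included most often
  v <- c(rep(1, 7), 100)
  pop2 <- init_population(8, cfg, v)
  expect_equal(which.max(colMeans(pop2)), 8L)
  expect_identical(init_population(8, cfg, v), pop2)
  expect_true(all(rowSums(pop) >= 1))
  expect_error(init_population(0, cfg, numeric(0)), "d")
})

test_that("escape energy follows the decaying schedule", {
  expect_equal(escape_energy(10, 10, e0 = 0.7), 0)
  expect_equal(escape_energy(0, 10, e0 = 1), 2)
  expect_error(escape_energy(11, 10, e0 = 1), "<=")
  # E at t = T/2 is uniform on [-1, 1]
  draws <- vapply(1:5000, function(s) escape_energy(5, 10, seed = s),
                  numeric(1))
  ks <- stats::ks.test(draws, "punif", -1, 1)
  expect_gt(ks$p.value, 0.01)
})

test_that("exploration and exploitation steps match scalar-loop oracles", {
  hawk <- c(1, 0, 1, 1, 0)
  rnd <- c(0, 0, 1, 0, 1)
  expect_equal(explore_step(hawk, hawk, r1 = 0.7), hawk)
  expect_equal(explore_step(hawk, rnd, r1 = 0), hawk)
  r1 <- 0.43
  oracle <- numeric(5)
  for (i in 1:5) oracle[i] <- hawk[i] + r1 * abs(hawk[i] - rnd[i])
  expect_equal(explore_step(hawk, rnd, r1 = r1), oracle)
  best <- c(1, 1, 0, 1, 0)
  expect_equal(exploit_step(hawk, best, E = 0, J = 1.3), best)
  expect_equal(exploit_step(best, best, E = 0.8, J = 1), best)
  E <- -0.6; J <- 1.7
  oracle2 <- numeric(5)
  for (i in 1:5) oracle2[i] <- best[i] - E * abs(J * best[i] - hawk[i])
  expect_equal(exploit_step(hawk, best, E = E, J = J), oracle2)
  expect_error(exploit_step(hawk, NULL, 0), "best")
})

test_that("stochastic binarization follows the logistic transfer function", {
  cfg <- hho_config(seed = 1)
  expect_equal(binarize(rep(1000, 6), cfg, seed = 1), rep(1L, 6))
  expect_equal(mean(vapply(1:2000, function(s)
    binarize(0.5, cfg, seed = s), integer(1))), 1)  # rescue forces the bit
  # empirical inclusion frequencies follow the logistic transfer (the
  # position is long enough that the all-zero rescue is negligible)
  pos <- c(-1, 0.5, 2, 0, 1, -0.5, 1.5, 0.3)
  p_true <- 1 / (1 + exp(-(pos - 0.5)))
  draws <- matrix(0L, 10000, 8)
  for (s in 1:10000) draws[s, ] <- binarize(pos, cfg, seed = s)
  expect_lt(max(abs(colMeans(draws) - p_true)), 0.02)
})

test_that("the accuracy fitness separates signal from noise and caches", {
  f <- gen_features(synthetic_feature_spec(200, 10, 4, effect_size = 5,
                                           classes = 4, seed = 2))
  cfg <- hho_config(pop_size = 4, iterations = 2, seed = 3,
                    fitness_nrounds = 20)
  fit <- hho_fitness_fn(f$x, f$y, cfg)
  env <- attr(fit, "env")
  planted <- as.integer(f$informative)
  noise <- 1L - planted
  a_sig <- fit(planted)
  a_noise <- fit(noise)
  expect_gt(a_sig, a_noise)
  n1 <- env$n_evals
  expect_identical(fit(planted), a_sig)
  expect_identical(env$n_evals, n1)          # cache hit, counter unchanged
  expect_error(fit(rep(0L, 10)), "empty")
  # single noise feature on zero-effect data: accuracy near the majority rate
  f0 <- gen_features(synthetic_feature_spec(300, 5, 0, effect_size = 0,
                                            classes = 2,
                                            class_proportions = c(0.7, 0.3),
                                            seed = 5))
  fit0 <- hho_fitness_fn(f0$x, f0$y, hho_config(seed = 1))
  maj <- max(table(f0$y)) / length(f0$y)
  acc0 <- fit0(c(1L, rep(0L, 4)))
  expect_lt(abs(acc0 - maj), 3 * sqrt(maj * (1 - maj) / length(f0$y)) + 0.02)
})

test_that("HHO finds the toy optimum and the trace never decreases", {
  target <- c(1, 0, 1, 1, 0, 0, 1, 0, 1, 0)
  toy <- function(bits) mean(bits == target)
  hits <- 0
  for (s in 1:10) {
    r <- run_hho(cfg = hho_config(pop_size = 10, iterations = 150, seed = s),
                 fitness_fn = toy, d = 10)
    expect_false(is.unsorted(r$trace))
    hits <- hits + (r$best_fitness == 1)
  }
  expect_gte(hits, 9)
})

test_that("HHO attains but never exceeds the exhaustive optimum (d = 8)", {
  set.seed(42)
  w <- stats::runif(8)
  toy <- function(bits) sum(w * bits) / (1 + abs(sum(bits) - 4))
  grid <- as.matrix(expand.grid(rep(list(0:1), 8)))[-1, ]
  opt <- max(apply(grid, 1, toy))
  matches <- 0
  for (s in 1:10) {
    r <- run_hho(cfg = hho_config(10, 100, seed = s), fitness_fn = toy,
                 d = 8)
    expect_lte(r$best_fitness, opt + 1e-12)
    matches <- matches + (abs(r$best_fitness - opt) < 1e-12)
  }
  expect_gte(matches, 6)
})

test_that("HHO runs are reproducible and reports are consistent", {
  f <- gen_features(synthetic_feature_spec(150, 12, 3, effect_size = 4,
                                           classes = 3, seed = 4))
  cfg <- hho_config(pop_size = 6, iterations = 4, seed = 9,
                    fitness_nrounds = 15)
  r1 <- run_hho(f$x, f$y, cfg)
  r2 <- run_hho(f$x, f$y, cfg)
  expect_identical(r1$best_mask, r2$best_mask)
  expect_identical(r1$trace, r2$trace)
  expect_equal(r1$selected, which(r1$best_mask == 1L))
  expect_lte(length(r1$selected), 12)
  expect_gte(length(r1$selected), 1)
})
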