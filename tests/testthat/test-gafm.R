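test_that("logistic gates match a direct element-wise oracle", {
  p <- gafm_params(c(4, 4), fusion_dim = 4, identity_adapters = TRUE,
                   normalize = FALSE, seed = 1)
  set.seed(2)
  maps <- list(matrix(stats::rnorm(20), 5), matrix(stats::rnorm(20), 5))
  g <- gate_weights(maps, p)
  for (i in 1:2) {
    pre <- maps[[i]] %*% p$gates[[i]]$W +
      matrix(p$gates[[i]]$b, 5, 4, byrow = TRUE)
    oracle <- 1 / (1 + exp(-pre))
    expect_equal(g[[i]], oracle, tolerance = 1e-6)
    expect_true(all(g[[i]] > 0 & g[[i]] < 1))
  }
})

test_that("gate degenerate cases are exact", {
  maps <- list(matrix(stats::rnorm(12), 3), matrix(stats::rnorm(12), 3))
  p0 <- gafm_params(c(4, 4), 4, init = "zero", identity_adapters = TRUE,
                    normalize = FALSE)
  g0 <- gate_weights(maps, p0)
  expect_true(all(g0[[1]] == 0.5) && all(g0[[2]] == 0.5))
  # saturation: large positive bias drives gates to 1
  psat <- p0
  psat$gates[[1]]$b[] <- 50
  gs <- gate_weights(maps, psat)
  expect_equal(as.vector(gs[[1]]), rep(1, 12), tolerance = 1e-12)
})

test_that("fusion is a gated sum: selector, averaging and linearity", {
  set.seed(4)
  A <- matrix(stats::rnorm(12), 3); B <- matrix(stats::rnorm(12), 3)
  ones <- matrix(1, 3, 4); zeros <- matrix(0, 3, 4)
  # selector gates pick out one scale exactly
  expect_equal(fuse(list(A, B), list(ones, zeros))$vector, A)
  # all 0.5 on two identical maps reproduces the map
  expect_equal(fuse(list(A, A), list(ones / 2, ones / 2))$vector, A)
  # linearity in each map at fixed gates
  g <- list(matrix(stats::runif(12), 3), matrix(stats::runif(12), 3))
  A1 <- matrix(stats::rnorm(12), 3); A2 <- A - A1
  lhs <- fuse(list(A, B), g)$vector
  rhs <- fuse(list(A1, B), g)$vector + fuse(list(A2, zeros), g)$vector
  expect_equal(lhs, rhs, tolerance = 1e-12)
  expect_error(fuse(list(A, B), list(ones)), "gate sets")
})

test_that("analytic GAFM gradients agree with finite differences", {
  set.seed(9)
  n <- 15; y <- rep(1:3, 5)
  maps <- list(matrix(stats::rnorm(n * 5), n), matrix(stats::rnorm(n * 4), n))
  for (mode in c("channel", "scalar")) {
    p <- gafm_params(c(5, 4), fusion_dim = 4, mode = mode, seed = 2)
    head <- list(W = matrix(stats::rnorm(12, 0, 0.1), 4, 3),
                 b = stats::rnorm(3, 0, 0.1))
    lg <- mammopipe:::gafm_loss_grad(maps, y, p, head)
    eps <- 1e-6
    # probe one entry in each parameter family
    probes <- list(c("adapters", "A"), c("adapters", "ab"),
                   c("gates", "W"), c("gates", "b"))
    for (pr in probes) {
      idx <- min(2L, length(p[[pr[1]]][[1]][[pr[2]]]))
      p_plus <- p; p_minus <- p
      p_plus[[pr[1]]][[1]][[pr[2]]][idx] <-
        p_plus[[pr[1]]][[1]][[pr[2]]][idx] + eps
      p_minus[[pr[1]]][[1]][[pr[2]]][idx] <-
        p_minus[[pr[1]]][[1]][[pr[2]]][idx] - eps
      num <- (mammopipe:::gafm_loss_grad(maps, y, p_plus, head)$loss -
                mammopipe:::gafm_loss_grad(maps, y, p_minus, head)$loss) /
        (2 * eps)
      ana <- lg$gtree[[pr[1]]][[1]][[pr[2]]][idx]
      expect_equal(ana, num, tolerance = 1e-4)
    }
  }
})

test_that("training prefers the informative scale and is seed-stable", {
  n <- 200; y <- rep(1:2, each = n / 2)
  wins <- 0
  for (s in 1:3) {
    set.seed(s + 10)
    sig <- matrix(stats::rnorm(n * 8), n)
    sig[, 1:4] <- sig[, 1:4] + (y - 1) * 2
    maps <- list(sig, matrix(stats::rnorm(n * 8), n),
                 matrix(stats::rnorm(n * 8), n))
    gf <- train_gafm(maps, y, fusion_dim = 8, epochs = 300, lr = 0.05,
                     seed = s)
    wins <- wins + (which.max(gf$gate_summary) == 1)
  }
  expect_gte(wins, 2)
  # symmetry: identical scales, no gate dominates beyond tolerance
  set.seed(30)
  base <- matrix(stats::rnorm(n * 6), n)
  base[, 1:3] <- base[, 1:3] + (y - 1)
  gsym <- train_gafm(list(base, base, base), y, fusion_dim = 6,
                     epochs = 150, lr = 0.05, seed = 1)
  expect_lt(diff(range(gsym$gate_summary)), 0.1)
  # determinism
  g1 <- train_gafm(list(base, base), y, fusion_dim = 6, epochs = 30,
                   lr = 0.05, seed = 4)
  g2 <- train_gafm(list(base, base), y, fusion_dim = 6, epochs = 30,
                   lr = 0.05, seed = 4)
  expect_identical(g1$params, g2$params)
  expect_error(train_gafm(list(base), rep(1, n)), "2 classes")
})
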