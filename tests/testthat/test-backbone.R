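test_that("patchify_embed produces the expected token grid", {
  cfg <- backbone_config(patch_size = 16, embed_dim = 16, n_stages = 2,
                         blocks_per_stage = 1, heads = 4, window = 2)
  m <- init_backbone(cfg, 64, 2, seed = 1)
  tg <- patchify_embed(matrix(stats::runif(4096), 64), m)
  expect_equal(c(tg$gr, tg$gc), c(4, 4))
  expect_equal(dim(tg$tokens), c(16, 16))
  # zero image, zero bias: all-zero tokens before positional encoding
  m0 <- m; m0$params$embed$b[] <- 0
  tg0 <- patchify_embed(matrix(0, 64, 64), m0, positional = FALSE)
  expect_equal(max(abs(tg0$tokens)), 0)
  expect_error(patchify_embed(matrix(0, 60, 60), m), "divisible")
})

test_that("changing one patch changes exactly one token (pre-positional)", {
  cfg <- backbone_config(patch_size = 16, embed_dim = 16, n_stages = 1,
                         blocks_per_stage = 1, heads = 4, window = 2)
  m <- init_backbone(cfg, 64, 2, seed = 2)
  set.seed(3)
  img1 <- matrix(stats::runif(4096), 64)
  img2 <- img1
  img2[17:32, 33:48] <- stats::runif(256)   # patch at grid row 2, col 3
  t1 <- patchify_embed(img1, m, positional = FALSE)$tokens
  t2 <- patchify_embed(img2, m, positional = FALSE)$tokens
  changed <- which(rowSums(abs(t1 - t2)) > 1e-12)
  expect_equal(changed, (2 - 1) * 4 + 3)
})

test_that("scaled dot-product attention matches a naive dense oracle", {
  # single token: output is V exactly
  q <- matrix(stats::rnorm(8), 1)
  v <- matrix(stats::rnorm(8), 1)
  expect_equal(attention(q, q, v), v, ignore_attr = TRUE)
  # two identical keys: weights 0.5 each, output is the mean of V
  K <- matrix(rep(stats::rnorm(8), 2), 2, byrow = TRUE)
  V <- matrix(stats::rnorm(16), 2)
  out <- attention(q, K, V)
  expect_equal(as.vector(attr(out, "weights")), c(0.5, 0.5))
  expect_equal(as.vector(out), colMeans(V), ignore_attr = TRUE)
  # random 4x8 against an element-wise oracle
  set.seed(5)
  Q <- matrix(stats::rnorm(32), 4); K2 <- matrix(stats::rnorm(32), 4)
  V2 <- matrix(stats::rnorm(32), 4)
  S <- matrix(0, 4, 4)
  for (i in 1:4) for (j in 1:4)
    S[i, j] <- sum(Q[i, ] * K2[j, ]) / sqrt(8)
  W <- t(apply(S, 1, function(r) exp(r - max(r)) / sum(exp(r - max(r)))))
  oracle <- W %*% V2
  expect_equal(unclass(attention(Q, K2, V2)), oracle, tolerance = 1e-6,
               ignore_attr = TRUE)
  # convexity: weight rows sum to 1
  expect_equal(rowSums(attr(attention(Q, K2, V2), "weights")), rep(1, 4))
  expect_error(attention(Q, K2[, 1:4], V2), "d_k")
})

test_that("window attention with a full-grid window equals global attention", {
  cfg <- backbone_config(patch_size = 16, embed_dim = 8, n_stages = 1,
                         blocks_per_stage = 1, heads = 1, window = 4)
  m <- init_backbone(cfg, 64, 2, seed = 4)
  p <- m$params$stage1[[1]]$attn_win
  set.seed(6)
  X <- matrix(stats::rnorm(16 * 8), 16)
  for (axis in c("window", "grid")) {
    out <- axis_attention(X, 4, 4, 4, p, heads = 1, axis = axis)
    lin <- function(W, b) X %*% W + matrix(b, 16, 8, byrow = TRUE)
    glob <- attention(lin(p$Wq, p$bq), lin(p$Wk, p$bk), lin(p$Wv, p$bv))
    oracle <- glob %*% p$Wo + matrix(p$bo, 16, 8, byrow = TRUE)
    expect_equal(out, oracle, tolerance = 1e-10, ignore_attr = TRUE)
  }
})

test_that("window attention is local: cross-window swaps only touch those windows", {
  cfg <- backbone_config(patch_size = 16, embed_dim = 8, n_stages = 1,
                         blocks_per_stage = 1, heads = 2, window = 2)
  m <- init_backbone(cfg, 64, 2, seed = 5)
  p <- m$params$stage1[[1]]$attn_win
  set.seed(7)
  X <- matrix(stats::rnorm(16 * 8), 16)
  wg <- mammopipe:::window_groups(4, 4, 2)
  # swap one token of window 1 with one token of window 4
  X2 <- X
  X2[c(wg[[1]][1], wg[[4]][1]), ] <- X[c(wg[[4]][1], wg[[1]][1]), ]
  o1 <- axis_attention(X, 4, 4, 2, p, heads = 2, axis = "window")
  o2 <- axis_attention(X2, 4, 4, 2, p, heads = 2, axis = "window")
  touched <- sort(c(wg[[1]], wg[[4]]))
  diffs <- which(rowSums(abs(o1 - o2)) > 1e-12)
  expect_true(all(diffs %in% touched))
  expect_equal(o1[setdiff(1:16, touched), ], o2[setdiff(1:16, touched), ])
})

test_that("a block with zeroed output projections is the identity", {
  cfg <- backbone_config(patch_size = 8, embed_dim = 8, n_stages = 1,
                         blocks_per_stage = 1, heads = 2, window = 2,
                         dropout = 0)
  m <- init_backbone(cfg, 32, 2, seed = 1)
  blk <- m$params$stage1[[1]]
  blk$attn_win$Wo[] <- 0; blk$attn_win$bo[] <- 0
  blk$attn_grid$Wo[] <- 0; blk$attn_grid$bo[] <- 0
  blk$ffn1$W2[] <- 0; blk$ffn1$b2[] <- 0
  blk$ffn2$W2[] <- 0; blk$ffn2$b2[] <- 0
  tg <- patchify_embed(matrix(stats::runif(1024), 32), m)
  out <- multi_axis_block(tg, blk, heads = 2, window = 2)
  expect_equal(out$tokens, tg$tokens)
  expect_error(multi_axis_block(tg, blk, heads = 2, window = 3),
               "divisible")
})

test_that("multiscale extraction has the declared shapes and is deterministic", {
  bb <- tiny_backbone()
  img <- minmax_normalize(tiny_image_set()$images[[1]])
  f1 <- extract_multiscale(img, bb)
  expect_s3_class(f1, "feature_map_set")
  expect_length(f1$maps, 2)
  # mean+max pooling: twice the stage dims (16, 32)
  expect_equal(unname(f1$dims), c(32L, 64L))
  expect_identical(f1, extract_multiscale(img, bb))
  um <- init_backbone(bb$cfg, 64, 2, seed = 9)
  expect_warning(extract_multiscale(img, um), "untrained")
})

test_that("training reduces cross-entropy and features support a linear probe", {
  d <- tiny_image_set()
  bb <- tiny_backbone()
  h <- bb$history
  expect_lt(utils::tail(h$train_loss, 1), h$train_loss[1])
  proc <- lapply(d$images, minmax_normalize)
  fms <- lapply(proc, extract_multiscale, model = bb)
  X <- t(vapply(fms, function(f) f$maps[[length(f$maps)]], numeric(64)))
  y <- d$labels; n <- length(y)
  set.seed(1)
  tr <- sample(n, n %/% 2); te <- setdiff(seq_len(n), tr)
  fit <- glmnet::glmnet(X[tr, ], factor(y[tr]), family = "binomial",
                        alpha = 0, lambda = 0.05)
  acc <- mean((predict(fit, X[te, ], type = "response")[, 1] > 0.5) + 1 ==
                y[te])
  expect_gt(acc, 0.5)   # above the 2-class chance level
})

test_that("training and prediction are deterministic under seed", {
  d <- tiny_image_set()
  keep <- c(1:8, 31:38)               # both classes represented
  proc <- lapply(d$images[keep], minmax_normalize)
  y <- d$labels[keep]
  cfg <- backbone_config(16, 8, 1, 1, 2, 2, dropout = 0.2)
  b1 <- train_backbone(proc, y, cfg, epochs = 2, lr = 1e-3, val_frac = 0.2,
                       seed = 3)
  b2 <- train_backbone(proc, y, cfg, epochs = 2, lr = 1e-3, val_frac = 0.2,
                       seed = 3)
  expect_identical(b1$params, b2$params)
  expect_identical(predict(b1, proc[1:2]), predict(b2, proc[1:2]))
})
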