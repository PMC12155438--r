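# Miniature multi-axis transformer feature extractor.
#
# Images are split into patches, linearly embedded, and processed by blocks
# that alternate local window attention (non-overlapping w x w tiles of the
# token grid) and global grid attention (strided token subsets), each with
# residual and feed-forward sublayers under pre-layer-norm. Stages are
# separated by 2x2 patch merging (dimension doubles); each stage emits a
# globally average-pooled feature vector, giving a multi-scale feature set.
# Everything is plain R matrix algebra so the model is trainable from
# scratch at desk scale.

#' Backbone configuration
#'
#' @param patch_size Patch side in pixels; the image side must be divisible
#'   by it.
#' @param embed_dim Embedding channels of the first stage; must be divisible
#'   by `heads`. Dimension doubles at each patch merge.
#' @param n_stages Number of hierarchical stages (>= 1; >= 2 gives a true
#'   multi-scale feature set).
#' @param blocks_per_stage Multi-axis blocks per stage.
#' @param heads Attention heads.
#' @param window Window side (in tokens) for local attention; the token grid
#'   side must be divisible by it. The same size parameterizes the strided
#'   grid attention.
#' @param dropout Dropout probability applied to sublayer outputs during
#'   training.
#' @param ffn_mult Feed-forward hidden width as a multiple of the stage
#'   dimension.
#' @return An object of class `backbone_config`.
#' @export
backbone_config <- function(patch_size = 32L, embed_dim = 64L,
                            n_stages = 2L, blocks_per_stage = 5L,
                            heads = 4L, window = 2L, dropout = 0.2,
                            ffn_mult = 2L) {
  check_number(patch_size, "patch_size", lower = 1, integer = TRUE)
  check_number(embed_dim, "embed_dim", lower = 1, integer = TRUE)
  check_number(n_stages, "n_stages", lower = 1, integer = TRUE)
  check_number(blocks_per_stage, "blocks_per_stage", lower = 1,
               integer = TRUE)
  check_number(heads, "heads", lower = 1, integer = TRUE)
  check_number(window, "window", lower = 1, integer = TRUE)
  check_number(dropout, "dropout", lower = 0, upper = 0.95)
  check_number(ffn_mult, "ffn_mult", lower = 1, integer = TRUE)
  if (embed_dim %% heads != 0L)
    stop_bad_arg("`embed_dim` must be divisible by `heads`")
  structure(list(patch_size = as.integer(patch_size),
                 embed_dim = as.integer(embed_dim),
                 n_stages = as.integer(n_stages),
                 blocks_per_stage = as.integer(blocks_per_stage),
                 heads = as.integer(heads),
                 window = as.integer(window),
                 dropout = dropout,
                 ffn_mult = as.integer(ffn_mult)),
            class = "backbone_config")
}

# --- parameter initialization ----------------------------------------------

rand_mat <- function(nr, nc, sd = 0.02) matrix(stats::rnorm(nr * nc, 0, sd),
                                               nr, nc)

init_attn <- function(d) list(Wq = rand_mat(d, d), bq = numeric(d),
                              Wk = rand_mat(d, d), bk = numeric(d),
                              Wv = rand_mat(d, d), bv = numeric(d),
                              Wo = rand_mat(d, d), bo = numeric(d))

init_ln <- function(d) list(g = rep(1, d), b = numeric(d))

init_ffn <- function(d, h) list(W1 = rand_mat(d, h), b1 = numeric(h),
                                W2 = rand_mat(h, d), b2 = numeric(d))

init_block <- function(d, ffn_mult) {
  h <- d * ffn_mult
  list(ln1 = init_ln(d), attn_win = init_attn(d),
       ln2 = init_ln(d), ffn1 = init_ffn(d, h),
       ln3 = init_ln(d), attn_grid = init_attn(d),
       ln4 = init_ln(d), ffn2 = init_ffn(d, h))
}

stage_dims <- function(cfg) cfg$embed_dim * 2L^(seq_len(cfg$n_stages) - 1L)

#' Initialize an untrained backbone
#'
#' @param cfg A [backbone_config()].
#' @param image_size Input image side in pixels.
#' @param n_classes Number of classes for the training head.
#' @param seed Integer seed for weight initialization.
#' @return An object of class `mini_maxvit` (untrained).
#' @export
init_backbone <- function(cfg, image_size, n_classes, seed = 1L) {
  if (!inherits(cfg, "backbone_config"))
    stop_bad_arg("`cfg` must be a backbone_config")
  check_number(image_size, "image_size", lower = cfg$patch_size,
               integer = TRUE)
  check_number(n_classes, "n_classes", lower = 2, integer = TRUE)
  if (image_size %% cfg$patch_size != 0L)
    stop_bad_arg("image side %d is not divisible by patch_size %d",
                 image_size, cfg$patch_size)
  gr1 <- image_size %/% cfg$patch_size
  gr_s <- gr1 %/% 2L^(seq_len(cfg$n_stages) - 1L)
  if (any(gr_s < 1L))
    stop_bad_arg("too many stages for a %dx%d token grid", gr1, gr1)
  dims <- stage_dims(cfg)
  with_seed(seed, {
    params <- list(
      embed = list(W = rand_mat(cfg$patch_size^2, cfg$embed_dim),
                   b = numeric(cfg$embed_dim)))
    for (s in seq_len(cfg$n_stages)) {
      blocks <- lapply(seq_len(cfg$blocks_per_stage), function(i)
        init_block(dims[s], cfg$ffn_mult))
      params[[paste0("stage", s)]] <- blocks
      if (s < cfg$n_stages)
        params[[paste0("merge", s)]] <-
          list(W = rand_mat(4L * dims[s], dims[s + 1L]),
               b = numeric(dims[s + 1L]))
    }
    # Per-stage pooled features are mean + max over tokens (2 x stage dim).
    params$head <- list(W = rand_mat(2L * sum(dims), n_classes),
                        b = numeric(n_classes))
    structure(list(cfg = cfg, params = params, image_size = image_size,
                   n_classes = as.integer(n_classes),
                   grid_sides = gr_s, dims = dims,
                   trained = FALSE, history = NULL),
              class = "mini_maxvit")
  })
}

# --- token grid helpers -----------------------------------------------------

# Sinusoidal positional encoding over flattened token positions.
posenc <- function(n, d) {
  pos <- seq_len(n) - 1L
  pe <- matrix(0, n, d)
  half <- d %/% 2L
  for (k in seq_len(half)) {
    freq <- 1 / 10000^(2 * (k - 1) / d)
    pe[, 2L * k - 1L] <- sin(pos * freq)
    pe[, 2L * k] <- cos(pos * freq)
  }
  if (d %% 2L == 1L) pe[, d] <- sin(pos / 10000)
  pe
}

# Row-major token index for grid cell (i, j).
tok_index <- function(i, j, gc) (i - 1L) * gc + j

# Non-overlapping w x w window groups of a gr x gc token grid.
window_groups <- function(gr, gc, w) {
  if (gr %% w != 0L || gc %% w != 0L)
    stop_bad_arg("token grid %dx%d not divisible by window %d", gr, gc, w)
  out <- list()
  for (wi in seq_len(gr %/% w)) for (wj in seq_len(gc %/% w)) {
    rows <- (wi - 1L) * w + seq_len(w)
    cols <- (wj - 1L) * w + seq_len(w)
    out[[length(out) + 1L]] <-
      as.vector(outer(rows, cols, function(i, j) tok_index(i, j, gc)))
  }
  out
}

# Strided (dilated) grid groups: tokens sharing a residue class modulo the
# stride gr/w; group sizes match the window groups and the degenerate case
# w = gr yields a single global group.
grid_groups <- function(gr, gc, w) {
  if (gr %% w != 0L || gc %% w != 0L)
    stop_bad_arg("token grid %dx%d not divisible by window %d", gr, gc, w)
  sr <- gr %/% w; sc <- gc %/% w
  out <- list()
  for (a in seq_len(sr)) for (b in seq_len(sc)) {
    rows <- seq(a, gr, by = sr)
    cols <- seq(b, gc, by = sc)
    out[[length(out) + 1L]] <-
      as.vector(outer(rows, cols, function(i, j) tok_index(i, j, gc)))
  }
  out
}

#' Patchify and embed an image into a token grid
#'
#' Splits the image into non-overlapping `patch_size` patches, flattens each
#' and applies the model's learnable linear projection, then (optionally)
#' adds a sinusoidal positional encoding.
#'
#' @param img Normalized image whose side is divisible by the patch size.
#' @param model A `mini_maxvit` from [init_backbone()] or [train_backbone()].
#' @param positional Add the sinusoidal positional encoding (default TRUE).
#' @return A `token_grid`: list with `tokens` (N x embed_dim matrix, row-major
#'   over the grid), `gr`, `gc`.
#' @export
patchify_embed <- function(img, model, positional = TRUE) {
  check_image(img)
  if (!inherits(model, "mini_maxvit"))
    stop_bad_arg("`model` must be a mini_maxvit")
  ps <- model$cfg$patch_size
  if (nrow(img) %% ps != 0L || ncol(img) %% ps != 0L)
    stop_bad_arg("image %dx%d not divisible by patch_size %d",
                 nrow(img), ncol(img), ps)
  gr <- nrow(img) %/% ps; gc <- ncol(img) %/% ps
  pm <- matrix(0, gr * gc, ps * ps)
  for (i in seq_len(gr)) for (j in seq_len(gc))
    pm[tok_index(i, j, gc), ] <-
      as.vector(img[(i - 1L) * ps + seq_len(ps), (j - 1L) * ps + seq_len(ps)])
  tokens <- pm %*% model$params$embed$W +
    matrix(model$params$embed$b, gr * gc, length(model$params$embed$b),
           byrow = TRUE)
  if (positional) tokens <- tokens + posenc(gr * gc, ncol(tokens))
  structure(list(tokens = tokens, gr = gr, gc = gc, patches = pm),
            class = "token_grid")
}

#' Scaled dot-product attention
#'
#' `softmax(Q K' / sqrt(d_k)) V`. Each output row is a convex combination of
#' the rows of `V`; the attention-weight rows sum to 1.
#'
#' @param Q,K,V Numeric matrices; `Q` and `K` share the inner dimension
#'   `d_k`, `K` and `V` the number of rows.
#' @return The attended value matrix, with the weight matrix in
#'   `attr(, "weights")`.
#' @export
attention <- function(Q, K, V) {
  if (!is.matrix(Q) || !is.matrix(K) || !is.matrix(V))
    stop_bad_arg("Q, K, V must be matrices")
  if (ncol(Q) != ncol(K)) stop_bad_arg("Q and K must share d_k")
  if (nrow(K) != nrow(V)) stop_bad_arg("K and V must share their row count")
  if (ncol(Q) < 1L) stop_bad_arg("d_k must be positive")
  A <- softmax_rows(Q %*% t(K) / sqrt(ncol(Q)))
  out <- A %*% V
  attr(out, "weights") <- A
  out
}

# --- forward primitives (with caches for backprop) -------------------------

ln_fwd <- function(X, p, eps = 1e-5) {
  mu <- rowMeans(X)
  xc <- X - mu
  v <- rowMeans(xc^2)
  istd <- 1 / sqrt(v + eps)
  xhat <- xc * istd
  Y <- sweep(xhat, 2L, p$g, "*")
  Y <- sweep(Y, 2L, p$b, "+")
  list(Y = Y, xhat = xhat, istd = istd)
}

lin_fwd <- function(X, W, b) X %*% W + matrix(b, nrow(X), length(b),
                                              byrow = TRUE)

# Multi-head self-attention restricted to token groups (a partition of rows).
mhsa_fwd <- function(X, p, groups, heads) {
  d <- ncol(X); dh <- d %/% heads
  Y <- matrix(0, nrow(X), d)
  cache <- vector("list", length(groups))
  for (gi in seq_along(groups)) {
    g <- groups[[gi]]
    Xg <- X[g, , drop = FALSE]
    Q <- lin_fwd(Xg, p$Wq, p$bq)
    K <- lin_fwd(Xg, p$Wk, p$bk)
    V <- lin_fwd(Xg, p$Wv, p$bv)
    O <- matrix(0, length(g), d)
    As <- vector("list", heads)
    for (h in seq_len(heads)) {
      cols <- (h - 1L) * dh + seq_len(dh)
      A <- softmax_rows(Q[, cols, drop = FALSE] %*%
                          t(K[, cols, drop = FALSE]) / sqrt(dh))
      O[, cols] <- A %*% V[, cols, drop = FALSE]
      As[[h]] <- A
    }
    Y[g, ] <- lin_fwd(O, p$Wo, p$bo)
    cache[[gi]] <- list(Xg = Xg, Q = Q, K = K, V = V, O = O, As = As)
  }
  list(Y = Y, cache = cache)
}

ffn_fwd <- function(X, p) {
  H <- lin_fwd(X, p$W1, p$b1)
  Hr <- pmax(H, 0)
  list(Y = lin_fwd(Hr, p$W2, p$b2), H = H, Hr = Hr)
}

drop_fwd <- function(X, rate, training) {
  if (!training || rate <= 0) return(list(Y = X, mask = NULL))
  mask <- matrix(stats::rbinom(length(X), 1L, 1 - rate), nrow(X)) /
    (1 - rate)
  list(Y = X * mask, mask = mask)
}

# One multi-axis block: window attention, FFN, grid attention, FFN, each as a
# pre-norm residual sublayer.
block_fwd <- function(X, bp, gr, gc, w, heads, dropout, training) {
  wg <- window_groups(gr, gc, w)
  gg <- grid_groups(gr, gc, w)
  c1 <- ln_fwd(X, bp$ln1); a1 <- mhsa_fwd(c1$Y, bp$attn_win, wg, heads)
  d1 <- drop_fwd(a1$Y, dropout, training); X1 <- X + d1$Y
  c2 <- ln_fwd(X1, bp$ln2); f1 <- ffn_fwd(c2$Y, bp$ffn1)
  d2 <- drop_fwd(f1$Y, dropout, training); X2 <- X1 + d2$Y
  c3 <- ln_fwd(X2, bp$ln3); a2 <- mhsa_fwd(c3$Y, bp$attn_grid, gg, heads)
  d3 <- drop_fwd(a2$Y, dropout, training); X3 <- X2 + d3$Y
  c4 <- ln_fwd(X3, bp$ln4); f2 <- ffn_fwd(c4$Y, bp$ffn2)
  d4 <- drop_fwd(f2$Y, dropout, training); X4 <- X3 + d4$Y
  list(Y = X4, wg = wg, gg = gg,
       c1 = c1, a1 = a1, d1 = d1, X1 = X1,
       c2 = c2, f1 = f1, d2 = d2, X2 = X2,
       c3 = c3, a2 = a2, d3 = d3, X3 = X3,
       c4 = c4, f2 = f2, d4 = d4, X = X)
}

#' Apply one multi-axis attention block to a token grid
#'
#' Runs, in order: pre-norm local window attention, feed-forward, pre-norm
#' strided grid attention, feed-forward, each with a residual connection.
#' With `window` equal to the grid side, both attention sublayers degenerate
#' to global attention over all tokens.
#'
#' @param tg A `token_grid` from [patchify_embed()] (or a list with `tokens`,
#'   `gr`, `gc`).
#' @param block Block parameters (one element of `model$params$stageS`).
#' @param heads Number of attention heads.
#' @param window Window side in tokens.
#' @return A `token_grid` with transformed tokens.
#' @export
multi_axis_block <- function(tg, block, heads, window) {
  if (is.null(tg$tokens)) stop_bad_arg("`tg` must contain tokens")
  fw <- block_fwd(tg$tokens, block, tg$gr, tg$gc, window, heads,
                  dropout = 0, training = FALSE)
  structure(list(tokens = fw$Y, gr = tg$gr, gc = tg$gc),
            class = "token_grid")
}

#' One axis-attention sublayer (no residual, no norm)
#'
#' Exposes the raw multi-head attention over window or grid token groups,
#' mainly for equivalence and locality checks.
#'
#' @param X Token matrix (N x d).
#' @param gr,gc Token grid dims (N = gr * gc, row-major).
#' @param window Window side in tokens.
#' @param params Attention parameter list (Wq/bq/Wk/bk/Wv/bv/Wo/bo).
#' @param heads Number of heads.
#' @param axis `"window"` for local tiles, `"grid"` for strided groups.
#' @return Attended token matrix (N x d).
#' @export
axis_attention <- function(X, gr, gc, window, params, heads,
                           axis = c("window", "grid")) {
  axis <- match.arg(axis)
  groups <- if (axis == "window") window_groups(gr, gc, window)
            else grid_groups(gr, gc, window)
  mhsa_fwd(X, params, groups, heads)$Y
}

# Patch-merge index map: output token t (on the gr/2 grid) gathers input
# tokens idx[t, 1:4]; dimension doubles through the merge projection.
merge_index <- function(gr, gc) {
  gr2 <- gr %/% 2L; gc2 <- gc %/% 2L
  idx <- matrix(0L, gr2 * gc2, 4L)
  for (i in seq_len(gr2)) for (j in seq_len(gc2)) {
    t <- tok_index(i, j, gc2)
    idx[t, ] <- c(tok_index(2L * i - 1L, 2L * j - 1L, gc),
                  tok_index(2L * i - 1L, 2L * j, gc),
                  tok_index(2L * i, 2L * j - 1L, gc),
                  tok_index(2L * i, 2L * j, gc))
  }
  idx
}

merge_fwd <- function(X, mp, gr, gc) {
  idx <- merge_index(gr, gc)
  Xc <- cbind(X[idx[, 1L], , drop = FALSE], X[idx[, 2L], , drop = FALSE],
              X[idx[, 3L], , drop = FALSE], X[idx[, 4L], , drop = FALSE])
  list(Y = lin_fwd(Xc, mp$W, mp$b), Xc = Xc, idx = idx)
}

# Full forward pass; returns per-stage pooled features, class scores and the
# cache needed for backprop.
backbone_fwd <- function(img, model, training = FALSE) {
  cfg <- model$cfg
  tg <- patchify_embed(img, model)
  X <- tg$tokens
  gr <- tg$gr; gc <- tg$gc
  stages <- vector("list", cfg$n_stages)
  pooled <- vector("list", cfg$n_stages)
  for (s in seq_len(cfg$n_stages)) {
    w <- min(cfg$window, gr)
    blocks <- model$params[[paste0("stage", s)]]
    bcaches <- vector("list", length(blocks))
    for (b in seq_along(blocks)) {
      bcaches[[b]] <- block_fwd(X, blocks[[b]], gr, gc, w, cfg$heads,
                                cfg$dropout, training)
      X <- bcaches[[b]]$Y
    }
    # Mean pooling summarizes global tissue context; max pooling keeps the
    # response of the single strongest token (small bright lesions occupy
    # one or two patches and would otherwise be diluted by the background).
    amax <- apply(X, 2L, which.max)
    pooled[[s]] <- c(colMeans(X), X[cbind(amax, seq_len(ncol(X)))])
    stages[[s]] <- list(bcaches = bcaches, X_out = X, gr = gr, gc = gc,
                        w = w, argmax = amax)
    if (s < cfg$n_stages) {
      mf <- merge_fwd(X, model$params[[paste0("merge", s)]], gr, gc)
      stages[[s]]$merge <- mf
      X <- mf$Y
      gr <- gr %/% 2L; gc <- gc %/% 2L
    }
  }
  feat <- unlist(pooled)
  z <- as.vector(feat %*% model$params$head$W) + model$params$head$b
  p <- exp(z - max(z)); p <- p / sum(p)
  list(tg = tg, stages = stages, pooled = pooled, feat = feat,
       scores = z, probs = p)
}

#' Extract multi-scale pooled features from an image
#'
#' Runs the backbone in inference mode (no dropout) and returns, per stage,
#' the concatenated mean- and max-pooled token features (length twice the
#' stage dimension).
#'
#' @param img Normalized image.
#' @param model A `mini_maxvit`.
#' @return A `feature_map_set`: list with `maps` (list of per-stage numeric
#'   vectors), `scale_ids` and `dims`.
#' @export
extract_multiscale <- function(img, model) {
  if (!inherits(model, "mini_maxvit"))
    stop_bad_arg("`model` must be a mini_maxvit")
  if (!isTRUE(model$trained))
    warning("extracting features from an untrained backbone", call. = FALSE)
  fw <- backbone_fwd(img, model, training = FALSE)
  structure(list(maps = fw$pooled,
                 scale_ids = seq_along(fw$pooled),
                 dims = lengths(fw$pooled)),
            class = "feature_map_set")
}
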