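# Analytic backpropagation and AdamW training for the miniature multi-axis
# transformer. Gradients mirror the nested parameter lists.

zeros_like <- function(x) if (is.list(x)) lapply(x, zeros_like) else x * 0

add_tree <- function(a, b) {
  if (is.list(a)) {
    for (k in seq_along(a)) a[[k]] <- add_tree(a[[k]], b[[k]])
    a
  } else a + b
}

scale_tree <- function(a, s) {
  if (is.list(a)) lapply(a, scale_tree, s = s) else a * s
}

ln_bwd <- function(dY, cache, p) {
  dxhat <- sweep(dY, 2L, p$g, "*")
  xhat <- cache$xhat
  m1 <- rowMeans(dxhat)
  m2 <- rowMeans(dxhat * xhat)
  dX <- cache$istd * (dxhat - m1 - xhat * m2)
  list(dX = dX, g = colSums(dY * xhat), b = colSums(dY))
}

mhsa_bwd <- function(dY, cache, p, groups, heads) {
  d <- ncol(dY); dh <- d %/% heads
  dX <- matrix(0, nrow(dY), d)
  g <- zeros_like(p)
  for (gi in seq_along(groups)) {
    gidx <- groups[[gi]]
    cc <- cache[[gi]]
    dYg <- dY[gidx, , drop = FALSE]
    dO <- dYg %*% t(p$Wo)
    g$Wo <- g$Wo + t(cc$O) %*% dYg
    g$bo <- g$bo + colSums(dYg)
    dQ <- matrix(0, length(gidx), d)
    dK <- matrix(0, length(gidx), d)
    dV <- matrix(0, length(gidx), d)
    for (h in seq_len(heads)) {
      cols <- (h - 1L) * dh + seq_len(dh)
      A <- cc$As[[h]]
      dOh <- dO[, cols, drop = FALSE]
      Vh <- cc$V[, cols, drop = FALSE]
      dA <- dOh %*% t(Vh)
      dV[, cols] <- t(A) %*% dOh
      dS <- A * (dA - rowSums(dA * A))
      dS <- dS / sqrt(dh)
      dQ[, cols] <- dS %*% cc$K[, cols, drop = FALSE]
      dK[, cols] <- t(dS) %*% cc$Q[, cols, drop = FALSE]
    }
    Xg <- cc$Xg
    g$Wq <- g$Wq + t(Xg) %*% dQ; g$bq <- g$bq + colSums(dQ)
    g$Wk <- g$Wk + t(Xg) %*% dK; g$bk <- g$bk + colSums(dK)
    g$Wv <- g$Wv + t(Xg) %*% dV; g$bv <- g$bv + colSums(dV)
    dX[gidx, ] <- dQ %*% t(p$Wq) + dK %*% t(p$Wk) + dV %*% t(p$Wv)
  }
  list(dX = dX, grads = g)
}

ffn_bwd <- function(dY, cache, p, Xin) {
  dW2 <- t(cache$Hr) %*% dY
  db2 <- colSums(dY)
  dH <- (dY %*% t(p$W2)) * (cache$H > 0)
  dW1 <- t(Xin) %*% dH
  db1 <- colSums(dH)
  list(dX = dH %*% t(p$W1),
       grads = list(W1 = dW1, b1 = db1, W2 = dW2, b2 = db2))
}

drop_bwd <- function(dY, d) if (is.null(d$mask)) dY else dY * d$mask

block_bwd <- function(dY, bc, bp, heads) {
  g <- zeros_like(bp)
  # Sublayer 4 (FFN): X4 = X3 + drop(ffn2(ln4(X3)))
  du <- drop_bwd(dY, bc$d4)
  fb <- ffn_bwd(du, bc$f2, bp$ffn2, bc$c4$Y)
  g$ffn2 <- fb$grads
  lb <- ln_bwd(fb$dX, bc$c4, bp$ln4)
  g$ln4 <- list(g = lb$g, b = lb$b)
  dX3 <- dY + lb$dX
  # Sublayer 3 (grid attention)
  du <- drop_bwd(dX3, bc$d3)
  ab <- mhsa_bwd(du, bc$a2$cache, bp$attn_grid, bc$gg, heads)
  g$attn_grid <- ab$grads
  lb <- ln_bwd(ab$dX, bc$c3, bp$ln3)
  g$ln3 <- list(g = lb$g, b = lb$b)
  dX2 <- dX3 + lb$dX
  # Sublayer 2 (FFN)
  du <- drop_bwd(dX2, bc$d2)
  fb <- ffn_bwd(du, bc$f1, bp$ffn1, bc$c2$Y)
  g$ffn1 <- fb$grads
  lb <- ln_bwd(fb$dX, bc$c2, bp$ln2)
  g$ln2 <- list(g = lb$g, b = lb$b)
  dX1 <- dX2 + lb$dX
  # Sublayer 1 (window attention)
  du <- drop_bwd(dX1, bc$d1)
  ab <- mhsa_bwd(du, bc$a1$cache, bp$attn_win, bc$wg, heads)
  g$attn_win <- ab$grads
  lb <- ln_bwd(ab$dX, bc$c1, bp$ln1)
  g$ln1 <- list(g = lb$g, b = lb$b)
  list(dX = dX1 + lb$dX, grads = g)
}

# Cross-entropy gradient of one forward pass; returns loss and the full
# parameter-gradient tree.
backbone_bwd <- function(fw, model, y) {
  cfg <- model$cfg
  probs <- fw$probs
  loss <- -log(max(probs[y], 1e-12))
  dz <- probs
  dz[y] <- dz[y] - 1
  grads <- zeros_like(model$params)
  grads$head$W <- outer(fw$feat, dz)
  grads$head$b <- dz
  dfeat <- as.vector(model$params$head$W %*% dz)
  offs <- c(0L, cumsum(2L * model$dims))
  d_in_next <- NULL
  for (s in rev(seq_len(cfg$n_stages))) {
    st <- fw$stages[[s]]
    npix <- st$gr * st$gc
    ds <- model$dims[s]
    dpool <- dfeat[(offs[s] + 1L):offs[s + 1L]]
    dmean <- dpool[seq_len(ds)]
    dmax <- dpool[ds + seq_len(ds)]
    dXout <- matrix(dmean / npix, npix, ds, byrow = TRUE)
    dXout[cbind(st$argmax, seq_len(ds))] <-
      dXout[cbind(st$argmax, seq_len(ds))] + dmax
    if (s < cfg$n_stages) {
      mp <- model$params[[paste0("merge", s)]]
      mf <- st$merge
      dYm <- d_in_next
      grads[[paste0("merge", s)]] <-
        list(W = t(mf$Xc) %*% dYm, b = colSums(dYm))
      dXc <- dYm %*% t(mp$W)
      dsub <- ncol(dXout)
      for (q in 1:4) {
        cols <- (q - 1L) * dsub + seq_len(dsub)
        dXout[mf$idx[, q], ] <- dXout[mf$idx[, q], ] + dXc[, cols]
      }
    }
    blocks <- model$params[[paste0("stage", s)]]
    dX <- dXout
    for (b in rev(seq_along(blocks))) {
      bb <- block_bwd(dX, st$bcaches[[b]], blocks[[b]], cfg$heads)
      grads[[paste0("stage", s)]][[b]] <- bb$grads
      dX <- bb$dX
    }
    d_in_next <- dX
  }
  grads$embed <- list(W = t(fw$tg$patches) %*% d_in_next,
                      b = colSums(d_in_next))
  list(loss = loss, grads = grads)
}

# AdamW with decoupled weight decay; moment state is kept in an environment
# keyed by parameter path.
adamw_step <- function(params, grads, state, lr, weight_decay = 1e-4,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  t <- state$t
  walk <- function(p, g, path) {
    if (is.list(p)) {
      nms <- names(p)
      for (k in seq_along(p)) {
        key <- if (!is.null(nms) && nzchar(nms[k])) nms[k]
               else as.character(k)
        p[[k]] <- walk(p[[k]], g[[k]], paste0(path, ".", key))
      }
      return(p)
    }
    m <- state$m[[path]]; v <- state$v[[path]]
    if (is.null(m)) { m <- p * 0; v <- p * 0 }
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g^2
    state$m[[path]] <- m; state$v[[path]] <- v
    mhat <- m / (1 - beta1^t)
    vhat <- v / (1 - beta2^t)
    p - lr * (mhat / (sqrt(vhat) + eps) + weight_decay * p)
  }
  walk(params, grads, "p")
}

mean_ce_loss <- function(model, images, y) {
  mean(vapply(seq_along(images), function(i) {
    fw <- backbone_fwd(images[[i]], model, training = FALSE)
    -log(max(fw$probs[y[i]], 1e-12))
  }, numeric(1)))
}

#' Train the miniature multi-axis transformer from scratch
#'
#' Minimizes class cross-entropy of a linear head over the concatenated
#' per-stage pooled features with AdamW, using minibatch gradient
#' accumulation, dropout, and early stopping on a held-out validation split
#' when the validation loss has not improved for `patience` epochs.
#' Deterministic under `seed`.
#'
#' @param images List of normalized image matrices (equal size).
#' @param labels Integer class labels (1..C or any coercible factor).
#' @param cfg A [backbone_config()].
#' @param epochs Maximum training epochs.
#' @param lr AdamW learning rate (default 1e-4).
#' @param batch_size Minibatch size (default 8).
#' @param val_frac Fraction held out for validation (0 disables early
#'   stopping).
#' @param patience Early-stopping patience in epochs.
#' @param weight_decay AdamW decoupled weight decay.
#' @param seed Integer seed covering initialization, shuffling and dropout.
#' @param model Optionally a pre-initialized `mini_maxvit` to continue
#'   training.
#' @param verbose Print per-epoch losses.
#' @return A trained `mini_maxvit` with a `history` data frame (epoch,
#'   train_loss, val_loss) and the class levels in `$classes`.
#' @export
train_backbone <- function(images, labels, cfg = backbone_config(),
                           epochs = 5L, lr = 1e-4, batch_size = 8L,
                           val_frac = 0.2, patience = 10L,
                           weight_decay = 1e-4, seed = 1L, model = NULL,
                           verbose = FALSE) {
  if (!length(images)) stop_bad_arg("`images` is empty")
  labels <- as.integer(factor(labels))
  classes <- sort(unique(labels))
  if (length(classes) < 2L) stop_bad_arg("need at least 2 classes")
  if (is.null(model))
    model <- init_backbone(cfg, nrow(images[[1L]]), length(classes),
                           seed = seed)
  with_seed(seed + 1L, {
    n <- length(images)
    n_val <- if (val_frac > 0) max(1L, round(val_frac * n)) else 0L
    val_idx <- if (n_val > 0) sample.int(n, n_val) else integer(0)
    tr_idx <- setdiff(seq_len(n), val_idx)
    state <- new.env(parent = emptyenv())
    state$t <- 0L; state$m <- list(); state$v <- list()
    best_val <- Inf; best_params <- model$params; wait <- 0L
    hist <- data.frame(epoch = integer(0), train_loss = numeric(0),
                       val_loss = numeric(0))
    for (ep in seq_len(epochs)) {
      ord <- sample(tr_idx)
      ep_loss <- 0
      bstart <- seq(1L, length(ord), by = batch_size)
      for (bs in bstart) {
        bidx <- ord[bs:min(bs + batch_size - 1L, length(ord))]
        gacc <- NULL
        for (i in bidx) {
          fw <- backbone_fwd(images[[i]], model, training = TRUE)
          bw <- backbone_bwd(fw, model, labels[i])
          ep_loss <- ep_loss + bw$loss
          gacc <- if (is.null(gacc)) bw$grads else add_tree(gacc, bw$grads)
        }
        gacc <- scale_tree(gacc, 1 / length(bidx))
        model$params <- adamw_step(model$params, gacc, state, lr,
                                   weight_decay)
      }
      tr_loss <- ep_loss / length(ord)
      vl <- if (n_val > 0)
        mean_ce_loss(model, images[val_idx], labels[val_idx]) else NA_real_
      hist <- rbind(hist, data.frame(epoch = ep, train_loss = tr_loss,
                                     val_loss = vl))
      if (verbose)
        message(sprintf("epoch %d: train %.4f val %.4f", ep, tr_loss, vl))
      if (n_val > 0) {
        if (vl < best_val - 1e-6) {
          best_val <- vl; best_params <- model$params; wait <- 0L
        } else {
          wait <- wait + 1L
          if (wait >= patience) break
        }
      }
    }
    if (n_val > 0) model$params <- best_params
    model$trained <- TRUE
    model$history <- hist
    model$classes <- classes
    model
  })
}

#' @export
print.mini_maxvit <- function(x, ...) {
  cfg <- x$cfg
  cat(sprintf(
    "Miniature multi-axis transformer (%s)\n",
    if (isTRUE(x$trained)) "trained" else "untrained"))
  cat(sprintf("  patch %dpx, stages %d (dims %s), %d block(s)/stage, %d heads, window %d\n",
              cfg$patch_size, cfg$n_stages,
              paste(x$dims, collapse = "/"), cfg$blocks_per_stage,
              cfg$heads, cfg$window))
  if (!is.null(x$history) && nrow(x$history))
    cat(sprintf("  final train loss %.4f over %d epoch(s)\n",
                utils::tail(x$history$train_loss, 1), nrow(x$history)))
  invisible(x)
}

#' Predict class probabilities with the backbone's training head
#'
#' @param object A trained `mini_maxvit`.
#' @param images List of normalized images.
#' @param ... Unused.
#' @return Matrix of class probabilities (one row per image).
#' @export
predict.mini_maxvit <- function(object, images, ...) {
  probs <- t(vapply(images, function(im)
    backbone_fwd(im, object, training = FALSE)$probs,
    numeric(object$n_classes)))
  colnames(probs) <- paste0("class", seq_len(object$n_classes))
  probs
}
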