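# Gated attention fusion module (GAFM): per-scale linear adapters to a common
# fusion dimension, logistic gates alpha_i = sigmoid(W_i f_i + b_i), fused
# representation F_fused = sum_i alpha_i (elementwise) f_i, trained jointly
# with a softmax classification head.

# Accept a feature_map_set (vectors), a list of vectors, or a list of
# matrices (samples x dim per scale); return a list of matrices.
as_scale_matrices <- function(maps) {
  if (inherits(maps, "feature_map_set")) maps <- maps$maps
  if (!is.list(maps) || !length(maps))
    stop_bad_arg("`maps` must be a non-empty list of per-scale features")
  lapply(maps, function(m) {
    if (is.matrix(m)) m else matrix(m, nrow = 1L)
  })
}

#' Stack per-sample feature map sets into batch form
#'
#' Turns a list of per-image `feature_map_set`s (from
#' [extract_multiscale()]) into the batch layout [train_gafm()] expects:
#' one `n x d_i` matrix per scale.
#'
#' @param fms_list List of `feature_map_set` objects with identical scale
#'   structure.
#' @return List over scales of sample-by-dimension matrices.
#' @export
stack_feature_maps <- function(fms_list) {
  k <- length(fms_list[[1L]]$maps)
  lapply(seq_len(k), function(s)
    t(vapply(fms_list, function(f) f$maps[[s]],
             numeric(length(fms_list[[1L]]$maps[[s]])))))
}

#' GAFM parameters
#'
#' One linear adapter (`A_i`, `ab_i`) projecting each scale to the common
#' fusion dimension, plus learnable gate parameters (`W_i`, `b_i`) per scale.
#' In `"channel"` mode gates are per-channel vectors in (0, 1); in `"scalar"`
#' mode one gate per scale (the ablation variant).
#'
#' @param dims Integer vector of per-scale input dimensions.
#' @param fusion_dim Common fusion dimension (default `min(dims)`).
#' @param mode `"channel"` or `"scalar"` gating.
#' @param init `"random"` (small Gaussian) or `"zero"` (gates exactly 0.5 at
#'   start).
#' @param identity_adapters If TRUE (requires all `dims == fusion_dim`),
#'   adapters are fixed identities — used when gating raw maps directly.
#' @param normalize RMS-normalize each adapted scale per sample before
#'   gating and fusion (default TRUE). This equalizes scale amplitudes so
#'   the gates — not the adapter norms — decide how much each scale
#'   contributes, which is what makes the trained gate magnitudes
#'   interpretable as scale importance. Set FALSE to gate the raw projected
#'   features.
#' @param seed Seed for random initialization.
#' @return An object of class `gafm_params`.
#' @export
gafm_params <- function(dims, fusion_dim = min(dims),
                        mode = c("channel", "scalar"),
                        init = c("random", "zero"),
                        identity_adapters = FALSE, normalize = TRUE,
                        seed = 1L) {
  mode <- match.arg(mode); init <- match.arg(init)
  dims <- as.integer(dims)
  if (length(dims) < 1L || any(dims < 1L))
    stop_bad_arg("`dims` must be positive integers")
  check_number(fusion_dim, "fusion_dim", lower = 1, integer = TRUE)
  if (identity_adapters && any(dims != fusion_dim))
    stop_bad_arg("identity adapters need all dims == fusion_dim")
  gdim <- if (mode == "channel") fusion_dim else 1L
  with_seed(seed, {
    adapters <- lapply(dims, function(d) {
      if (identity_adapters) list(A = diag(1, d, fusion_dim),
                                  ab = numeric(fusion_dim))
      else if (init == "zero") list(A = diag(1, d, fusion_dim) * 0 +
                                      rand_mat(d, fusion_dim, 0.05),
                                    ab = numeric(fusion_dim))
      else list(A = rand_mat(d, fusion_dim, 0.05),
                ab = numeric(fusion_dim))
    })
    gates <- lapply(dims, function(d) {
      if (init == "zero") list(W = matrix(0, fusion_dim, gdim),
                               b = numeric(gdim))
      else list(W = rand_mat(fusion_dim, gdim, 0.05), b = numeric(gdim))
    })
    structure(list(dims = dims, fusion_dim = as.integer(fusion_dim),
                   mode = mode, identity_adapters = identity_adapters,
                   normalize = isTRUE(normalize),
                   adapters = adapters, gates = gates),
              class = "gafm_params")
  })
}

# Per-sample RMS normalization: y = x / sqrt(mean(x^2) + eps).
rms_fwd <- function(X, eps = 1e-6) {
  istd <- 1 / sqrt(rowMeans(X^2) + eps)
  list(Y = X * istd, istd = istd)
}

rms_bwd <- function(dY, Y, istd) (dY - Y * rowMeans(dY * Y)) * istd

gafm_adapt <- function(maps, p) {
  lapply(seq_along(maps), function(i) {
    a <- lin_fwd(maps[[i]], p$adapters[[i]]$A, p$adapters[[i]]$ab)
    if (isTRUE(p$normalize)) rms_fwd(a)$Y else a
  })
}

#' Compute GAFM gate weights
#'
#' Applies the per-scale adapters and evaluates the logistic gates
#' `alpha_i = sigmoid(W_i f_i + b_i)`; every gate lies strictly in (0, 1).
#' With `W = 0, b = 0` all gates are exactly 0.5.
#'
#' @param maps A `feature_map_set`, a list of per-scale vectors, or a list of
#'   per-scale sample matrices.
#' @param p A [gafm_params()].
#' @return List of gate matrices (one per scale; `n x fusion_dim` in channel
#'   mode, `n x 1` in scalar mode).
#' @export
gate_weights <- function(maps, p) {
  if (!inherits(p, "gafm_params")) stop_bad_arg("`p` must be gafm_params")
  maps <- as_scale_matrices(maps)
  if (length(maps) != length(p$dims))
    stop_bad_arg("expected %d scales, got %d", length(p$dims), length(maps))
  for (i in seq_along(maps))
    if (ncol(maps[[i]]) != p$dims[i])
      stop_bad_arg("scale %d has dim %d, expected %d", i, ncol(maps[[i]]),
                   p$dims[i])
  ad <- gafm_adapt(maps, p)
  lapply(seq_along(ad), function(i)
    logistic(lin_fwd(ad[[i]], p$gates[[i]]$W, p$gates[[i]]$b)))
}

#' Fuse feature maps with gates
#'
#' `F_fused = sum_i alpha_i * f_i` (elementwise product; scalar gates
#' broadcast). When `p` is supplied, scales are first passed through its
#' adapters; with `p = NULL` the maps are fused as given (they must share
#' one dimension). Linear in each map at fixed gates.
#'
#' @param maps As in [gate_weights()].
#' @param gates List of gate matrices (or vectors) conforming to `maps`.
#' @param p Optional [gafm_params()] providing the adapters.
#' @return A `fused_feature`: list with `vector` (n x fusion_dim matrix, or a
#'   plain vector for single-sample input) and `gates`.
#' @export
fuse <- function(maps, gates, p = NULL) {
  single <- inherits(maps, "feature_map_set") ||
    (is.list(maps) && !is.matrix(maps[[1L]]))
  maps <- as_scale_matrices(maps)
  if (!is.list(gates)) stop_bad_arg("`gates` must be a list (one per scale)")
  gates <- lapply(gates, function(g) if (is.matrix(g)) g
                  else matrix(g, nrow = 1L))
  if (length(gates) != length(maps))
    stop_bad_arg("%d gate sets for %d scales", length(gates), length(maps))
  ad <- if (is.null(p)) maps else gafm_adapt(maps, p)
  dimn <- ncol(ad[[1L]])
  if (any(vapply(ad, ncol, integer(1)) != dimn))
    stop_bad_arg("scales must share one dimension for fusion")
  fused <- matrix(0, nrow(ad[[1L]]), dimn)
  for (i in seq_along(ad)) {
    g <- gates[[i]]
    if (ncol(g) == 1L && dimn > 1L) g <- g[, rep(1L, dimn), drop = FALSE]
    if (!all(dim(g) == dim(ad[[i]])))
      stop_bad_arg("gate %d does not conform to its map", i)
    fused <- fused + g * ad[[i]]
  }
  structure(list(vector = if (single && nrow(fused) == 1L)
                   as.vector(fused) else fused,
                 gates = gates),
            class = "fused_feature")
}

# Mean cross-entropy and full analytic gradient tree for one GAFM forward.
gafm_loss_grad <- function(maps, y, p, head, Y = NULL) {
  n <- nrow(maps[[1L]])
  if (is.null(Y)) {
    C <- length(head$b)
    Y <- matrix(0, n, C); Y[cbind(seq_len(n), y)] <- 1
  }
  fw <- gafm_fwd(maps, p, head)
  loss <- -mean(log(pmax(fw$P[cbind(seq_len(n), y)], 1e-12)))
  dZ <- (fw$P - Y) / n
  gtree <- list(adapters = zeros_like(p$adapters),
                gates = zeros_like(p$gates),
                head = list(W = t(fw$fused) %*% dZ, b = colSums(dZ)))
  dfused <- dZ %*% t(head$W)
  for (i in seq_along(maps)) {
    Ad <- fw$ad[[i]]; G <- fw$gates[[i]]
    if (p$mode == "channel") {
      dG <- dfused * Ad
      dAd <- dfused * G
      dpre <- dG * G * (1 - G)
      gtree$gates[[i]]$W <- t(Ad) %*% dpre
      gtree$gates[[i]]$b <- colSums(dpre)
      dAd <- dAd + dpre %*% t(p$gates[[i]]$W)
    } else {
      gs <- as.vector(G)
      dGs <- rowSums(dfused * Ad)
      dAd <- dfused * gs
      dpre <- matrix(dGs * gs * (1 - gs), ncol = 1L)
      gtree$gates[[i]]$W <- t(Ad) %*% dpre
      gtree$gates[[i]]$b <- colSums(dpre)
      dAd <- dAd + dpre %*% t(p$gates[[i]]$W)
    }
    dRaw <- if (isTRUE(p$normalize))
      rms_bwd(dAd, Ad, fw$istd[[i]]) else dAd
    gtree$adapters[[i]]$A <- t(maps[[i]]) %*% dRaw
    gtree$adapters[[i]]$ab <- colSums(dRaw)
  }
  list(loss = loss, gtree = gtree, fw = fw)
}

# Batch forward with cache.
gafm_fwd <- function(maps, p, head) {
  ad <- vector("list", length(maps))
  istd <- vector("list", length(maps))
  for (i in seq_along(maps)) {
    a <- lin_fwd(maps[[i]], p$adapters[[i]]$A, p$adapters[[i]]$ab)
    if (isTRUE(p$normalize)) {
      nf <- rms_fwd(a)
      ad[[i]] <- nf$Y; istd[[i]] <- nf$istd
    } else ad[[i]] <- a
  }
  gates <- lapply(seq_along(ad), function(i)
    logistic(lin_fwd(ad[[i]], p$gates[[i]]$W, p$gates[[i]]$b)))
  dimn <- p$fusion_dim
  fused <- matrix(0, nrow(ad[[1L]]), dimn)
  for (i in seq_along(ad)) {
    g <- gates[[i]]
    if (ncol(g) == 1L && dimn > 1L) g <- g[, rep(1L, dimn), drop = FALSE]
    fused <- fused + g * ad[[i]]
  }
  Z <- lin_fwd(fused, head$W, head$b)
  P <- softmax_rows(Z)
  list(ad = ad, istd = istd, gates = gates, fused = fused, Z = Z, P = P)
}

#' Train the GAFM and its classification head
#'
#' Jointly fits the adapters, gates and a softmax head by full-batch Adam on
#' the class cross-entropy. Deterministic under `seed`.
#'
#' @param maps Batch feature maps: list over scales of `n x d_i` matrices
#'   (use [stack_feature_maps()] to build it from per-image extractions).
#' @param labels Class labels, length n (at least 2 classes).
#' @param fusion_dim Common fusion dimension (default `min(dims)`).
#' @param mode `"channel"` (vector gates) or `"scalar"` (one gate per scale).
#' @param epochs Number of Adam epochs (full-batch).
#' @param lr Adam learning rate.
#' @param val_frac Held-out fraction for the early-stopping validation loss
#'   (0 disables).
#' @param patience Early-stopping patience in epochs.
#' @param seed Integer seed.
#' @return An object of class `gafm`: params, head, per-scale mean gate
#'   magnitude (`gate_summary`), training history and class levels.
#' @export
train_gafm <- function(maps, labels, fusion_dim = NULL,
                       mode = c("channel", "scalar"), epochs = 150L,
                       lr = 0.01, val_frac = 0, patience = 20L, seed = 1L) {
  mode <- match.arg(mode)
  maps <- as_scale_matrices(maps)
  n <- nrow(maps[[1L]])
  labels <- as.integer(factor(labels))
  C <- length(unique(labels))
  if (C < 2L) stop_bad_arg("need at least 2 classes to train the GAFM")
  if (any(vapply(maps, nrow, integer(1)) != n))
    stop_bad_arg("all scales must have the same number of samples")
  dims <- vapply(maps, ncol, integer(1))
  if (is.null(fusion_dim)) fusion_dim <- min(dims)
  with_seed(seed, {
    p <- gafm_params(dims, fusion_dim, mode = mode, init = "random",
                     seed = sample.int(.Machine$integer.max, 1L))
    head <- list(W = rand_mat(fusion_dim, C, 0.05), b = numeric(C))
    n_val <- if (val_frac > 0) max(1L, round(val_frac * n)) else 0L
    vi <- if (n_val > 0) sample.int(n, n_val) else integer(0)
    ti <- setdiff(seq_len(n), vi)
    tr_maps <- lapply(maps, function(m) m[ti, , drop = FALSE])
    va_maps <- lapply(maps, function(m) m[vi, , drop = FALSE])
    Y <- matrix(0, length(ti), C); Y[cbind(seq_along(ti), labels[ti])] <- 1
    state <- new.env(parent = emptyenv())
    state$t <- 0L; state$m <- list(); state$v <- list()
    best <- list(val = Inf, p = p, head = head); wait <- 0L
    hist <- data.frame(epoch = integer(0), train_loss = numeric(0),
                       val_loss = numeric(0))
    nt <- length(ti)
    for (ep in seq_len(epochs)) {
      lg <- gafm_loss_grad(tr_maps, labels[ti], p, head, Y)
      loss <- lg$loss
      gtree <- lg$gtree
      ptree <- list(adapters = p$adapters, gates = p$gates, head = head)
      ptree <- adamw_step(ptree, gtree, state, lr, weight_decay = 0)
      p$adapters <- ptree$adapters; p$gates <- ptree$gates
      head <- ptree$head
      vl <- NA_real_
      if (n_val > 0) {
        vf <- gafm_fwd(va_maps, p, head)
        vl <- -mean(log(pmax(vf$P[cbind(seq_len(n_val), labels[vi])],
                             1e-12)))
        if (vl < best$val - 1e-6) {
          best <- list(val = vl, p = p, head = head); wait <- 0L
        } else {
          wait <- wait + 1L
        }
      }
      hist <- rbind(hist, data.frame(epoch = ep, train_loss = loss,
                                     val_loss = vl))
      if (n_val > 0 && wait >= patience) break
    }
    if (n_val > 0 && is.finite(best$val)) {
      p <- best$p; head <- best$head
    }
    fw <- gafm_fwd(maps, p, head)
    gate_summary <- vapply(fw$gates, function(g) mean(abs(g)), numeric(1))
    structure(list(params = p, head = head, gate_summary = gate_summary,
                   history = hist, classes = sort(unique(labels))),
              class = "gafm")
  })
}

#' Apply a trained GAFM to feature maps
#'
#' @param object A `gafm` from [train_gafm()].
#' @param maps Batch feature maps (list over scales of `n x d_i` matrices) or
#'   a single `feature_map_set`.
#' @return Matrix of fused features (`n x fusion_dim`).
#' @export
gafm_apply <- function(object, maps) {
  if (!inherits(object, "gafm")) stop_bad_arg("`object` must be a gafm")
  maps <- as_scale_matrices(maps)
  gafm_fwd(maps, object$params, object$head)$fused
}

#' @export
predict.gafm <- function(object, maps, ...) {
  maps <- as_scale_matrices(maps)
  fw <- gafm_fwd(maps, object$params, object$head)
  list(class = max.col(fw$P), prob = fw$P)
}

#' @export
print.gafm <- function(x, ...) {
  cat(sprintf("GAFM: %d scales -> fusion dim %d (%s gates)\n",
              length(x$params$dims), x$params$fusion_dim, x$params$mode))
  cat("  mean |gate| per scale:",
      paste(sprintf("%.3f", x$gate_summary), collapse = ", "), "\n")
  invisible(x)
}
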