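# SMOTE oversampling: synthetic minority samples by interpolation toward
# same-class nearest neighbors, x_new = x_i + lambda (x_neighbor - x_i).

#' SMOTE parameters
#'
#' @param k_neighbors Number of same-class nearest neighbors to interpolate
#'   toward (>= 1).
#' @param seed Integer seed; oversampling is deterministic under it.
#' @return An object of class `smote_params`.
#' @export
smote_params <- function(k_neighbors = 5L, seed = 1L) {
  check_number(k_neighbors, "k_neighbors", lower = 1, integer = TRUE)
  check_number(seed, "seed", integer = TRUE)
  structure(list(k_neighbors = as.integer(k_neighbors),
                 seed = as.integer(seed)),
            class = "smote_params")
}

#' SMOTE oversampling of minority classes
#'
#' Brings every class up to the majority-class count. Each synthetic sample
#' lies on the segment between a minority sample and one of its
#' `k_neighbors` same-class nearest (Euclidean) neighbors, at a uniform
#' random position lambda in [0, 1]. Original rows are returned untouched and
#' first; the `origin` vector maps every output row to its source row index
#' (`NA` for synthetic rows), which is what the cross-validation leakage
#' guard checks.
#'
#' @param x Numeric feature matrix (samples x features).
#' @param y Class labels (length `nrow(x)`).
#' @param p A [smote_params()].
#' @return List with `x`, `y`, `origin` (source row index, NA = synthetic)
#'   and `synthetic` (logical flag per output row).
#' @export
smote_oversample <- function(x, y, p = smote_params()) {
  if (!is.matrix(x) || !is.numeric(x))
    stop_bad_arg("`x` must be a numeric matrix")
  if (length(y) != nrow(x))
    stop_bad_arg("`y` must have one label per row of `x`")
  if (!inherits(p, "smote_params")) stop_bad_arg("`p` must be smote_params")
  y <- as.vector(y)
  counts <- table(y)
  n_max <- max(counts)
  minority <- names(counts)[counts < n_max]
  for (cl in minority) {
    if (counts[[cl]] < p$k_neighbors + 1L)
      stop_bad_arg(
        "class '%s' has %d samples but SMOTE needs at least k_neighbors + 1 = %d",
        cl, counts[[cl]], p$k_neighbors + 1L)
  }
  new_x <- list(); new_y <- list()
  with_seed(p$seed, {
    for (cl in minority) {
      idx <- which(y == cl)
      xc <- x[idx, , drop = FALSE]
      n_c <- length(idx)
      n_new <- n_max - n_c
      # Pairwise distances within the class; k nearest excluding self.
      dmat <- as.matrix(stats::dist(xc))
      diag(dmat) <- Inf
      nn <- t(apply(dmat, 1L, function(r) order(r)[seq_len(p$k_neighbors)]))
      base_i <- sample(rep_len(seq_len(n_c), n_new))
      lam <- stats::runif(n_new)
      nb_pick <- sample.int(p$k_neighbors, n_new, replace = TRUE)
      xs <- matrix(0, n_new, ncol(x))
      for (s in seq_len(n_new)) {
        xi <- xc[base_i[s], ]
        xn <- xc[nn[base_i[s], nb_pick[s]], ]
        xs[s, ] <- xi + lam[s] * (xn - xi)
      }
      new_x[[cl]] <- xs
      new_y[[cl]] <- rep(if (is.numeric(y)) as.numeric(cl) else cl, n_new)
    }
  })
  if (length(new_x)) {
    xs_all <- do.call(rbind, new_x)
    colnames(xs_all) <- colnames(x)
    out_x <- rbind(x, xs_all)
    out_y <- c(y, unlist(new_y, use.names = FALSE))
    origin <- c(seq_len(nrow(x)), rep(NA_integer_, nrow(xs_all)))
  } else {
    out_x <- x; out_y <- y; origin <- seq_len(nrow(x))
  }
  list(x = out_x, y = out_y, origin = origin, synthetic = is.na(origin))
}
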