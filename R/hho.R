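# Binary Harris Hawks optimization (HHO) over feature-inclusion masks.
#
# Hawks are binary masks x in {0,1}^d. Each iteration every hawk draws an
# escape energy E = 2 E0 (1 - t/T), E0 ~ U[-1,1]; with |E| >= 1 it takes a
# randomized exploration step X + r1 |X - X_rand|, otherwise an exploitation
# step X_best - E |J X_best - X| with jump strength J = 2(1 - r). Continuous
# proposals are binarized through a stochastic logistic transfer function.
# Fitness is the internally cross-validated accuracy of a classifier trained
# on the selected columns; acceptance is elitist (a hawk is replaced only by
# a better proposal; fitness ties go to the sparser mask).

#' HHO configuration
#'
#' @param pop_size Number of hawks P (>= 2).
#' @param iterations Iteration budget T (default 150).
#' @param seed Integer seed; the whole run is deterministic under it.
#' @param binarize_threshold Center of the logistic transfer function.
#' @param fitness_cv_folds Internal stratified folds for the accuracy
#'   fitness.
#' @param tie_break_fewer Break equal-fitness comparisons in favor of the
#'   mask with fewer selected features.
#' @param fitness_classifier `"xgboost"` (default, a small fast booster) or
#'   `"logistic"`.
#' @param fitness_nrounds,fitness_depth,fitness_eta Booster settings for the
#'   fitness classifier (kept small: the fitness is called thousands of
#'   times).
#' @return An object of class `hho_config`.
#' @export
hho_config <- function(pop_size = 10L, iterations = 150L, seed = 1L,
                       binarize_threshold = 0.5, fitness_cv_folds = 3L,
                       tie_break_fewer = TRUE,
                       fitness_classifier = c("xgboost", "logistic"),
                       fitness_nrounds = 30L, fitness_depth = 3L,
                       fitness_eta = 0.3) {
  check_number(pop_size, "pop_size", lower = 2, integer = TRUE)
  check_number(iterations, "iterations", lower = 1, integer = TRUE)
  check_number(seed, "seed", integer = TRUE)
  check_number(binarize_threshold, "binarize_threshold")
  check_number(fitness_cv_folds, "fitness_cv_folds", lower = 2,
               integer = TRUE)
  structure(list(pop_size = as.integer(pop_size),
                 iterations = as.integer(iterations),
                 seed = as.integer(seed),
                 binarize_threshold = binarize_threshold,
                 fitness_cv_folds = as.integer(fitness_cv_folds),
                 tie_break_fewer = isTRUE(tie_break_fewer),
                 fitness_classifier = match.arg(fitness_classifier),
                 fitness_nrounds = as.integer(fitness_nrounds),
                 fitness_depth = as.integer(fitness_depth),
                 fitness_eta = fitness_eta),
            class = "hho_config")
}

# Per-bit inclusion probabilities favoring high-variance features:
# p_i = 0.3 + 0.4 * rank_i / d (rank 1 = lowest variance).
variance_inclusion_probs <- function(variances) {
  d <- length(variances)
  0.3 + 0.4 * rank(variances, ties.method = "average") / d
}

# Draw P masks from per-bit probabilities using the current RNG stream;
# all-zero masks are redrawn.
draw_population <- function(d, probs, P) {
  pop <- matrix(0L, P, d)
  for (j in seq_len(P)) {
    bits <- as.integer(stats::runif(d) < probs)
    while (sum(bits) == 0L) bits <- as.integer(stats::runif(d) < probs)
    pop[j, ] <- bits
  }
  pop
}

#' Initialize the hawk population
#'
#' Bit i is set with probability increasing in the variance rank of feature
#' i (`0.3 + 0.4 rank/d`), so high-variance features are favored initially;
#' all-zero masks are redrawn. Deterministic under `cfg$seed`.
#'
#' @param d Number of features (>= 1).
#' @param cfg An [hho_config()].
#' @param feature_variances Numeric vector of length `d`.
#' @return Integer matrix (`pop_size x d`) of binary masks.
#' @export
init_population <- function(d, cfg, feature_variances) {
  check_number(d, "d", lower = 1, integer = TRUE)
  if (!inherits(cfg, "hho_config")) stop_bad_arg("`cfg` must be hho_config")
  if (length(feature_variances) != d)
    stop_bad_arg("`feature_variances` must have length %d", d)
  probs <- variance_inclusion_probs(feature_variances)
  with_seed(cfg$seed, draw_population(d, probs, cfg$pop_size))
}

#' Escape energy schedule
#'
#' `E = 2 E0 (1 - t/T)` with `E0 ~ U[-1, 1]`; the envelope |E| <= 2(1 - t/T)
#' decays linearly to 0 at `t = T`.
#'
#' @param t Current iteration (0 <= t <= T).
#' @param T Total iterations.
#' @param seed Optional seed for the `E0` draw.
#' @param e0 Optionally force `E0` (bypasses the draw).
#' @return The scalar escape energy.
#' @export
escape_energy <- function(t, T, seed = NULL, e0 = NULL) {
  check_number(t, "t", lower = 0)
  check_number(T, "T", lower = 1)
  if (t > T) stop_bad_arg("`t` (%g) must be <= `T` (%g)", t, T)
  if (is.null(e0)) e0 <- with_seed(seed, stats::runif(1, -1, 1))
  2 * e0 * (1 - t / T)
}

#' Exploration step (continuous proposal)
#'
#' `X + r1 |X - X_rand|` with a scalar `r1 ~ U[0, 1]`; the proposal is
#' binarized separately (see [binarize()]). `r1 = 0` or `X = X_rand`
#' returns `X` unchanged.
#'
#' @param hawk,rand_hawk Binary (or continuous) position vectors of equal
#'   length.
#' @param seed Optional seed for the `r1` draw.
#' @param r1 Optionally force `r1`.
#' @return Continuous proposal vector.
#' @export
explore_step <- function(hawk, rand_hawk, seed = NULL, r1 = NULL) {
  if (length(hawk) != length(rand_hawk))
    stop_bad_arg("hawk and rand_hawk must have equal length")
  if (is.null(r1)) r1 <- with_seed(seed, stats::runif(1))
  hawk + r1 * abs(hawk - rand_hawk)
}

#' Exploitation step (continuous proposal)
#'
#' `X_best - E |J X_best - X|` with jump strength `J = 2(1 - r)`,
#' `r ~ U[0, 1]`. At `E = 0` the proposal is exactly `X_best`.
#'
#' @param hawk Current position vector.
#' @param best Best position found so far.
#' @param E Escape energy.
#' @param seed Optional seed for the `J` draw.
#' @param J Optionally force the jump strength.
#' @return Continuous proposal vector.
#' @export
exploit_step <- function(hawk, best, E, seed = NULL, J = NULL) {
  if (is.null(best)) stop_bad_arg("`best` is not set")
  if (length(hawk) != length(best))
    stop_bad_arg("hawk and best must have equal length")
  check_number(E, "E")
  if (is.null(J)) J <- with_seed(seed, 2 * (1 - stats::runif(1)))
  best - E * abs(J * best - hawk)
}

# Stochastic logistic binarization using the current RNG stream.
binarize_draw <- function(position, threshold) {
  p <- logistic(position - threshold)
  bits <- as.integer(stats::runif(length(p)) < p)
  if (sum(bits) == 0L) {
    bits <- as.integer(stats::runif(length(p)) < p)
    if (sum(bits) == 0L) bits[which.max(p)] <- 1L
  }
  bits
}

#' Binarize a continuous position into a feature mask
#'
#' Bit i is set with probability `logistic(position_i - threshold)` (an
#' S-shaped stochastic transfer function). An all-zero draw is redrawn once;
#' if still empty, the single most probable bit is forced on, so an
#' evaluated mask always selects at least one feature.
#'
#' @param position Finite continuous position vector.
#' @param cfg An [hho_config()] (supplies the threshold).
#' @param seed Optional seed for the draw.
#' @return Integer vector of bits.
#' @export
binarize <- function(position, cfg = hho_config(), seed = NULL) {
  if (!all(is.finite(position))) stop_bad_arg("`position` must be finite")
  with_seed(seed, binarize_draw(position, cfg$binarize_threshold))
}

#' Build a cached cross-validated accuracy fitness function
#'
#' Returns `f(bits) -> accuracy`: the mean accuracy of the configured
#' classifier over `fitness_cv_folds` internal stratified folds of the
#' supplied (training) data, using only the selected columns. Results are
#' cached by bit pattern; `attr(f, "env")$n_evals` counts distinct
#' evaluations. Folds are drawn once (from `cfg$seed`) so the fitness is a
#' deterministic function of the mask.
#'
#' @param x Feature matrix (training data only).
#' @param y Class labels (>= 2 classes).
#' @param cfg An [hho_config()].
#' @return The fitness closure.
#' @export
hho_fitness_fn <- function(x, y, cfg = hho_config()) {
  if (!is.matrix(x)) stop_bad_arg("`x` must be a matrix")
  y <- as.integer(factor(y))
  if (length(unique(y)) < 2L) stop_bad_arg("need >= 2 classes for fitness")
  plan <- make_folds(y, k = cfg$fitness_cv_folds, seed = cfg$seed + 7L)
  env <- new.env(parent = emptyenv())
  env$cache <- new.env(parent = emptyenv())
  env$n_evals <- 0L
  f <- function(bits) {
    if (sum(bits) == 0L) stop_bad_arg("cannot evaluate an empty mask")
    key <- paste(bits, collapse = "")
    hit <- get0(key, envir = env$cache, inherits = FALSE)
    if (!is.null(hit)) return(hit)
    env$n_evals <- env$n_evals + 1L
    cols <- which(bits == 1L)
    accs <- vapply(plan$folds, function(te) {
      tr <- setdiff(seq_along(y), te)
      xtr <- x[tr, cols, drop = FALSE]; xte <- x[te, cols, drop = FALSE]
      pred <- if (cfg$fitness_classifier == "xgboost") {
        bcfg <- booster_config(learning_rate = cfg$fitness_eta,
                               max_depth = cfg$fitness_depth,
                               n_trees = cfg$fitness_nrounds,
                               reg_lambda = 1, seed = cfg$seed)
        m <- fit_classifier(xtr, y[tr], bcfg)
        predict(m, xte)$class
      } else {
        fit_logistic_clf(xtr, y[tr], seed = cfg$seed)(xte)$class
      }
      mean(pred == y[te])
    }, numeric(1))
    val <- mean(accs)
    assign(key, val, envir = env$cache)
    val
  }
  attr(f, "env") <- env
  f
}

# Elitist comparison: is (f_new, k_new) better than (f_old, k_old)?
hho_better <- function(f_new, k_new, f_old, k_old, tie_fewer) {
  if (f_new > f_old) return(TRUE)
  if (tie_fewer && f_new == f_old && k_new < k_old) return(TRUE)
  FALSE
}

#' Run binary Harris Hawks feature selection
#'
#' Per iteration each hawk draws its escape energy and takes an exploration
#' step (|E| >= 1) or an exploitation step toward the best mask (|E| < 1);
#' the binarized proposal replaces the hawk only if its fitness improves
#' (ties going to the sparser mask), and the best-so-far mask is updated the
#' same way, so the best-fitness trace is non-decreasing. Deterministic
#' under `cfg$seed`.
#'
#' @param x Feature matrix (ignored when `fitness_fn` is given).
#' @param y Labels (ignored when `fitness_fn` is given).
#' @param cfg An [hho_config()].
#' @param fitness_fn Optional custom fitness `f(bits) -> value in [0, 1]`
#'   (e.g. a toy objective); by default [hho_fitness_fn()] on `x`, `y`.
#' @param d Number of features (required with a custom `fitness_fn`).
#' @param feature_variances Per-feature variances for the initialization
#'   bias; defaults to `apply(x, 2, var)` or all-equal for custom fitness.
#' @return An object of class `hho_result`: `best_mask` (bits),
#'   `best_fitness`, `selected` (column indices), `trace` (best fitness per
#'   iteration, non-decreasing), and `n_evaluations`.
#' @export
run_hho <- function(x = NULL, y = NULL, cfg = hho_config(),
                    fitness_fn = NULL, d = NULL,
                    feature_variances = NULL) {
  if (!inherits(cfg, "hho_config")) stop_bad_arg("`cfg` must be hho_config")
  if (is.null(fitness_fn)) {
    if (is.null(x) || is.null(y))
      stop_bad_arg("provide `x` and `y`, or a custom `fitness_fn` with `d`")
    fitness_fn <- hho_fitness_fn(x, y, cfg)
    d <- ncol(x)
    if (is.null(feature_variances))
      feature_variances <- apply(x, 2L, stats::var)
  }
  if (is.null(d)) stop_bad_arg("`d` is required with a custom fitness_fn")
  check_number(d, "d", lower = 1, integer = TRUE)
  if (is.null(feature_variances)) feature_variances <- rep(1, d)
  probs <- variance_inclusion_probs(feature_variances)
  P <- cfg$pop_size; T_iter <- cfg$iterations
  with_seed(cfg$seed, {
    pop <- draw_population(d, probs, P)
    fit <- apply(pop, 1L, fitness_fn)
    nsel <- rowSums(pop)
    bi <- order(-fit, nsel)[1L]
    best_bits <- pop[bi, ]; best_fit <- fit[bi]; best_k <- nsel[bi]
    trace <- numeric(T_iter)
    for (t in seq_len(T_iter)) {
      for (j in seq_len(P)) {
        E <- 2 * stats::runif(1, -1, 1) * (1 - t / T_iter)
        pos <- if (abs(E) >= 1) {
          rnd <- pop[sample.int(P, 1L), ]
          pop[j, ] + stats::runif(1) * abs(pop[j, ] - rnd)
        } else {
          J <- 2 * (1 - stats::runif(1))
          best_bits - E * abs(J * best_bits - pop[j, ])
        }
        bits <- binarize_draw(pos, cfg$binarize_threshold)
        f <- fitness_fn(bits)
        k <- sum(bits)
        if (hho_better(f, k, fit[j], nsel[j], cfg$tie_break_fewer)) {
          pop[j, ] <- bits; fit[j] <- f; nsel[j] <- k
        }
        if (hho_better(f, k, best_fit, best_k, cfg$tie_break_fewer)) {
          best_bits <- bits; best_fit <- f; best_k <- k
        }
      }
      trace[t] <- best_fit
    }
    env <- attr(fitness_fn, "env")
    structure(list(best_mask = best_bits, best_fitness = best_fit,
                   selected = which(best_bits == 1L), trace = trace,
                   n_evaluations = if (!is.null(env)) env$n_evals
                                   else NA_integer_),
              class = "hho_result")
  })
}

#' @export
print.hho_result <- function(x, ...) {
  cat(sprintf("HHO: %d/%d features selected, fitness %.4f (%s evaluations)\n",
              length(x$selected), length(x$best_mask), x$best_fitness,
              ifelse(is.na(x$n_evaluations), "?", x$n_evaluations)))
  invisible(x)
}
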