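#' @keywords internal
"_PACKAGE"

# Internal validation helpers ------------------------------------------------

stop_bad_arg <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         integer = FALSE, strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_bad_arg("`%s` must be a single finite number", name)
  if (integer && x != round(x))
    stop_bad_arg("`%s` must be an integer", name)
  if (strict_lower) {
    if (x <= lower) stop_bad_arg("`%s` must be > %s", name, lower)
  } else if (x < lower) {
    stop_bad_arg("`%s` must be >= %s", name, lower)
  }
  if (x > upper) stop_bad_arg("`%s` must be <= %s", name, upper)
  invisible(x)
}

check_image <- function(img, name = "img") {
  if (!is.matrix(img) || !is.numeric(img) || length(img) == 0L)
    stop_bad_arg("`%s` must be a non-empty numeric matrix", name)
  if (!all(is.finite(img)))
    stop_bad_arg("`%s` must contain only finite values", name)
  invisible(img)
}

check_normalized <- function(img, name = "img") {
  check_image(img, name)
  rng <- range(img)
  if (rng[1] < -1e-9 || rng[2] > 1 + 1e-9)
    stop_bad_arg("`%s` must be normalized to [0, 1]; got range [%g, %g]",
                 name, rng[1], rng[2])
  invisible(img)
}

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv()))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  expr
}

logistic <- function(x) 1 / (1 + exp(-x))

# Row-wise numerically stable softmax of a matrix.
softmax_rows <- function(m) {
  m <- m - apply(m, 1L, max)
  e <- exp(m)
  e / rowSums(e)
}
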