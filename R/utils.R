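# Internal helpers: argument checks, seeded RNG scoping, small geometry utils.

stop_arg <- function(...) stop(..., call. = FALSE)

check_number <- function(x, name, positive = FALSE, nonneg = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_arg(sprintf("`%s` must be a single finite number", name))
  if (positive && x <= 0) stop_arg(sprintf("`%s` must be > 0", name))
  if (nonneg && x < 0) stop_arg(sprintf("`%s` must be >= 0", name))
  invisible(x)
}

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# RNG state (generation stays bit-reproducible for a fixed seed).
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

# Skew-symmetric cross-product matrix: skew(a) %*% b == a x b
skew <- function(a) {
  matrix(c(0, a[3], -a[2],
           -a[3], 0, a[1],
           a[2], -a[1], 0), 3, 3)
}

vnorm <- function(x) sqrt(sum(x^2))

`%||%` <- function(a, b) if (is.null(a)) b else a
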