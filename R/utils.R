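#' @keywords internal
"_PACKAGE"

# Run `code` under a fixed RNG seed, restoring the caller's RNG state on exit.
# seed = NULL leaves the current stream untouched.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Trapezoid rule on a (possibly non-uniform) grid.
trapz <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(0)
  sum((y[-1] + y[-n]) / 2 * diff(x))
}

# Squared Euclidean distance matrix via BLAS (fast for n in the thousands).
pairwise_d2 <- function(x, y) {
  X <- cbind(x, y)
  s <- rowSums(X^2)
  d2 <- outer(s, s, "+") - 2 * tcrossprod(X)
  d2[d2 < 0] <- 0
  d2
}

stop_if_not_scalar_pos <- function(x, name, allow_zero = FALSE) {
  ok <- is.numeric(x) && length(x) == 1L && is.finite(x) &&
    (x > 0 || (allow_zero && x >= 0))
  if (!ok) stop(sprintf("'%s' must be a single %s number", name,
                        if (allow_zero) "non-negative" else "positive"),
                call. = FALSE)
  invisible(x)
}
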