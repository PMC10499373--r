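#' Numerically stable log-sum-exp
#'
#' Computes `log(sum(exp(x)))` without overflow or underflow by shifting by
#' the maximum. Used throughout the WAIC machinery so that log predictive
#' densities of extreme magnitude never pass through raw exponentials.
#'
#' @param x Numeric vector of log-scale values. May contain `-Inf`.
#' @return A single numeric value, `log(sum(exp(x)))`.
#' @examples
#' log_sum_exp(c(-1000, -1000)) # == -1000 + log(2), exactly
#' @export
log_sum_exp <- function(x) {
  if (length(x) == 0L) return(-Inf)
  m <- max(x)
  if (!is.finite(m)) return(m) # all -Inf (or an Inf/NaN propagates)
  m + log(sum(exp(x - m)))
}

#' Row-wise log-sum-exp of a matrix
#'
#' @param x Numeric matrix; the reduction runs over columns within each row.
#' @return Numeric vector with one value per row.
#' @keywords internal
row_log_sum_exp <- function(x) {
  m <- apply(x, 1L, max)
  finite <- is.finite(m)
  out <- m
  if (any(finite)) {
    xs <- x[finite, , drop = FALSE] - m[finite]
    out[finite] <- m[finite] + log(rowSums(exp(xs)))
  }
  out
}

#' Simpson's rule weights
#'
#' Composite Simpson weights for `n` equally spaced nodes (n odd, >= 3).
#' The returned weights already include the h/3 factor, so the integral is
#' `sum(w * f(x))` for nodes spanning `[a, b]`.
#'
#' @param n Odd number of nodes.
#' @param a,b Integration limits.
#' @return Numeric vector of length `n`.
#' @keywords internal
simpson_weights <- function(n, a, b) {
  if (n < 3L || n %% 2L == 0L) {
    stop("Simpson's rule requires an odd number of nodes >= 3, got ", n)
  }
  h <- (b - a) / (n - 1L)
  w <- rep(c(2, 4), length.out = n)
  w[1L] <- 1
  w[n] <- 1
  w * h / 3
}

# Derive a reproducible per-stream seed from a root seed. The splitting rule
# is fixed (documented here and in the vignette): stream k gets
# (root * 48271 + k * 2654435769) mod (2^31 - 1), i.e. a multiplicative hash
# that keeps streams stable when later streams are added.
split_seed <- function(root_seed, stream) {
  root_seed <- as.double(root_seed)
  stream <- as.double(stream)
  as.integer((root_seed * 48271 + stream * 2654435769) %% 2147483647)
}

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's RNG state afterwards.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopifnot_scalar_number <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop("'", name, "' must be a single finite number")
  }
  if (positive && x <= 0) stop("'", name, "' must be > 0")
  invisible(x)
}
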