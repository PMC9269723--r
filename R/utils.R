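`%||%` <- function(x, y) if (is.null(x)) y else x

#' Standard gravity used throughout the package (m/s^2)
#' @keywords internal
GRAVITY <- 9.81

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

deg <- function(rad) rad * 180 / pi
rad <- function(deg) deg * pi / 180

# trapezoidal integral of y sampled uniformly at rate fs
trapz_uniform <- function(y, fs) {
  n <- length(y)
  if (n < 2) return(0)
  sum(y[-1] + y[-n]) / (2 * fs)
}

# row-wise cross product of n x 3 matrices (recycling a single row)
cross3 <- function(a, b) {
  if (is.null(dim(a))) a <- matrix(a, nrow = 1)
  if (is.null(dim(b))) b <- matrix(b, nrow = 1)
  n <- max(nrow(a), nrow(b))
  if (nrow(a) == 1 && n > 1) a <- a[rep(1, n), , drop = FALSE]
  if (nrow(b) == 1 && n > 1) b <- b[rep(1, n), , drop = FALSE]
  cbind(
    a[, 2] * b[, 3] - a[, 3] * b[, 2],
    a[, 3] * b[, 1] - a[, 1] * b[, 3],
    a[, 1] * b[, 2] - a[, 2] * b[, 1]
  )
}

# derive a reproducible 32-bit sub-seed from a base seed and integer tags
derive_seed <- function(seed, ...) {
  tags <- c(...)
  s <- as.double(seed) %% 2147483647
  for (t in tags) s <- (s * 69069 + as.double(t) * 104729 + 12345) %% 2147483647
  as.integer(s)
}

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}
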