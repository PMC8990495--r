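# Internal numerical helpers shared across the package.

#' @keywords internal
#' @noRd
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Fast row-wise maximum (apply(x, 1, max) without the apply overhead).
#' @noRd
row_max <- function(x) {
  m <- x[, 1L]
  for (k in seq_len(ncol(x))[-1L]) m <- pmax(m, x[, k])
  m
}

# Row-wise logsumexp of a matrix.
#' @noRd
row_logsumexp <- function(x) {
  m <- row_max(x)
  m[!is.finite(m)] <- 0
  m + log(rowSums(exp(x - m)))
}

# Evaluate a block of code with a temporary RNG state seeded at `seed`,
# restoring the caller's state afterwards. All stochastic operations in the
# package funnel through this so that seeds are explicit arguments and no
# global state leaks.
#' @noRd
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Derive a stream of child seeds from one parent seed, keeping them within
# 32-bit integer range.
#' @noRd
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

# log density of bivariate normals for a matrix of points (n x 2).
#' @noRd
dmvnorm2_log <- function(x, mean, sigma) {
  ch <- chol(sigma)
  z <- forwardsolve(t(ch), t(x) - mean)
  -log(2 * pi) - sum(log(diag(ch))) - 0.5 * colSums(z^2)
}

# Draw n bivariate normal deviates by Cholesky transform.
#' @noRd
rmvnorm2 <- function(n, mean, sigma) {
  z <- matrix(stats::rnorm(2L * n), ncol = 2L)
  sweep(z %*% chol(sigma), 2L, mean, `+`)
}

#' @noRd
is_spd2 <- function(m, tol = 0) {
  is.matrix(m) && all(dim(m) == 2L) && all(is.finite(m)) &&
    isTRUE(all.equal(m, t(m), tolerance = 1e-8)) &&
    min(eigen(m, symmetric = TRUE, only.values = TRUE)$values) > tol
}

# Shannon entropy of a probability vector, base-2 by default, 0*log0 := 0.
#' @noRd
entropy_vec <- function(p, base = 2) {
  p <- p[p > 0]
  h <- -sum(p * log(p)) / log(base)
  h + 0   # avoid returning negative zero
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a
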