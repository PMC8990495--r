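# Scaled forward-backward recursions shared by the variational Bayesian EM
# fitter and the hierarchical-EM clustering routine.
#
# Sequences are processed in groups of equal length so the recursions can be
# vectorised across sequences: within a group, alpha and beta are S x K
# matrices updated by one K x K matrix product per time step. Emission
# weights are rescaled once per call (row maximum subtracted in log space);
# the per-sequence scale totals are added back to the log normalisers.

# Split sequence indices by length.
#' @noRd
length_groups <- function(lens) split(seq_along(lens), lens)

# Rescaled emission weights shared by both passes.
#' @noRd
scale_emissions <- function(logB) {
  mx <- row_max(logB)
  mx[!is.finite(mx)] <- 0
  list(B = exp(logB - mx), mx = mx)
}

# Forward-backward over a set of sequences under (possibly subnormalised)
# initial weights `pi0` and transition weights `A`, with per-fixation
# emission log-weights `logB` (N x K, rows in sequence order) and optional
# per-sequence weights `w` applied to the aggregated transition statistics.
#
# Returns:
#   gamma  N x K posterior state weights per fixation (rows sum to 1)
#   xi     K x K sum over sequences/times of pairwise posteriors, weighted by w
#   gamma1 S x K posterior over the first state per sequence
#   logz   length-S log normalisers (the log-likelihood when pi0/A are proper)
#' @noRd
forward_backward_r <- function(pi0, A, logB, lens, w = NULL) {
  K <- length(pi0)
  S <- length(lens)
  if (is.null(w)) w <- rep(1, S)
  starts <- cumsum(c(0L, lens[-S]))            # 0-based row offset per sequence
  em <- scale_emissions(logB)
  gamma <- matrix(0, nrow(logB), K)
  xi <- matrix(0, K, K)
  gamma1 <- matrix(0, S, K)
  logz <- rowsum(em$mx, rep.int(seq_len(S), lens))[, 1L]
  tA <- t(A)
  for (grp in length_groups(lens)) {
    Tg <- lens[grp[1L]]
    Sg <- length(grp)
    wg <- w[grp]
    idx <- outer(starts[grp], seq_len(Tg), `+`)  # Sg x Tg fixation row indices
    alpha <- vector("list", Tg)
    Bt <- lapply(seq_len(Tg), function(t) em$B[idx[, t], , drop = FALSE])
    cc <- matrix(0, Sg, Tg)
    a <- Bt[[1L]] * rep(pi0, each = Sg)
    cc[, 1L] <- rowSums(a)
    alpha[[1L]] <- a / cc[, 1L]
    if (Tg > 1L) for (t in 2L:Tg) {
      a <- (alpha[[t - 1L]] %*% A) * Bt[[t]]
      cc[, t] <- rowSums(a)
      alpha[[t]] <- a / cc[, t]
    }
    logz[grp] <- logz[grp] + rowSums(log(cc))
    beta <- matrix(1, Sg, K)
    gamma[idx[, Tg], ] <- alpha[[Tg]]
    if (Tg > 1L) for (t in (Tg - 1L):1L) {
      wB <- (Bt[[t + 1L]] * beta) / cc[, t + 1L]           # Sg x K
      xi <- xi + A * crossprod(alpha[[t]] * wg, wB)
      beta <- wB %*% tA
      g <- alpha[[t]] * beta
      gamma[idx[, t], ] <- g / rowSums(g)
    }
    gamma1[grp, ] <- gamma[idx[, 1L], , drop = FALSE]
  }
  list(gamma = gamma, xi = xi, gamma1 = gamma1, logz = logz)
}

# Forward pass only: per-sequence log normalisers (used where only the
# likelihoods are needed, e.g. cluster responsibilities and A-B scoring).
#' @noRd
forward_logz_r <- function(pi0, A, logB, lens) {
  K <- length(pi0)
  S <- length(lens)
  starts <- cumsum(c(0L, lens[-S]))
  em <- scale_emissions(logB)
  logz <- rowsum(em$mx, rep.int(seq_len(S), lens))[, 1L]
  for (grp in length_groups(lens)) {
    Tg <- lens[grp[1L]]
    Sg <- length(grp)
    idx <- outer(starts[grp], seq_len(Tg), `+`)
    lz <- numeric(Sg)
    alpha <- NULL
    for (t in seq_len(Tg)) {
      B <- em$B[idx[, t], , drop = FALSE]
      a <- if (t == 1L) B * rep(pi0, each = Sg) else (alpha %*% A) * B
      cc <- rowSums(a)
      alpha <- a / cc
      lz <- lz + log(cc)
    }
    logz[grp] <- logz[grp] + lz
  }
  logz
}

# Fast C++ entry points (identical contracts to the reference R versions
# above, which are retained for cross-checking in the test suite).
#' @noRd
forward_backward <- function(pi0, A, logB, lens, w = NULL) {
  if (is.null(w)) w <- rep(1, length(lens))
  .fb_cpp(as.numeric(pi0), A, logB, as.integer(lens), as.numeric(w))
}

#' @noRd
forward_logz <- function(pi0, A, logB, lens) {
  .forward_logz_cpp(as.numeric(pi0), A, logB, as.integer(lens))
}
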