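# Independent oracles and small fixtures used across the suite.

log_sum_exp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}

bvnorm_logdens <- function(x, mean, sigma) {
  # direct bivariate normal log density (no shared code with the package)
  d <- x - mean
  -log(2 * pi) - 0.5 * log(det(sigma)) -
    0.5 * drop(t(d) %*% solve(sigma) %*% d)
}

# Brute-force log-likelihood by full enumeration of hidden-state paths.
brute_force_loglik <- function(model, xy) {
  K <- model$n_rois
  n <- nrow(xy)
  paths <- as.matrix(expand.grid(rep(list(seq_len(K)), n)))
  lp <- apply(paths, 1L, function(p) {
    l <- log(model$prior[p[1]]) +
      bvnorm_logdens(xy[1, ], model$means[p[1], ], model$covariances[[p[1]]])
    if (n > 1L) for (t in 2:n)
      l <- l + log(model$transitions[p[t - 1], p[t]]) +
        bvnorm_logdens(xy[t, ], model$means[p[t], ], model$covariances[[p[t]]])
    l
  })
  log_sum_exp(lp)
}

# Brute-force most probable path (first of the maximisers in row-major
# enumeration order, which matches the lower-index tie rule).
brute_force_decode <- function(model, xy) {
  K <- model$n_rois
  n <- nrow(xy)
  paths <- as.matrix(expand.grid(rep(list(seq_len(K)), n)))
  lp <- apply(paths, 1L, function(p) {
    l <- log(model$prior[p[1]]) +
      bvnorm_logdens(xy[1, ], model$means[p[1], ], model$covariances[[p[1]]])
    if (n > 1L) for (t in 2:n)
      l <- l + log(model$transitions[p[t - 1], p[t]]) +
        bvnorm_logdens(xy[t, ], model$means[p[t], ], model$covariances[[p[t]]])
    l
  })
  unname(paths[which.max(lp), ])
}

# Random valid model with K states (well-conditioned covariances).
random_model <- function(K, spread = 80) {
  prior <- as.numeric(rdirichlet1(K))
  trans <- t(vapply(seq_len(K), function(i) rdirichlet1(K), numeric(K)))
  means <- matrix(stats::runif(2 * K, -spread, spread), ncol = 2)
  covs <- lapply(seq_len(K), function(i) {
    a <- matrix(stats::rnorm(4, sd = 0.3), 2)
    diag(stats::runif(2, 50, 400)) + a %*% t(a)
  })
  gaussian_hmm(prior, trans, means, covs)
}

rdirichlet1 <- function(K) {
  g <- stats::rgamma(K, shape = 1) + 1e-6
  g / sum(g)
}

# Well-separated 3-ROI generator used by the recovery suites.
three_roi_truth <- function() {
  gaussian_hmm(c(1, 0, 0),
               rbind(c(.1, .6, .3), c(.2, .1, .7), c(.5, .4, .1)),
               rbind(c(0, 0), c(0, 120), c(120, 0)),
               rep(list(diag(2) * 64), 3))
}

# Match estimated states to true states by greedy nearest ROI center.
match_states <- function(est_means, true_means) {
  K <- nrow(true_means)
  perm <- integer(K)
  left <- seq_len(nrow(est_means))
  for (k in seq_len(K)) {
    d <- sqrt(rowSums((est_means[left, , drop = FALSE] -
                         matrix(true_means[k, ], length(left), 2,
                                byrow = TRUE))^2))
    perm[k] <- left[which.min(d)]
    left <- setdiff(left, perm[k])
    if (!length(left)) break
  }
  perm
}
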