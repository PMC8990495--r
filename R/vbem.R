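# Variational Bayesian EM for Gaussian-emission hidden Markov models.
#
# Conjugate priors: Dirichlet on the initial-state vector and on each
# transition row, Normal-Wishart on each ROI's (mean, precision). The E-step
# runs forward-backward with geometric-mean parameters (exponentiated
# expected logs); the variational lower bound is the sum of the resulting
# log normalisers minus the Dirichlet and Normal-Wishart KL terms, and is
# non-decreasing across iterations. The lower bound also scores the number
# of ROIs, so model selection needs no separate criterion.

#' Hyperparameters for variational Bayesian HMM fitting
#'
#' Weakly informative defaults: ROI mean prior at the face center with small
#' strength, covariance prior scaled to a quarter of the face box, and unit
#' Dirichlet concentrations on the initial-state vector and transition rows.
#'
#' @param mean_prior_center Prior ROI center, face-centered pixels.
#' @param mean_prior_strength Pseudo-count strength of the mean prior
#'   (> 0; small values leave ROI centers data-driven).
#' @param covariance_prior_scale 2 x 2 positive-definite matrix giving the
#'   typical prior ROI covariance. Default `diag((face_box / 4)^2)`.
#' @param covariance_prior_dof Wishart degrees of freedom (> 1).
#' @param dirichlet_concentration_prior Concentration applied to the prior
#'   vector and to each transition row (> 0).
#' @param face_box Width/height of the face region in pixels, used only to
#'   build the default covariance scale.
#' @return A list of class `"vb_hyper"`.
#' @export
#' @examples
#' h <- vb_hyper()
#' h$covariance_prior_scale
vb_hyper <- function(mean_prior_center = c(0, 0),
                     mean_prior_strength = 0.01,
                     covariance_prior_scale = NULL,
                     covariance_prior_dof = 5,
                     dirichlet_concentration_prior = 1,
                     face_box = c(256, 256)) {
  if (is.null(covariance_prior_scale))
    covariance_prior_scale <- diag((face_box / 4)^2)
  stopifnot(mean_prior_strength > 0, covariance_prior_dof > 1,
            dirichlet_concentration_prior > 0,
            is_spd2(covariance_prior_scale))
  structure(list(mean_prior_center = as.numeric(mean_prior_center),
                 mean_prior_strength = mean_prior_strength,
                 covariance_prior_scale = covariance_prior_scale,
                 covariance_prior_dof = covariance_prior_dof,
                 dirichlet_concentration_prior = dirichlet_concentration_prior),
            class = "vb_hyper")
}

# KL(Dirichlet(a) || Dirichlet(a0)), elementwise concentration vectors.
#' @noRd
kl_dirichlet <- function(a, a0) {
  sa <- sum(a)
  lgamma(sa) - sum(lgamma(a)) - lgamma(sum(a0)) + sum(lgamma(a0)) +
    sum((a - a0) * (digamma(a) - digamma(sa)))
}

# Multivariate digamma / log-gamma, d = 2.
#' @noRd
mvdigamma2 <- function(a) digamma(a) + digamma(a - 0.5)
#' @noRd
mvlgamma2 <- function(a) 0.5 * log(pi) + lgamma(a) + lgamma(a - 0.5)

# KL(NW(m, beta, W, nu) || NW(m0, beta0, W0, nu0)) for d = 2.
#' @noRd
kl_normal_wishart <- function(m, beta, W, nu, m0, beta0, W0, nu0) {
  d <- 2
  dm <- m - m0
  quad <- drop(crossprod(dm, W %*% dm))
  kl_gauss <- 0.5 * (d * log(beta / beta0) - d + d * beta0 / beta +
                       beta0 * nu * quad)
  W0invW <- solve(W0, W)
  kl_wish <- -(nu0 / 2) * determinant(W0invW, logarithm = TRUE)$modulus +
    (nu / 2) * (sum(diag(W0invW)) - d) +
    mvlgamma2(nu0 / 2) - mvlgamma2(nu / 2) +
    ((nu - nu0) / 2) * mvdigamma2(nu / 2)
  kl_gauss + as.numeric(kl_wish)
}

# Expected emission log densities under q(mu, Lambda): N x K matrix.
# Bishop-style: E[log N(x | mu_k, Lambda_k^-1)].
#' @noRd
vb_emission_logdens <- function(X, post) {
  K <- length(post$beta)
  out <- matrix(0, nrow(X), K)
  for (k in seq_len(K)) {
    elogdet <- mvdigamma2(post$nu[k] / 2) + 2 * log(2) +
      determinant(post$W[[k]], logarithm = TRUE)$modulus
    xc <- sweep(X, 2L, post$m[k, ])
    quad <- rowSums((xc %*% post$W[[k]]) * xc)
    out[, k] <- 0.5 * as.numeric(elogdet) - log(2 * pi) -
      0.5 * (2 / post$beta[k] + post$nu[k] * quad)
  }
  out
}

# M-step: update the variational posterior from expected sufficient stats.
#' @noRd
vb_mstep <- function(X, gamma, gamma1, xi, hyper, K) {
  a0 <- hyper$dirichlet_concentration_prior
  b0 <- hyper$mean_prior_strength
  m0 <- hyper$mean_prior_center
  nu0 <- hyper$covariance_prior_dof
  W0inv <- hyper$covariance_prior_scale * nu0   # so E[Lambda] = scale^-1
  Nk <- colSums(gamma)
  post <- list(alpha = a0 + colSums(gamma1),
               eps = a0 + xi,
               beta = b0 + Nk, nu = nu0 + Nk,
               m = matrix(0, K, 2), W = vector("list", K), Nk = Nk)
  for (k in seq_len(K)) {
    if (Nk[k] > 0) {
      xbar <- colSums(X * gamma[, k]) / Nk[k]
      xc <- sweep(X, 2L, xbar)
      Sk <- crossprod(xc * gamma[, k], xc)
      dm <- xbar - m0
      Winv <- W0inv + Sk + (b0 * Nk[k] / (b0 + Nk[k])) * tcrossprod(dm)
    } else {
      xbar <- m0
      Winv <- W0inv
    }
    post$m[k, ] <- (b0 * m0 + Nk[k] * xbar) / (b0 + Nk[k])
    post$W[[k]] <- solve((Winv + t(Winv)) / 2)
  }
  post
}

# Lower bound given the E-step log normalisers under the current posterior.
#' @noRd
vb_lower_bound <- function(logz, post, hyper, K) {
  a0 <- hyper$dirichlet_concentration_prior
  nu0 <- hyper$covariance_prior_dof
  W0 <- solve(hyper$covariance_prior_scale * nu0)
  kl <- kl_dirichlet(post$alpha, rep(a0, K))
  for (i in seq_len(K))
    kl <- kl + kl_dirichlet(post$eps[i, ], rep(a0, K))
  for (k in seq_len(K))
    kl <- kl + kl_normal_wishart(post$m[k, ], post$beta[k], post$W[[k]],
                                 post$nu[k], hyper$mean_prior_center,
                                 hyper$mean_prior_strength, W0, nu0)
  sum(logz) - kl
}

# One full VBEM run from a given initialisation; returns posterior, bound
# trace, and convergence flag.
#' @noRd
vbem_run <- function(X, lens, K, hyper, init_centers, max_iter, tol) {
  # initial hard-ish responsibilities from nearest initial center
  if (K == 1L) {
    gamma <- matrix(1, nrow(X), 1L)
  } else {
    d2 <- vapply(seq_len(K), function(k)
      rowSums(sweep(X, 2L, init_centers[k, ])^2), numeric(nrow(X)))
    nearest <- max.col(-d2, ties.method = "first")
    gamma <- matrix(0.5 / (K - 1), nrow(X), K)
    gamma[cbind(seq_len(nrow(X)), nearest)] <- 0.5
    gamma <- gamma / rowSums(gamma)
  }
  S <- length(lens)
  first_rows <- cumsum(c(1L, lens[-S]))
  gamma1 <- gamma[first_rows, , drop = FALSE]
  if (S == 1L) gamma1 <- matrix(gamma1, 1L, K)
  xi <- crossprod(gamma[-nrow(gamma), , drop = FALSE],
                  gamma[-1L, , drop = FALSE]) + 1e-3
  post <- vb_mstep(X, gamma, gamma1, xi, hyper, K)
  bounds <- numeric(0)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    pi_t <- exp(digamma(post$alpha) - digamma(sum(post$alpha)))
    A_t <- exp(digamma(post$eps) - digamma(rowSums(post$eps)))
    logB <- vb_emission_logdens(X, post)
    fb <- forward_backward(pi_t, A_t, logB, lens)
    lb <- vb_lower_bound(fb$logz, post, hyper, K)
    bounds <- c(bounds, lb)
    if (it > 1L && abs(lb - bounds[it - 1L]) < tol) { converged <- TRUE; break }
    post <- vb_mstep(X, fb$gamma, fb$gamma1, fb$xi, hyper, K)
  }
  list(post = post, bounds = bounds, lower_bound = bounds[length(bounds)],
       converged = converged)
}

# Point-estimate model from the variational posterior, pruning ROIs whose
# expected occupancy is below `prune_tol` fixations.
#' @noRd
vb_point_estimate <- function(post, prune_tol = 1e-3) {
  keep <- which(post$Nk >= prune_tol)
  if (length(keep) == 0L) keep <- which.max(post$Nk)
  prior <- post$alpha[keep] / sum(post$alpha[keep])
  trans <- post$eps[keep, keep, drop = FALSE]
  trans <- trans / rowSums(trans)
  covs <- lapply(keep, function(k) {
    sig <- solve(post$W[[k]]) / (post$nu[k] - 3)   # E[Sigma], d = 2
    (sig + t(sig)) / 2
  })
  gaussian_hmm(prior, trans, post$m[keep, , drop = FALSE], covs)
}

#' Fit an HMM to fixation sequences by variational Bayesian EM
#'
#' Runs `n_restarts` independently initialised VBEM fits and returns the one
#' with the highest variational lower bound. The returned model is the
#' posterior point estimate (posterior mean parameters); ROIs with expected
#' occupancy below `prune_tol` fixations are pruned, so the effective number
#' of ROIs can be smaller than `n_rois`.
#'
#' @param seqs List of `fixseq` objects (or position matrices).
#' @param n_rois Requested number of ROIs K (1-10).
#' @param hyper A [vb_hyper()] object.
#' @param n_restarts Number of random restarts (>= 1).
#' @param seed Integer seed; identical inputs and seed reproduce the fit
#'   exactly.
#' @param max_iter,tol Convergence controls: stop when the lower-bound change
#'   drops below `tol` or after `max_iter` iterations.
#' @param prune_tol Expected-occupancy threshold below which an ROI is
#'   dropped from the reported model.
#' @return A list of class `"hmm_fit"`: `model`, `lower_bound` (nats),
#'   `n_rois_selected`, `n_restarts_used`, `converged`, `seed`, and the
#'   per-iteration `bound_trace` of the winning restart.
#' @export
fit_vbem <- function(seqs, n_rois, hyper = vb_hyper(), n_restarts = 5,
                     seed = 1, max_iter = 300, tol = 1e-6,
                     prune_tol = 1e-3) {
  if (length(seqs) < 1L) stop("need at least one sequence")
  if (n_rois < 1L || n_rois > 10L) stop("n_rois must be between 1 and 10")
  if (n_restarts < 1L) stop("n_restarts must be at least 1")
  xy <- lapply(seqs, fix_xy)
  lens <- vapply(xy, nrow, integer(1))
  X <- do.call(rbind, xy)
  if (nrow(X) < n_rois)
    stop("total fixation count (", nrow(X), ") below n_rois (", n_rois, ")")
  seeds <- derive_seeds(seed, n_restarts)
  best <- NULL
  for (r in seq_len(n_restarts)) {
    centers <- with_seed(seeds[r], {
      X[sample.int(nrow(X), n_rois), , drop = FALSE] +
        matrix(stats::rnorm(2L * n_rois, sd = 1e-3), ncol = 2L)
    })
    run <- vbem_run(X, lens, n_rois, hyper, centers, max_iter, tol)
    if (is.null(best) || run$lower_bound > best$lower_bound + 1e-12) best <- run
  }
  model <- vb_point_estimate(best$post, prune_tol)
  structure(list(model = model, lower_bound = best$lower_bound,
                 n_rois_selected = model$n_rois,
                 n_restarts_used = n_restarts,
                 converged = best$converged, seed = seed,
                 bound_trace = best$bounds),
            class = "hmm_fit")
}

#' @export
print.hmm_fit <- function(x, ...) {
  cat(sprintf("<hmm_fit> %d ROI(s), lower bound %.3f nats, %s\n",
              x$n_rois_selected, x$lower_bound,
              if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' Select the number of ROIs by the variational lower bound
#'
#' Fits every candidate K in `roi_range` with [fit_vbem()] and returns the
#' fit with the highest lower bound; ties (within 1e-8 nats) are broken
#' toward the smaller K.
#'
#' @param roi_range Integer vector of candidate ROI counts, within 1-10.
#' @inheritParams fit_vbem
#' @return The winning `"hmm_fit"`, with the candidate table attached as
#'   attribute `"candidates"` (K and lower bound per candidate).
#' @export
select_n_rois <- function(seqs, roi_range = 1:10, hyper = vb_hyper(),
                          n_restarts = 5, seed = 1, max_iter = 300,
                          tol = 1e-6) {
  roi_range <- sort(unique(as.integer(roi_range)))
  if (length(roi_range) == 0L) stop("roi_range must be non-empty")
  if (min(roi_range) < 1L || max(roi_range) > 10L)
    stop("roi_range must lie within 1..10")
  fits <- vector("list", length(roi_range))
  best <- NULL
  for (i in seq_along(roi_range)) {
    fits[[i]] <- fit_vbem(seqs, roi_range[i], hyper, n_restarts, seed,
                          max_iter, tol)
    if (is.null(best) || fits[[i]]$lower_bound > best$lower_bound + 1e-8)
      best <- fits[[i]]
  }
  attr(best, "candidates") <- data.frame(
    n_rois = roi_range,
    lower_bound = vapply(fits, `[[`, numeric(1), "lower_bound"))
  best
}
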