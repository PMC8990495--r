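# Pattern and consistency metrics derived from fitted HMMs.

# Mean per-sequence log-likelihood of a set of sequences under a model,
# vectorised through the forward pass.
#' @noRd
mean_loglik_set <- function(model, seqs) {
  xy <- lapply(seqs, fix_xy)
  lens <- vapply(xy, nrow, integer(1))
  X <- do.call(rbind, xy)
  logB <- matrix(0, nrow(X), model$n_rois)
  for (k in seq_len(model$n_rois))
    logB[, k] <- dmvnorm2_log(X, model$means[k, ], model$covariances[[k]])
  mean(forward_logz(model$prior, model$transitions, logB, lens))
}

#' A-B scale: likelihood contrast between two representative patterns
#'
#' Quantifies where a participant's eye movements fall on the axis between
#' Pattern A and Pattern B: `(A - B) / (|A| + |B|)`, where A and B are the
#' participant's mean per-sequence log-likelihoods under the two pattern
#' HMMs. Means (rather than sums) are used so the scale is comparable across
#' unequal trial counts. More positive values indicate greater similarity to
#' Pattern A; more negative, to Pattern B. Swapping the patterns negates the
#' value exactly.
#'
#' @param seqs List of `fixseq` objects (one participant-condition's trials).
#' @param pattern_a,pattern_b The two representative `gaussian_hmm`s.
#' @return List of class `"ab_score"`: `value` in \[-1, 1\], `ll_a`, `ll_b`
#'   (nats per sequence), and `degenerate` (TRUE only if both
#'   log-likelihoods are exactly zero, in which case `value` is 0).
#' @export
#' @examples
#' a <- gaussian_hmm(1, matrix(1), rbind(c(0, 0)), list(diag(2) * 400))
#' b <- gaussian_hmm(1, matrix(1), rbind(c(0, 80)), list(diag(2) * 400))
#' s <- sample_hmm_sequences(a, 5, 8, seed = 1)
#' ab_scale(s, a, b)$value > 0
ab_scale <- function(seqs, pattern_a, pattern_b) {
  if (length(seqs) == 0L) stop("need at least one sequence")
  validate_hmm(pattern_a)
  validate_hmm(pattern_b)
  ll_a <- mean_loglik_set(pattern_a, seqs)
  ll_b <- mean_loglik_set(pattern_b, seqs)
  denom <- abs(ll_a) + abs(ll_b)
  degenerate <- denom == 0
  value <- if (degenerate) 0 else (ll_a - ll_b) / denom
  structure(list(value = value, ll_a = ll_a, ll_b = ll_b,
                 degenerate = degenerate),
            class = "ab_score")
}

#' @export
print.ab_score <- function(x, ...) {
  cat(sprintf("<ab_score> %.4f (ll A = %.2f, ll B = %.2f nats/sequence)%s\n",
              x$value, x$ll_a, x$ll_b,
              if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}

#' Marginal and conditional fixation entropies of an HMM
#'
#' Eye-movement consistency measures computed from the model parameters
#' (not from decoded label frequencies): the entropy of the first fixation's
#' ROI distribution, and the conditional entropies of the second ROI given
#' the first and of the third given the second. With prior `p` and
#' transition matrix `A`,
#' `h1 = H(p)`, `h2_given_1 = sum_i p_i H(A[i, ])`, and
#' `h3_given_2 = sum_j (pA)_j H(A[j, ])`, with `H` the row entropy and
#' `0 log 0 := 0`. Lower entropy means more consistent gaze behavior.
#'
#' @param model A `gaussian_hmm`.
#' @param base Logarithm base: 2 (bits, default) or `exp(1)` (nats).
#' @return List of class `"entropy_profile"`: `h1`, `h2_given_1`,
#'   `h3_given_2`, each in \[0, log_base(K)\].
#' @export
#' @examples
#' m <- gaussian_hmm(c(0.7, 0.3), rbind(c(0.8, 0.2), c(0.4, 0.6)),
#'                   rbind(c(0, 0), c(0, 60)), list(diag(2), diag(2)))
#' fixation_entropies(m)   # h2_given_1 approximately 0.7966 bits
fixation_entropies <- function(model, base = 2) {
  validate_hmm(model)
  p <- model$prior
  A <- model$transitions
  row_h <- apply(A, 1L, entropy_vec, base = base)
  p2 <- drop(p %*% A)
  structure(list(h1 = entropy_vec(p, base),
                 h2_given_1 = sum(p * row_h),
                 h3_given_2 = sum(p2 * row_h),
                 base = base),
            class = "entropy_profile")
}

#' @export
print.entropy_profile <- function(x, ...) {
  unit <- if (isTRUE(all.equal(x$base, 2))) "bits" else "nats"
  cat(sprintf("<entropy_profile> h1 = %.4f, h2|1 = %.4f, h3|2 = %.4f %s\n",
              x$h1, x$h2_given_1, x$h3_given_2, unit))
  invisible(x)
}
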