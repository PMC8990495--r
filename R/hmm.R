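# Gaussian-emission hidden Markov models of fixation sequences.
#
# A model has K regions of interest (ROIs): hidden states with bivariate
# Gaussian emissions over (x, y) fixation position. The prior vector gives
# the ROI distribution of the first fixation and the transition matrix the
# row-stochastic dynamics between consecutive fixations.

#' Construct a Gaussian-emission hidden Markov model
#'
#' @param prior Length-K probability vector over initial ROIs.
#' @param transitions K x K row-stochastic transition matrix.
#' @param means K x 2 matrix of ROI centers (x, y pixels).
#' @param covariances List of K symmetric positive-definite 2 x 2 matrices.
#' @return An object of class `"gaussian_hmm"`.
#' @export
#' @examples
#' m <- gaussian_hmm(prior = c(0.6, 0.4),
#'                   transitions = rbind(c(0.8, 0.2), c(0.3, 0.7)),
#'                   means = rbind(c(0, 0), c(0, 60)),
#'                   covariances = list(diag(2) * 100, diag(2) * 100))
#' m$n_rois
gaussian_hmm <- function(prior, transitions, means, covariances) {
  k <- length(prior)
  if (k < 1L || k > 10L) stop("number of ROIs must be between 1 and 10")
  transitions <- as.matrix(transitions)
  means <- matrix(as.numeric(means), nrow = k)
  model <- structure(
    list(n_rois = k, prior = as.numeric(prior), transitions = transitions,
         means = means, covariances = covariances),
    class = "gaussian_hmm")
  validate_hmm(model)
  model
}

#' Validate hidden Markov model invariants
#'
#' Checks that the prior and each transition row are probability vectors
#' (sum 1 within 1e-8, non-negative entries) and every ROI covariance is
#' symmetric positive-definite.
#'
#' @param model A `gaussian_hmm`.
#' @return `model`, invisibly; otherwise an error describing the violation.
#' @export
validate_hmm <- function(model) {
  k <- model$n_rois
  if (length(model$prior) != k || any(model$prior < 0) ||
      abs(sum(model$prior) - 1) > 1e-8)
    stop("prior must be a non-negative vector summing to 1")
  if (!is.matrix(model$transitions) || any(dim(model$transitions) != k) ||
      any(model$transitions < 0) ||
      any(abs(rowSums(model$transitions) - 1) > 1e-8))
    stop("transitions must be a row-stochastic K x K matrix")
  if (!is.matrix(model$means) || nrow(model$means) != k ||
      ncol(model$means) != 2L || !all(is.finite(model$means)))
    stop("means must be a finite K x 2 matrix")
  if (length(model$covariances) != k ||
      !all(vapply(model$covariances, is_spd2, logical(1))))
    stop("each ROI covariance must be a symmetric positive-definite 2 x 2 matrix")
  invisible(model)
}

#' @export
print.gaussian_hmm <- function(x, ...) {
  cat(sprintf("<gaussian_hmm> %d ROI(s)\n", x$n_rois))
  cat("prior:", signif(x$prior, 3), "\n")
  cat("ROI centers:\n")
  print(signif(x$means, 4))
  invisible(x)
}

# K x T matrix of per-state emission log densities for one sequence,
# with an explicit error for degenerate covariances.
#' @noRd
emission_logdens <- function(model, xy) {
  out <- matrix(0, nrow = model$n_rois, ncol = nrow(xy))
  for (i in seq_len(model$n_rois)) {
    dens <- tryCatch(
      dmvnorm2_log(xy, model$means[i, ], model$covariances[[i]]),
      error = function(e) stop("model degeneracy: ROI ", i,
                               " covariance is singular", call. = FALSE))
    out[i, ] <- dens
  }
  out
}

#' Forward log-likelihood of a fixation sequence
#'
#' Computes `log p(x_1..x_T | model)` over fixation positions by the forward
#' recursion in log space. Fixation durations are ignored.
#'
#' @param model A `gaussian_hmm`.
#' @param seq A `fixseq` object, or a numeric matrix of positions with
#'   columns x, y.
#' @return Log-probability in nats (a single finite number for finite input).
#' @export
#' @examples
#' m <- gaussian_hmm(1, matrix(1), rbind(c(0, 0)), list(diag(2)))
#' loglik_hmm(m, cbind(x = c(0, 1), y = c(0, -1)))
loglik_hmm <- function(model, seq) {
  validate_hmm(model)
  xy <- fix_xy(seq)
  if (nrow(xy) == 0L) stop("empty fixation sequence")
  lb <- emission_logdens(model, xy)
  alpha <- log(model$prior) + lb[, 1L]
  if (nrow(xy) > 1L) {
    ltr <- log(model$transitions)
    for (t in 2L:nrow(xy))
      alpha <- row_logsumexp(t(alpha + ltr)) + lb[, t]
  }
  logsumexp(alpha)
}

#' Decode the most probable ROI sequence
#'
#' Returns the jointly most probable hidden-state path for the fixation
#' sequence (max-product / Viterbi recursion in log space). Ties are broken
#' deterministically toward the lower ROI index.
#'
#' @inheritParams loglik_hmm
#' @return Integer vector of ROI labels, one per fixation.
#' @export
decode_rois <- function(model, seq) {
  validate_hmm(model)
  xy <- fix_xy(seq)
  if (nrow(xy) == 0L) stop("empty fixation sequence")
  k <- model$n_rois
  n <- nrow(xy)
  lb <- emission_logdens(model, xy)
  delta <- log(model$prior) + lb[, 1L]
  back <- matrix(0L, nrow = k, ncol = n)
  ltr <- log(model$transitions)
  if (n > 1L) for (t in 2L:n) {
    cand <- delta + ltr                 # cand[i, j]: best-so-far ending i -> j
    # which.max returns the first maximum, giving the lower-index tie rule
    back[, t] <- apply(cand, 2L, which.max)
    delta <- cand[cbind(back[, t], seq_len(k))] + lb[, t]
  }
  path <- integer(n)
  path[n] <- which.max(delta)
  if (n > 1L) for (t in (n - 1L):1L) path[t] <- back[path[t + 1L], t + 1L]
  path
}

#' Sample fixation sequences from a model
#'
#' Ancestral sampling: the first ROI from the prior, subsequent ROIs from the
#' transition matrix, and each fixation position from the ROI's Gaussian.
#' Durations are filled with a nominal constant since the model does not
#' describe them.
#'
#' @param model A `gaussian_hmm`.
#' @param n_trials Number of sequences to draw.
#' @param lengths Either a single positive integer (all sequences that long),
#'   a vector of `n_trials` lengths, or a function `function(n)` returning
#'   `n` positive integer lengths.
#' @param seed Integer seed; same seed reproduces the output exactly.
#' @param participant_id,phase,learn_mask,recog_mask Metadata stamped on the
#'   generated sequences.
#' @return List of `fixseq` objects with a `"states"` attribute on each
#'   holding the true ROI path.
#' @export
sample_hmm_sequences <- function(model, n_trials, lengths, seed,
                                 participant_id = "sim",
                                 phase = "learning",
                                 learn_mask = "unmasked",
                                 recog_mask = if (phase == "learning")
                                   "not_applicable" else "unmasked") {
  validate_hmm(model)
  if (n_trials < 1L) stop("n_trials must be at least 1")
  with_seed(seed, {
    len <- if (is.function(lengths)) lengths(n_trials)
           else if (length(lengths) == 1L) rep(as.integer(lengths), n_trials)
           else as.integer(lengths)
    if (length(len) != n_trials || any(len < 1L))
      stop("sequence lengths must be positive integers (no mass on 0)")
    lapply(seq_len(n_trials), function(tr) {
      s <- integer(len[tr])
      s[1L] <- sample.int(model$n_rois, 1L, prob = model$prior)
      if (len[tr] > 1L) for (t in 2L:len[tr])
        s[t] <- sample.int(model$n_rois, 1L,
                           prob = model$transitions[s[t - 1L], ])
      xy <- t(vapply(s, function(i)
        drop(rmvnorm2(1L, model$means[i, ], model$covariances[[i]])),
        numeric(2)))
      fx <- fixation_sequence(participant_id, paste0("trial", tr), phase,
                              learn_mask, recog_mask,
                              x = xy[, 1L], y = xy[, 2L],
                              duration = rep(250, len[tr]))
      attr(fx, "states") <- s
      fx
    })
  })
}

#' Write a model to JSON
#'
#' Serializes parameters plus optional provenance (seed, hyperparameters,
#' variational lower bound) so fits can be archived and reloaded exactly.
#'
#' @param model A `gaussian_hmm`.
#' @param path Output path.
#' @param provenance Optional named list stored verbatim alongside the
#'   parameters.
#' @return `path`, invisibly.
#' @export
write_hmm_json <- function(model, path, provenance = NULL) {
  obj <- list(n_rois = model$n_rois, prior = model$prior,
              transitions = model$transitions, means = model$means,
              covariances = model$covariances)
  if (!is.null(provenance)) obj$provenance <- provenance
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       matrix = "rowmajor")
  invisible(path)
}

#' Read a model from JSON
#'
#' @param path Path written by [write_hmm_json()].
#' @return A `gaussian_hmm`; any provenance is attached as attribute
#'   `"provenance"`.
#' @export
read_hmm_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  covs <- obj$covariances
  if (is.array(covs) && length(dim(covs)) == 3L)
    covs <- lapply(seq_len(dim(covs)[1L]), function(i) covs[i, , ])
  model <- gaussian_hmm(obj$prior, obj$transitions, obj$means, covs)
  if (!is.null(obj$provenance)) attr(model, "provenance") <- obj$provenance
  model
}
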