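# Clustering individual HMMs into representative gaze patterns.
#
# Hierarchical EM over virtual samples: each input HMM is represented by a
# seeded set of virtual fixation sequences drawn from it, and a mixture of
# group HMMs is fitted to those samples with the constraint that all of one
# input model's samples carry the same cluster responsibility. The monitored
# objective is the penalised log-likelihood of the virtual samples (an
# inverse-Wishart stabiliser on the group covariances makes the M-step MAP,
# keeping the objective monotone and the covariances positive-definite).

#' Median ROI count across individual models
#'
#' Integer median of the number of ROIs; when the median falls between two
#' integers it is rounded up.
#'
#' @param models List of `gaussian_hmm` objects.
#' @return Integer.
#' @export
#' @examples
#' # two models with 2 ROIs and two with 3 -> median 2.5 -> 3
median_roi_count <- function(models) {
  if (length(models) == 0L) stop("need at least one model")
  ks <- vapply(models, function(m) m$n_rois, numeric(1))
  as.integer(ceiling(stats::median(ks)))
}

#' Settings for hierarchical-EM clustering
#'
#' @param virtual_length Length of each virtual sequence.
#' @param virtual_samples Number of virtual sequences drawn per input model.
#' @param n_restarts Independently initialised runs; the best objective wins.
#' @param max_iter,tol Convergence controls: stop when the objective change
#'   falls below `tol * (1 + |objective|)`.
#' @param cov_prior_scale,cov_prior_dof Inverse-Wishart stabiliser on group
#'   ROI covariances (scale matrix defaults to a quarter-face-box diagonal).
#' @return A list of class `"vhem_config"`.
#' @export
vhem_config <- function(virtual_length = 10, virtual_samples = 1000,
                        n_restarts = 5, max_iter = 100, tol = 1e-6,
                        cov_prior_scale = diag(64^2, 2), cov_prior_dof = 5) {
  stopifnot(virtual_length >= 1, virtual_samples >= 1, n_restarts >= 1)
  structure(list(virtual_length = as.integer(virtual_length),
                 virtual_samples = as.integer(virtual_samples),
                 n_restarts = as.integer(n_restarts),
                 max_iter = as.integer(max_iter), tol = tol,
                 cov_prior_scale = cov_prior_scale,
                 cov_prior_dof = cov_prior_dof),
            class = "vhem_config")
}

# Deterministic content key so virtual-sample seeds follow the model, not
# its position in the input list (clustering is then order-invariant).
#' @noRd
model_signature <- function(m) {
  paste(signif(c(m$prior, m$transitions, m$means,
                 unlist(m$covariances)), 10), collapse = ",")
}

# log inverse-Wishart kernel on the group covariances (the MAP penalty).
#' @noRd
log_cov_prior <- function(covs, S0, nu0) {
  d <- 2
  sum(vapply(covs, function(sig) {
    -(nu0 + d + 1) / 2 *
      as.numeric(determinant(sig, logarithm = TRUE)$modulus) -
      0.5 * sum(diag(solve(sig, S0 * nu0)))
  }, numeric(1)))
}

# One EM run of the constrained mixture of HMMs over virtual samples.
# X: pooled virtual fixations; lens: per-sequence lengths; model_of: input
# model index per sequence; init: list of group HMM parameter lists.
#' @noRd
vhem_run <- function(X, lens, model_of, n_models, groups, config) {
  J <- length(groups)
  K <- length(groups[[1L]]$prior)
  S0 <- config$cov_prior_scale
  nu0 <- config$cov_prior_dof
  n_seq <- length(lens)
  obj_trace <- numeric(0)
  z <- matrix(1 / J, n_models, J)
  rho <- rep(1 / J, J)
  for (it in seq_len(config$max_iter)) {
    # E-step: per-sequence log-likelihoods under each group HMM
    ll_model <- matrix(0, n_models, J)
    logB_all <- vector("list", J)
    for (j in seq_len(J)) {
      g <- groups[[j]]
      logB <- matrix(0, nrow(X), K)
      for (k in seq_len(K))
        logB[, k] <- dmvnorm2_log(X, g$means[k, ], g$covariances[[k]])
      logB_all[[j]] <- logB
      lz <- forward_logz(g$prior, g$transitions, logB, lens)
      ll_model[, j] <- as.numeric(rowsum(lz, model_of))
    }
    lw <- sweep(ll_model, 2L, log(rho), `+`)
    norm <- row_logsumexp(lw)
    z <- exp(lw - norm)
    obj <- sum(norm) +
      sum(vapply(groups, function(g)
        log_cov_prior(g$covariances, S0, nu0), numeric(1)))
    obj_trace <- c(obj_trace, obj)
    if (it > 1L && abs(obj - obj_trace[it - 1L]) <
          config$tol * (1 + abs(obj))) break
    # M-step: weighted Baum-Welch statistics per group
    rho <- colMeans(z)
    for (j in seq_len(J)) {
      g <- groups[[j]]
      w_seq <- z[model_of, j]
      fb <- forward_backward(g$prior, g$transitions, logB_all[[j]],
                             lens, w = w_seq)
      w_fix <- rep(w_seq, lens)
      gw <- fb$gamma * w_fix
      Nk <- colSums(gw)
      prior <- colSums(fb$gamma1 * w_seq)
      g$prior <- (prior + 1e-12) / sum(prior + 1e-12)
      trans <- fb$xi + 1e-12
      g$transitions <- trans / rowSums(trans)
      for (k in seq_len(K)) {
        if (Nk[k] > 1e-8) {
          mu <- colSums(X * gw[, k]) / Nk[k]
          xc <- sweep(X, 2L, mu)
          sig <- (crossprod(xc * gw[, k], xc) + S0 * nu0) /
            (Nk[k] + nu0 + 3)
        } else {
          mu <- g$means[k, ]
          sig <- S0
        }
        g$means[k, ] <- mu
        g$covariances[[k]] <- (sig + t(sig)) / 2
      }
      groups[[j]] <- g
    }
  }
  list(groups = groups, z = z, rho = rho, objective = max(obj_trace),
       obj_trace = obj_trace, ll_model = ll_model)
}

# Moment-style initial group HMM from a pool of fixations.
#' @noRd
init_group_hmm <- function(Xpool, K, config) {
  centers <- Xpool[sample.int(nrow(Xpool), K), , drop = FALSE] +
    matrix(stats::rnorm(2L * K, sd = 1e-3), ncol = 2L)
  sig <- stats::cov(Xpool) / max(1, K) + diag(1e-2, 2)
  list(prior = rep(1 / K, K),
       transitions = matrix(1 / K, K, K),
       means = centers,
       covariances = rep(list((sig + t(sig)) / 2), K))
}

#' Cluster individual HMMs into representative patterns
#'
#' Groups individual fixation-sequence HMMs into `n_clusters` representative
#' group HMMs (each with `n_group_rois` states) by hierarchical EM over
#' seeded virtual samples, and hard-assigns every input model to the cluster
#' with the largest responsibility (ties to the first cluster).
#'
#' @param models Named list of `gaussian_hmm` objects (names are participant
#'   identifiers; unnamed lists get positional names).
#' @param n_clusters Number of representative patterns (2 for the usual
#'   Pattern A / Pattern B analysis).
#' @param n_group_rois States per group HMM, typically
#'   [median_roi_count()] of the inputs.
#' @param config A [vhem_config()].
#' @param seed Integer seed.
#' @return For `n_clusters = 2`, a list of class `"pattern_pair"` with
#'   `pattern_a`, `pattern_b`, `assignments` (named character vector of
#'   `"A"`/`"B"`), `n_group_rois`, `responsibilities`, `objective` and
#'   `degenerate`. Otherwise a general `"hmm_clustering"` list with
#'   `groups`, `assignments` (integers), and the same diagnostics.
#' @export
cluster_vhem <- function(models, n_clusters = 2, n_group_rois,
                         config = vhem_config(), seed = 1) {
  n <- length(models)
  if (n < n_clusters) stop("fewer models (", n, ") than clusters")
  if (n_group_rois < 1L) stop("n_group_rois must be at least 1")
  if (is.null(names(models))) names(models) <- paste0("m", seq_len(n))
  lapply(models, validate_hmm)

  # canonical processing order keyed on model content, for order invariance
  sigs <- vapply(models, model_signature, character(1))
  ord <- order(sigs)
  models_c <- models[ord]
  all_identical <- length(unique(sigs)) == 1L

  seeds <- derive_seeds(seed, n + config$n_restarts)
  virt <- lapply(seq_len(n), function(i)
    sample_hmm_sequences(models_c[[i]], config$virtual_samples,
                         config$virtual_length, seed = seeds[i]))
  X <- do.call(rbind, lapply(virt, function(vs)
    do.call(rbind, lapply(vs, fix_xy))))
  lens <- rep(config$virtual_length, n * config$virtual_samples)
  model_of <- rep(seq_len(n), each = config$virtual_samples)

  # each restart seeds every group HMM from the virtual samples of one
  # randomly chosen exemplar model, giving well-separated starting points;
  # when every input model is identical there is no partition to find, so a
  # single group is fitted and duplicated (flagged degenerate below)
  one_restart <- function(restart_seed) {
    with_seed(restart_seed, {
      if (all_identical) {
        groups <- list(init_group_hmm(X, n_group_rois, config))
        run <- vhem_run(X, lens, model_of, n, groups, config)
        run$groups <- rep(run$groups, n_clusters)
        run$z <- matrix(rep(c(1, rep(0, n_clusters - 1L)), each = n),
                        n, n_clusters)
        run$ll_model <- run$ll_model[, rep(1L, n_clusters), drop = FALSE]
        run
      } else {
        ex <- sample.int(n, n_clusters)
        groups <- lapply(ex, function(i)
          init_group_hmm(X[model_of == i, , drop = FALSE], n_group_rois,
                         config))
        vhem_run(X, lens, model_of, n, groups, config)
      }
    })
  }
  best <- NULL
  for (r in seq_len(config$n_restarts)) {
    run <- one_restart(seeds[n + r])
    if (is.null(best) || run$objective > best$objective + 1e-12) best <- run
  }

  hard <- max.col(best$z, ties.method = "first")
  counts <- tabulate(hard, n_clusters)
  # re-initialise once if a cluster came out empty; flag if it persists
  degenerate <- FALSE
  if (any(counts == 0L)) {
    run <- one_restart(seeds[n + 1L] + 1L)
    if (run$objective > best$objective) {
      best <- run
      hard <- max.col(best$z, ties.method = "first")
      counts <- tabulate(hard, n_clusters)
    }
    if (any(counts == 0L)) degenerate <- TRUE
  }
  # near-uniform responsibilities for every model: no separation to find;
  # report the best-fitting group HMM for every cluster so the "patterns"
  # are identical by construction
  if (all_identical || all(abs(best$z - 1 / n_clusters) < 0.1)) {
    degenerate <- TRUE
    j_star <- which.max(colSums(best$ll_model))
    best$groups <- rep(best$groups[j_star], n_clusters)
    hard <- rep(1L, n)
  }

  to_hmm <- function(g) gaussian_hmm(g$prior, g$transitions, g$means,
                                     g$covariances)
  inv <- order(ord)    # map canonical order back to input order
  z_in <- best$z[inv, , drop = FALSE]
  hard_in <- hard[inv]
  rownames(z_in) <- names(models)
  if (n_clusters == 2L) {
    assignments <- stats::setNames(c("A", "B")[hard_in], names(models))
    structure(list(pattern_a = to_hmm(best$groups[[1L]]),
                   pattern_b = to_hmm(best$groups[[2L]]),
                   assignments = assignments,
                   n_group_rois = as.integer(n_group_rois),
                   responsibilities = z_in,
                   objective = best$objective,
                   obj_trace = best$obj_trace,
                   degenerate = degenerate, seed = seed),
              class = "pattern_pair")
  } else {
    structure(list(groups = lapply(best$groups, to_hmm),
                   assignments = stats::setNames(hard_in, names(models)),
                   n_group_rois = as.integer(n_group_rois),
                   responsibilities = z_in,
                   objective = best$objective,
                   obj_trace = best$obj_trace,
                   degenerate = degenerate, seed = seed),
              class = "hmm_clustering")
  }
}

#' @export
print.pattern_pair <- function(x, ...) {
  cat(sprintf("<pattern_pair> %d group ROI(s); %d participants: %d Pattern A, %d Pattern B%s\n",
              x$n_group_rois, length(x$assignments),
              sum(x$assignments == "A"), sum(x$assignments == "B"),
              if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}

#' Likelihood separation between the two representative patterns
#'
#' For each participant, computes the mean per-sequence log-likelihood of
#' their data under both pattern HMMs and the margin (own-pattern minus
#' other-pattern). Pattern separation is then tested as a one-way comparison
#' of the signed likelihood difference (Pattern A minus Pattern B) between
#' the two assigned groups, reported as F with partial eta-squared and its
#' 90% confidence interval.
#'
#' @param sequences_by_participant Named list: participant id -> list of
#'   `fixseq` objects.
#' @param pattern_pair A `"pattern_pair"` from [cluster_vhem()].
#' @return List of class `"separation_result"`: `per_participant` data frame
#'   (participant_id, assignment, ll_a, ll_b, margin), `f_stat`, `df`,
#'   `p_value`, `effect_size`, `effect_ci`, `stable`.
#' @export
pattern_separation <- function(sequences_by_participant, pattern_pair) {
  ids <- names(pattern_pair$assignments)
  missing <- setdiff(ids, names(sequences_by_participant))
  if (length(missing))
    stop("participants without sequences: ", paste(missing, collapse = ", "))
  ll <- t(vapply(ids, function(id) {
    seqs <- sequences_by_participant[[id]]
    if (length(seqs) == 0L) stop("participant ", id, " has no sequences")
    c(mean_loglik_set(pattern_pair$pattern_a, seqs),
      mean_loglik_set(pattern_pair$pattern_b, seqs))
  }, numeric(2)))
  assign <- pattern_pair$assignments[ids]
  own_minus_other <- ifelse(assign == "A", ll[, 1L] - ll[, 2L],
                            ll[, 2L] - ll[, 1L])
  diff_ab <- ll[, 1L] - ll[, 2L]
  tab <- data.frame(participant_id = ids, assignment = assign,
                    ll_a = ll[, 1L], ll_b = ll[, 2L],
                    margin = own_minus_other, row.names = NULL)
  nA <- sum(assign == "A"); nB <- sum(assign == "B")
  stable <- nA >= 2L && nB >= 2L
  if (!stable) {
    warning("fewer than two participants in a pattern group; ",
            "separation statistic is unstable")
    return(structure(list(per_participant = tab, f_stat = NA_real_,
                          df = c(1, nA + nB - 2), p_value = NA_real_,
                          effect_size = NA_real_, effect_ci = c(NA, NA),
                          stable = FALSE),
                     class = "separation_result"))
  }
  grp <- factor(assign, levels = c("A", "B"))
  gm <- tapply(diff_ab, grp, mean)
  ssb <- nA * (gm[1] - mean(diff_ab))^2 + nB * (gm[2] - mean(diff_ab))^2
  ssw <- sum((diff_ab - gm[as.integer(grp)])^2)
  df_err <- nA + nB - 2L
  f <- if (ssw < 1e-12 && ssb < 1e-12) 0 else (ssb / 1) / (ssw / df_err)
  p <- stats::pf(f, 1, df_err, lower.tail = FALSE)
  eta <- f / (f + df_err)
  ci <- etasq_ci(f, 1, df_err, level = 0.90)
  structure(list(per_participant = tab, f_stat = as.numeric(f),
                 df = c(1, df_err), p_value = as.numeric(p),
                 effect_size = as.numeric(eta), effect_ci = ci,
                 stable = TRUE),
            class = "separation_result")
}

#' @export
print.separation_result <- function(x, ...) {
  if (!x$stable) {
    cat("<separation_result> unstable (a pattern group has < 2 participants)\n")
    return(invisible(x))
  }
  cat(sprintf("<separation_result> F(%g, %g) = %.2f, p = %.3g, eta_p^2 = %.3f, 90%% CI [%.4f, %.4f]\n",
              x$df[1], x$df[2], x$f_stat, x$p_value, x$effect_size,
              x$effect_ci[1], x$effect_ci[2]))
  cat(sprintf("  margins: %d/%d participants better fit by their own pattern\n",
              sum(x$per_participant$margin > 0), nrow(x$per_participant)))
  invisible(x)
}

#' Write a clustering report as CSV
#'
#' One row per participant: assignment, mean log-likelihood under each
#' pattern, and the own-minus-other margin.
#'
#' @param separation A `"separation_result"`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_clustering_report <- function(separation, path) {
  tab <- separation$per_participant
  names(tab)[names(tab) == "ll_a"] <- "ll_under_A"
  names(tab)[names(tab) == "ll_b"] <- "ll_under_B"
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
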