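test_that("K = 1 fit matches the closed-form Gaussian posterior", {
  hyper <- vb_hyper()
  truth <- gaussian_hmm(1, matrix(1), rbind(c(10, -20)), list(diag(2) * 150))
  seqs <- sample_hmm_sequences(truth, 20, 8, seed = 31)
  fit <- fit_vbem(seqs, 1, hyper, n_restarts = 1, seed = 2)
  X <- do.call(rbind, lapply(seqs, function(s) s$fixations[, 1:2]))
  n <- nrow(X)
  b0 <- hyper$mean_prior_strength
  m0 <- hyper$mean_prior_center
  xbar <- colMeans(X)
  # Normal-Wishart posterior computed independently of the fitter
  m_post <- (b0 * m0 + n * xbar) / (b0 + n)
  S <- crossprod(sweep(X, 2, xbar))
  dm <- xbar - m0
  Winv <- hyper$covariance_prior_scale * hyper$covariance_prior_dof +
    S + (b0 * n / (b0 + n)) * tcrossprod(dm)
  nu_post <- hyper$covariance_prior_dof + n
  sigma_post <- Winv / (nu_post - 3)
  expect_equal(drop(fit$model$means), m_post, tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_equal(fit$model$covariances[[1]], sigma_post, tolerance = 1e-6,
               ignore_attr = TRUE)
  # with a weak prior the mean is essentially the pooled mean
  expect_lt(max(abs(drop(fit$model$means) - xbar)), 0.01)
})

test_that("the variational lower bound never decreases within a run", {
  truth <- three_roi_truth()
  for (s in 1:3) {
    seqs <- sample_hmm_sequences(truth, 25, 8, seed = s)
    fit <- fit_vbem(seqs, 3, n_restarts = 1, seed = s + 100)
    expect_true(all(diff(fit$bound_trace) > -1e-8))
  }
})

test_that("VBEM recovers a well-separated 3-ROI generator", {
  truth <- three_roi_truth()
  for (s in 1:3) {
    seqs <- sample_hmm_sequences(truth, 60, 10, seed = s)
    fit <- fit_vbem(seqs, 3, n_restarts = 3, seed = s * 7)
    expect_identical(fit$n_rois_selected, 3L)
    perm <- match_states(fit$model$means, truth$means)
    err <- sqrt(rowSums((fit$model$means[perm, ] - truth$means)^2))
    expect_lt(max(err), 5)
    tv <- max(rowSums(abs(fit$model$transitions[perm, perm] -
                            truth$transitions)) / 2)
    expect_lt(tv, 0.1)
  }
})

test_that("fitting is deterministic and invariant to duplicating the data", {
  truth <- three_roi_truth()
  seqs <- sample_hmm_sequences(truth, 30, 8, seed = 5)
  f1 <- fit_vbem(seqs, 3, n_restarts = 2, seed = 9)
  f2 <- fit_vbem(seqs, 3, n_restarts = 2, seed = 9)
  expect_identical(f1$model, f2$model)
  expect_identical(f1$lower_bound, f2$lower_bound)

  fdup <- fit_vbem(c(seqs, seqs), 3, n_restarts = 2, seed = 9)
  perm <- match_states(fdup$model$means, f1$model$means)
  expect_lt(max(abs(fdup$model$means[perm, ] - f1$model$means)), 0.5)
})

test_that("inadequate inputs are rejected", {
  truth <- three_roi_truth()
  seqs <- sample_hmm_sequences(truth, 2, 2, seed = 1)
  expect_error(fit_vbem(seqs, 5), "below n_rois")
  expect_error(fit_vbem(list(), 1), "at least one")
  expect_error(fit_vbem(seqs, 0), "between 1 and 10")
})

test_that("ROI-count selection finds the generating K and honors bounds", {
  truth <- three_roi_truth()
  hits <- 0L
  for (s in 1:5) {
    seqs <- sample_hmm_sequences(truth, 60, 10, seed = s + 20)
    sel <- select_n_rois(seqs, 1:6, n_restarts = 2, seed = s)
    hits <- hits + (sel$n_rois_selected == 3L)
    cand <- attr(sel, "candidates")
    expect_identical(cand$n_rois, 1:6)
    expect_true(all(cand$lower_bound <= sel$lower_bound + 1e-8))
  }
  expect_gte(hits, 4L)
  expect_error(select_n_rois(list(), integer(0)), "non-empty|at least one")
})

test_that("a singleton ROI range reduces to a plain fit", {
  truth <- three_roi_truth()
  seqs <- sample_hmm_sequences(truth, 20, 6, seed = 3)
  sel <- select_n_rois(seqs, 1, n_restarts = 2, seed = 17)
  fit <- fit_vbem(seqs, 1, n_restarts = 2, seed = 17)
  expect_equal(sel$lower_bound, fit$lower_bound, tolerance = 1e-12)
  expect_equal(sel$model, fit$model, tolerance = 1e-12)
})

test_that("vacant ROIs are pruned from the reported model", {
  # two clearly separated clusters, but K = 4 requested
  truth <- gaussian_hmm(c(0.5, 0.5), matrix(0.5, 2, 2),
                        rbind(c(-80, 0), c(80, 0)),
                        list(diag(2) * 50, diag(2) * 50))
  seqs <- sample_hmm_sequences(truth, 40, 8, seed = 13)
  fit <- fit_vbem(seqs, 4, n_restarts = 3, seed = 2)
  expect_lte(fit$n_rois_selected, 4L)
  expect_identical(fit$n_rois_selected, fit$model$n_rois)
  validate_hmm(fit$model)
})
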