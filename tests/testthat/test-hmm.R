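toy_2state <- function() {
  gaussian_hmm(c(0.6, 0.4),
               rbind(c(0.8, 0.2), c(0.3, 0.7)),
               rbind(c(0, 0), c(0, 60)),
               list(diag(2) * 100, rbind(c(150, 30), c(30, 90))))
}

test_that("model construction enforces stochasticity and SPD covariances", {
  expect_error(gaussian_hmm(c(0.5, 0.6), diag(2), rbind(c(0, 0), c(1, 1)),
                            list(diag(2), diag(2))),
               "summing to 1")
  expect_error(gaussian_hmm(c(0.5, 0.5), rbind(c(1, 0), c(0.5, 0.6)),
                            rbind(c(0, 0), c(1, 1)),
                            list(diag(2), diag(2))),
               "row-stochastic")
  expect_error(gaussian_hmm(c(0.5, 0.5), diag(2), rbind(c(0, 0), c(1, 1)),
                            list(diag(2), matrix(c(1, 2, 2, 1), 2))),
               "positive-definite")
  expect_error(gaussian_hmm(rep(0.1, 11), diag(11)[1:11, 1:11],
                            matrix(0, 11, 2), rep(list(diag(2)), 11)),
               "between 1 and 10")
})

test_that("K = 1 log-likelihood is the sum of single-Gaussian densities", {
  m <- gaussian_hmm(1, matrix(1), rbind(c(3, -2)),
                    list(rbind(c(120, 20), c(20, 80))))
  set.seed(11)
  xy <- cbind(rnorm(6, 3, 10), rnorm(6, -2, 10))
  closed <- sum(vapply(seq_len(6), function(t)
    bvnorm_logdens(xy[t, ], c(3, -2), m$covariances[[1]]), numeric(1)))
  expect_equal(loglik_hmm(m, xy), closed, tolerance = 1e-12)
})

test_that("length-1 sequences use the prior mixture density", {
  m <- toy_2state()
  x1 <- c(5, 20)
  mix <- log_sum_exp(c(log(0.6) + bvnorm_logdens(x1, m$means[1, ],
                                                 m$covariances[[1]]),
                       log(0.4) + bvnorm_logdens(x1, m$means[2, ],
                                                 m$covariances[[2]])))
  expect_equal(loglik_hmm(m, rbind(x1)), mix, tolerance = 1e-12)
})

test_that("forward likelihood and decoding match brute-force enumeration", {
  set.seed(42)
  for (rep in 1:30) {
    K <- sample(1:3, 1)
    n <- sample(1:4, 1)
    m <- random_model(K)
    xy <- cbind(runif(n, -100, 100), runif(n, -100, 100))
    expect_lt(abs(loglik_hmm(m, xy) - brute_force_loglik(m, xy)), 1e-8)
    expect_identical(decode_rois(m, xy), brute_force_decode(m, xy))
  }
})

test_that("likelihood is invariant to hidden-state relabeling", {
  set.seed(7)
  m <- random_model(3)
  perm <- c(3, 1, 2)
  mp <- gaussian_hmm(m$prior[perm], m$transitions[perm, perm],
                     m$means[perm, ], m$covariances[perm])
  xy <- cbind(runif(5, -50, 50), runif(5, -50, 50))
  expect_equal(loglik_hmm(m, xy), loglik_hmm(mp, xy), tolerance = 1e-12)
})

test_that("decoding breaks exact ties toward the lower ROI index", {
  m <- gaussian_hmm(c(0.5, 0.5), matrix(0.5, 2, 2),
                    rbind(c(-30, 0), c(30, 0)),
                    list(diag(2) * 100, diag(2) * 100))
  # fixation equidistant from both centers: everything ties
  expect_identical(decode_rois(m, rbind(c(0, 0))), 1L)
  # fixation exactly at center 2 must decode to ROI 2
  expect_identical(decode_rois(m, rbind(c(30, 0))), 2L)
})

test_that("degenerate models and empty sequences raise explicit errors", {
  m <- toy_2state()
  m$covariances[[2]] <- matrix(c(1, 1, 1, 1), 2)    # singular
  expect_error(loglik_hmm(m, rbind(c(0, 0))), "positive-definite|degeneracy")
  expect_error(loglik_hmm(toy_2state(), matrix(numeric(0), ncol = 2)),
               "empty")
})

test_that("sampling is seed-reproducible and respects forced paths", {
  m <- toy_2state()
  s1 <- sample_hmm_sequences(m, 5, 6, seed = 123)
  s2 <- sample_hmm_sequences(m, 5, 6, seed = 123)
  expect_identical(s1, s2)
  expect_error(sample_hmm_sequences(m, 2, 0, seed = 1), "positive")

  forced <- gaussian_hmm(c(1, 0), rbind(c(0, 1), c(1, 0)),
                         rbind(c(-50, 0), c(50, 0)),
                         list(diag(2) * 1e-6, diag(2) * 1e-6))
  s <- sample_hmm_sequences(forced, 3, 4, seed = 5)
  for (fx in s) {
    expect_identical(attr(fx, "states"), c(1L, 2L, 1L, 2L))
    expect_equal(fx$fixations[, "x"], c(-50, 50, -50, 50), tolerance = 0.1)
  }
})

test_that("empirical state occupancy matches the marginal distribution", {
  m <- toy_2state()
  seqs <- sample_hmm_sequences(m, 1000, 10, seed = 99)
  states <- unlist(lapply(seqs, attr, "states"))
  # marginal over 10 steps: average of pi %*% Psi^t
  marg <- Reduce(`+`, Reduce(function(p, .) p %*% m$transitions,
                             seq_len(9), init = rbind(m$prior),
                             accumulate = TRUE)) / 10
  emp <- tabulate(states, 2) / length(states)
  expect_lt(max(abs(emp - as.numeric(marg))), 0.02)
})

test_that("model JSON serialization round-trips exactly", {
  m <- toy_2state()
  path <- withr::local_tempfile(fileext = ".json")
  write_hmm_json(m, path, provenance = list(seed = 4, lower_bound = -12.5))
  back <- read_hmm_json(path)
  expect_equal(back$prior, m$prior, tolerance = 1e-12)
  expect_equal(back$transitions, m$transitions, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(back$means, m$means, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(back$covariances, m$covariances, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(attr(back, "provenance")$seed, 4)
})
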