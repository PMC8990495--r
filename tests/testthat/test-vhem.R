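quick_cfg <- function(...) {
  vhem_config(virtual_samples = 40, n_restarts = 2, ...)
}

make_two_camp_models <- function(n_per, seed) {
  proto <- make_prototypes()
  pop <- sample_population(proto, 2 * n_per, mix = 0.5, perturb = 0.15,
                           seed = seed)
  list(models = lapply(pop$participants, function(p) p$models$uu),
       truth = ifelse(pop$trait_table$archetype == "eyes_focused",
                      "eyes", "nose"))
}

test_that("median ROI count uses the round-up tie rule", {
  mk <- function(K) gaussian_hmm(rep(1 / K, K), matrix(1 / K, K, K),
                                 matrix(seq_len(2 * K), ncol = 2),
                                 rep(list(diag(2) * 10), K))
  expect_identical(median_roi_count(lapply(c(2, 3, 3, 4), mk)), 3L)
  expect_identical(median_roi_count(lapply(c(2, 2, 3, 3), mk)), 3L)
  expect_identical(median_roi_count(list(mk(5))), 5L)
  expect_error(median_roi_count(list()), "at least one")
})

test_that("clustering recovers a two-archetype population", {
  camps <- make_two_camp_models(15, seed = 41)
  cl <- cluster_vhem(camps$models, 2, 4, config = quick_cfg(), seed = 8)
  tab <- table(cl$assignments, camps$truth)
  acc <- max(sum(diag(tab)), sum(tab) - sum(diag(tab))) / sum(tab)
  expect_gte(acc, 0.9)
  expect_false(cl$degenerate)
  expect_s3_class(cl$pattern_a, "gaussian_hmm")
  expect_identical(cl$pattern_a$n_rois, 4L)
})

test_that("the clustering objective is monotone within a run", {
  camps <- make_two_camp_models(8, seed = 3)
  cl <- cluster_vhem(camps$models, 2, 3,
                     config = quick_cfg(max_iter = 40), seed = 5)
  expect_true(all(diff(cl$obj_trace) >
                    -1e-8 * (1 + abs(cl$obj_trace[-1]))))
})

test_that("clustering is invariant to the order of the input models", {
  camps <- make_two_camp_models(6, seed = 19)
  cl1 <- cluster_vhem(camps$models, 2, 3, config = quick_cfg(), seed = 4)
  perm <- c(7, 3, 11, 1, 12, 5, 9, 2, 10, 4, 8, 6)
  cl2 <- cluster_vhem(camps$models[perm], 2, 3, config = quick_cfg(),
                      seed = 4)
  a1 <- cl1$assignments[names(cl2$assignments)]
  same <- mean(a1 == cl2$assignments)
  expect_true(same == 1 || same == 0)   # identical up to cluster relabeling
})

test_that("recovery accuracy degrades as the prototypes merge", {
  proto <- make_prototypes()
  # shrink separation by blending Pattern A toward Pattern B
  merged <- function(w) {
    p <- proto
    p$pattern_a <- gazehmm:::blend_hmm(proto$pattern_a, proto$pattern_b, w)
    p
  }
  acc_at <- function(pp, seeds) {
    mean(vapply(seeds, function(s) {
      pop <- sample_population(pp, 24, mix = 0.5, perturb = 0.15, seed = s)
      models <- lapply(pop$participants, function(p) p$models$uu)
      cl <- cluster_vhem(models, 2, 4, config = quick_cfg(), seed = s + 1)
      tab <- table(cl$assignments, pop$trait_table$archetype)
      max(sum(diag(tab)), sum(tab) - sum(diag(tab))) / sum(tab)
    }, numeric(1)))
  }
  seeds <- c(61, 62)
  acc_full <- acc_at(proto, seeds)        # fully separated prototypes
  acc_near <- acc_at(merged(0.95), seeds) # nearly coincident prototypes
  expect_gte(acc_full, 0.9)
  expect_gt(acc_full, acc_near)
  expect_lte(acc_near, 0.85)              # chance-ish once patterns merge
})

test_that("identical input models yield equal patterns and a degeneracy flag", {
  proto <- make_prototypes()
  models <- rep(list(proto$pattern_a), 8)
  cl <- cluster_vhem(models, 2, 4, config = quick_cfg(), seed = 6)
  expect_true(cl$degenerate)
  # the two group HMMs describe the same distribution (equal likelihoods)
  probe <- sample_hmm_sequences(proto$pattern_a, 40, 8, seed = 9)
  lla <- mean(vapply(probe, function(s)
    loglik_hmm(cl$pattern_a, s), numeric(1)))
  llb <- mean(vapply(probe, function(s)
    loglik_hmm(cl$pattern_b, s), numeric(1)))
  expect_lt(abs(lla - llb), 0.5)
})

test_that("clustering rejects fewer models than clusters", {
  proto <- make_prototypes()
  expect_error(cluster_vhem(list(proto$pattern_a), 2, 2), "fewer models")
})

test_that("pattern separation margins behave as designed", {
  proto <- make_prototypes()
  ids <- sprintf("p%02d", 1:8)
  assign <- setNames(rep(c("A", "B"), each = 4), ids)
  pp <- structure(list(pattern_a = proto$pattern_a,
                       pattern_b = proto$pattern_b,
                       assignments = assign, n_group_rois = 4L,
                       degenerate = FALSE),
                  class = "pattern_pair")
  seqs <- lapply(seq_along(ids), function(i) {
    gen <- if (assign[i] == "A") proto$pattern_a else proto$pattern_b
    sample_hmm_sequences(gen, 15, 8, seed = 100 + i)
  })
  names(seqs) <- ids
  sep <- pattern_separation(seqs, pp)
  expect_true(all(sep$per_participant$margin > 0))
  expect_gt(sep$f_stat, 10)
  expect_lt(sep$p_value, 0.01)
  expect_true(sep$effect_size > 0 && sep$effect_size < 1)
  expect_true(sep$effect_ci[1] <= sep$effect_size + 1e-8)

  # identical patterns: all margins zero, F collapses to zero
  pp0 <- pp
  pp0$pattern_b <- pp0$pattern_a
  sep0 <- pattern_separation(seqs, pp0)
  expect_equal(max(abs(sep0$per_participant$margin)), 0, tolerance = 1e-10)
  expect_equal(sep0$f_stat, 0, tolerance = 1e-6)

  # single participant in a group: flagged unstable
  pp1 <- pp
  pp1$assignments[] <- c("A", rep("B", 7))
  expect_warning(sep1 <- pattern_separation(seqs, pp1), "unstable")
  expect_false(sep1$stable)
})
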