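test_that("design arithmetic matches the reference experiment", {
  des <- experiment_design()
  expect_identical(des$n_faces, 256L)
  expect_identical(des$targets_per_condition_per_block * 4L,
                   des$targets_per_block)
  expect_error(experiment_design(targets_per_condition_per_block = 3),
               "must equal")
})

test_that("face assignment balances conditions within and across participants", {
  des <- experiment_design()
  fa <- assign_faces(des, 1)
  expect_identical(nrow(fa), 256L)
  expect_identical(length(unique(fa$face_id)), 256L)
  for (b in unique(fa$block)) {
    blk <- fa[fa$block == b, ]
    tcount <- table(blk$condition[blk$role == "target"])
    fcount <- table(blk$condition[blk$role == "foil"])
    expect_true(all(tcount == 4L))
    expect_true(all(fcount == 4L))      # foils matched to target conditions
  }
  # Latin square: across 4 counterbalancing groups a face sees all conditions
  conds <- vapply(1:4, function(p) {
    fa_p <- assign_faces(des, p)
    fa_p$condition[fa_p$face_id == 1]
  }, character(1))
  expect_setequal(conds, c("uu", "um", "mu", "mm"))
})

test_that("prototypes match the intended qualitative structure", {
  proto <- make_prototypes()
  b <- proto$pattern_b
  eyes <- 2L                           # ROI order: broad, eyes, nose, forehead
  expect_gte(b$transitions[eyes, eyes], 0.9)
  expect_gte(b$transitions[1L, eyes], 0.9)   # broad -> eyes switch dominates
  ha <- fixation_entropies(proto$pattern_a)
  hb <- fixation_entropies(b)
  expect_lt(hb$h2_given_1, ha$h2_given_1)
  expect_lt(hb$h3_given_2, ha$h3_given_2)

  # serialisation round-trip preserves the prototypes exactly
  path <- withr::local_tempfile(fileext = ".json")
  write_hmm_json(b, path)
  back <- read_hmm_json(path)
  expect_equal(back$transitions, b$transitions, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_error(make_prototypes(layout = list(
    broad = list(mean = c(0, 0), cov = diag(2)),
    eyes = list(mean = c(0, 0), cov = diag(2)),
    nose = list(mean = c(1, 0), cov = diag(2)),
    forehead = list(mean = c(2, 0), cov = diag(2)))), "degenerate")
})

test_that("population sampling honors mix, perturbation and determinism", {
  proto <- make_prototypes()
  popA <- sample_population(proto, 10, mix = 1, seed = 2)
  expect_true(all(popA$trait_table$archetype == "eyes_focused"))

  # zero perturbation and neutral traits leave the prototypes untouched
  neutral <- trait_model(strategy_shift_mean = 0, strategy_shift_sd = 0,
                         consistency_gain_mean = 0, consistency_gain_sd = 0)
  pop0 <- sample_population(proto, 4, mix = 0, perturb = 0,
                            traits = neutral, seed = 3)
  for (p in pop0$participants) {
    expect_equal(p$models$uu, proto$pattern_a, tolerance = 1e-12)
    expect_equal(p$models$mu, proto$pattern_a, tolerance = 1e-12)
    expect_equal(p$models$learn_masked, proto$pattern_a, tolerance = 1e-12)
  }

  p1 <- sample_population(proto, 6, seed = 11)
  p2 <- sample_population(proto, 6, seed = 11)
  expect_identical(p1$trait_table, p2$trait_table)
  expect_equal(p1$participants, p2$participants, tolerance = 1e-15)
})

test_that("planted strategy shifts move the masked conditions toward Pattern B", {
  proto <- make_prototypes()
  pop <- sample_population(proto, 30, mix = 0, perturb = 0.05, seed = 7)
  # generating-model A-B score: masked recognition must sit closer to B
  ab_of <- function(m) {
    seqs <- sample_hmm_sequences(m, 20, 6, seed = 1)
    ab_scale(seqs, proto$pattern_a, proto$pattern_b)$value
  }
  d_um <- vapply(pop$participants[1:10], function(p)
    ab_of(p$models$um) - ab_of(p$models$uu), numeric(1))
  expect_lt(mean(d_um), 0)
})

test_that("the simulated experiment has the right trial structure", {
  des <- experiment_design(n_participants = 4, n_blocks = 2)
  proto <- make_prototypes()
  pop <- sample_population(proto, 4, seed = 5)
  ds <- simulate_experiment(des, pop, seed = 6)
  fx <- ds$fixations[[1]]
  expect_identical(length(fx$learn_unmasked) + length(fx$learn_masked),
                   2L * des$targets_per_block)
  expect_identical(length(fx$uu) + length(fx$um) + length(fx$mu) +
                     length(fx$mm),
                   2L * (des$targets_per_block + des$foils_per_block))
  resp <- ds$responses[ds$responses$participant_id == "p001", ]
  expect_identical(nrow(resp), 2L * 32L)
  expect_identical(sum(resp$is_old), 2L * 16L)
  counts <- table(resp$condition, resp$is_old)
  expect_true(all(counts == 8L))

  # byte-identical datasets from the same seed
  ds2 <- simulate_experiment(des, pop, seed = 6)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_dataset(ds, d1); write_dataset(ds2, d2)
  for (f in list.files(d1))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
})

test_that("null couplings and offsets yield flat condition d-primes", {
  des <- experiment_design(n_participants = 60, n_blocks = 4)
  proto <- make_prototypes()
  pop <- sample_population(proto, 60, seed = 8)
  ds <- simulate_experiment(des, pop,
                            coupling = list(strategy = 0, consistency = 0),
                            dprime_offsets = c(uu = 0, um = 0, mu = 0,
                                               mm = 0),
                            fixation_cells = character(0), seed = 9)
  resp <- ds$responses
  dps <- tapply(seq_len(nrow(resp)), resp$condition, function(idx) {
    d <- resp[idx, ]
    mean(vapply(split(d, d$participant_id), function(p) {
      old <- p[p$is_old, ]; new <- p[!p$is_old, ]
      dprime(sum(old$response), nrow(old), sum(new$response),
             nrow(new))$dprime
    }, numeric(1)))
  })
  expect_lt(max(dps) - min(dps), 0.2)
  # and the planted per-cell sensitivities are exactly equal
  expect_equal(max(apply(ds$ground_truth$d_cell, 1, function(r)
    max(r) - min(r))), 0, tolerance = 1e-12)
})
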