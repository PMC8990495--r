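# Synthetic masked-face recognition experiment with planted ground truth.
#
# The generator emulates a 2x2 within-subject design: faces learned with or
# without a mask and recognised with or without a mask (four cells: uu, um,
# mu, mm, learning condition first). Each participant carries a latent gaze
# archetype (eyes-focused vs nose-focused), trait scores that drive
# condition-specific strategy shifts, a baseline d-prime and criterion, and
# cognitive covariates correlated with the traits, so that every stage of
# the analysis pipeline can be checked against known truth.

#' Experiment design parameters
#'
#' Defaults follow the reference design: 88 participants, 8 blocks, 16
#' learning faces per block with 4 target stimuli in each of the four mask
#' conditions, 16 condition-matched foils at recognition, 5-second learning
#' exposure, and Latin-square counterbalancing of faces over conditions
#' across participants. Light/mask-color labels are carried as metadata only.
#'
#' @param n_participants,n_blocks,targets_per_block,foils_per_block,
#'   targets_per_condition_per_block Design counts.
#' @param learning_exposure_ms Learning exposure duration (metadata).
#' @return List of class `"experiment_design"`. The total number of unique
#'   face identities consumed is `n_blocks * (targets_per_block +
#'   foils_per_block)` (256 under defaults).
#' @export
experiment_design <- function(n_participants = 88, n_blocks = 8,
                              targets_per_block = 16, foils_per_block = 16,
                              targets_per_condition_per_block = 4,
                              learning_exposure_ms = 5000) {
  if (targets_per_condition_per_block * 4L != targets_per_block)
    stop("targets_per_condition_per_block x 4 must equal targets_per_block")
  if (foils_per_block != targets_per_block)
    stop("foil conditions must match target conditions one-to-one")
  structure(list(n_participants = as.integer(n_participants),
                 n_blocks = as.integer(n_blocks),
                 targets_per_block = as.integer(targets_per_block),
                 foils_per_block = as.integer(foils_per_block),
                 targets_per_condition_per_block =
                   as.integer(targets_per_condition_per_block),
                 learning_exposure_ms = learning_exposure_ms,
                 n_faces = as.integer(n_blocks *
                                        (targets_per_block + foils_per_block))),
            class = "experiment_design")
}

#' Latin-square face-to-condition assignment for one participant
#'
#' Faces are organised in quartets; each quartet rotates through the four
#' mask conditions as a function of the participant's counterbalancing group
#' (participant index mod 4), so every face appears in every condition
#' equally often across participants.
#'
#' @param design An [experiment_design()].
#' @param participant_index 1-based participant index.
#' @return Data frame: face_id, block, role (target/foil), condition
#'   (uu/um/mu/mm), light ("white_blue"/"yellow_white" learning-light/mask
#'   metadata).
#' @export
assign_faces <- function(design, participant_index) {
  conds <- c("uu", "um", "mu", "mm")
  rot <- (participant_index - 1L) %% 4L
  per_block <- design$targets_per_block + design$foils_per_block
  out <- vector("list", design$n_blocks)
  for (b in seq_len(design$n_blocks)) {
    face0 <- (b - 1L) * per_block
    role <- rep(c("target", "foil"),
                c(design$targets_per_block, design$foils_per_block))
    # quartet q gets condition (q + rotation) mod 4, within each role
    q_t <- rep(seq_len(design$targets_per_block / 4L), each = 4L)
    slot <- rep(seq_len(4L), times = design$targets_per_block / 4L)
    cond_t <- conds[((slot + rot - 1L) %% 4L) + 1L]
    out[[b]] <- data.frame(
      face_id = face0 + seq_len(per_block),
      block = b, role = role,
      condition = c(cond_t, cond_t),
      light = if (b <= design$n_blocks / 2L) "white_blue" else "yellow_white")
  }
  do.call(rbind, out)
}

#' Default ROI layout for the prototype gaze patterns
#'
#' Four anatomical ROIs in the face-centered frame (pixels; origin at the
#' midpoint between the eye centers, y downward): a broad center region
#' spanning eyes and nose, an eye-band region, a nose region, and a
#' forehead region.
#'
#' @param face_box Face width/height in pixels.
#' @return Named list of `list(mean, cov)` per ROI.
#' @export
roi_layout <- function(face_box = c(256, 256)) {
  s <- face_box[1L] / 256
  list(
    broad    = list(mean = c(0, 25) * s,  cov = diag(c(55, 45)^2 * s^2)),
    eyes     = list(mean = c(0, 0) * s,   cov = diag(c(60, 18)^2 * s^2)),
    nose     = list(mean = c(0, 70) * s,  cov = diag(c(25, 25)^2 * s^2)),
    forehead = list(mean = c(0, -45) * s, cov = diag(c(45, 22)^2 * s^2)))
}

#' Prototype eyes-focused and nose-focused gaze patterns
#'
#' Builds the two generating HMMs the population is sampled around.
#' Pattern A starts at the broad center region and explores it, the eyes
#' and the forehead with balanced transitions; Pattern B starts at the
#' broad region, then concentrates on the eye band with a high
#' self-transition (>= 0.9), giving it a lower conditional transition
#' entropy than Pattern A.
#'
#' @param face_box Face width/height in pixels.
#' @param layout ROI geometry, as from [roi_layout()].
#' @return List of class `"pattern_pair"` with `pattern_a`, `pattern_b`,
#'   empty `assignments`, and `n_group_rois = 4` (ROI order: broad, eyes,
#'   nose, forehead).
#' @export
make_prototypes <- function(face_box = c(256, 256),
                            layout = roi_layout(face_box)) {
  mus <- t(vapply(layout, `[[`, numeric(2), "mean"))
  if (any(dist(mus) < 1e-6))
    stop("degenerate layout: coincident ROI centers")
  covs <- lapply(layout, `[[`, "cov")
  a <- gaussian_hmm(
    prior = c(1, 0, 0, 0),
    transitions = rbind(c(.36, .38, .06, .20),
                        c(.05, .85, .05, .05),
                        c(.05, .05, .85, .05),
                        c(.05, .05, .05, .85)),
    means = mus, covariances = covs)
  b <- gaussian_hmm(
    prior = c(.96, 0, .01, .03),
    transitions = rbind(c(.01, .95, .02, .02),
                        c(.02, .94, .02, .02),
                        c(.05, .60, .30, .05),
                        c(.02, .08, .02, .88)),
    means = mus, covariances = covs)
  structure(list(pattern_a = a, pattern_b = b,
                 assignments = character(0), n_group_rois = 4L,
                 degenerate = FALSE),
            class = "pattern_pair")
}

#' Population trait distribution
#'
#' @param strategy_shift_mean,strategy_shift_sd Distribution of the
#'   propensity to shift toward the eyes-focused pattern when recognising
#'   unmasked faces that were learned masked (bounded to \[0, 0.9\]).
#' @param consistency_gain_mean,consistency_gain_sd Distribution of the
#'   propensity to sharpen gaze transitions for masked-face recognition
#'   (bounded to \[0, 1.5\]).
#' @param base_dprime_mean,base_dprime_sd Baseline sensitivity (>= 0).
#' @param criterion_sd Response-criterion spread around 0.
#' @param covariate_loading Strength with which the intelligence proxy and
#'   cognitive covariates load on the traits.
#' @return List of class `"trait_model"`.
#' @export
trait_model <- function(strategy_shift_mean = 0.35, strategy_shift_sd = 0.18,
                        consistency_gain_mean = 0.6, consistency_gain_sd = 0.25,
                        base_dprime_mean = 1.5, base_dprime_sd = 0.35,
                        criterion_sd = 0.2, covariate_loading = 0.4) {
  structure(as.list(environment()), class = "trait_model")
}

# Dirichlet-style perturbation of a probability vector; scale = 0 returns
# the vector unchanged.
#' @noRd
perturb_prob <- function(p, scale) {
  if (scale == 0) return(p)
  conc <- p * (20 / scale) + 1e-3
  g <- stats::rgamma(length(p), shape = conc)
  g / sum(g)
}

# Convex blend of two HMMs with identical state layout.
#' @noRd
blend_hmm <- function(m, target, w) {
  if (w == 0) return(m)
  covs <- lapply(seq_len(m$n_rois), function(k)
    (1 - w) * m$covariances[[k]] + w * target$covariances[[k]])
  gaussian_hmm((1 - w) * m$prior + w * target$prior,
               (1 - w) * m$transitions + w * target$transitions,
               (1 - w) * m$means + w * target$means, covs)
}

# Sharpen transition rows (and prior) by a power > 1, reducing entropy.
#' @noRd
sharpen_hmm <- function(m, gain) {
  if (gain == 0) return(m)
  pw <- function(p) { q <- p^(1 + gain); q / sum(q) }
  gaussian_hmm(pw(m$prior), t(apply(m$transitions, 1L, pw)),
               m$means, m$covariances)
}

# Parameter-space distance between two HMMs with matched state layouts:
# mean total-variation distance of prior and transition rows plus scaled
# mean ROI-center displacement. Monotone in how far one model moved.
#' @noRd
hmm_param_distance <- function(a, b) {
  tv <- function(p, q) sum(abs(p - q)) / 2
  mean(c(tv(a$prior, b$prior),
         vapply(seq_len(a$n_rois), function(i)
           tv(a$transitions[i, ], b$transitions[i, ]), numeric(1)))) +
    mean(sqrt(rowSums((a$means - b$means)^2))) / 100
}

# Random perturbation of a prototype HMM; scale = 0 is the identity.
#' @noRd
perturb_hmm <- function(m, scale) {
  if (scale == 0) return(m)
  for (attempt in 1:100) {
    ok <- TRUE
    means <- m$means + matrix(stats::rnorm(2L * m$n_rois, sd = 12 * scale),
                              ncol = 2L)
    covs <- lapply(m$covariances, function(sig) {
      f <- exp(stats::rnorm(1L, sd = 0.4 * scale))
      sig * f
    })
    prior <- perturb_prob(m$prior, scale)
    trans <- t(apply(m$transitions, 1L, perturb_prob, scale = scale))
    out <- tryCatch(gaussian_hmm(prior, trans, means, covs),
                    error = function(e) NULL)
    if (!is.null(out)) return(out)
  }
  stop("failed to generate a valid perturbed model in 100 attempts")
}

#' Sample a participant population around the prototypes
#'
#' Draws per-participant traits and condition-specific generating HMMs.
#' Each participant's base model is a perturbed copy of their archetype's
#' prototype. Recognition of masked faces (cells um, mm) shifts the model
#' toward Pattern B and sharpens its transitions in proportion to the
#' participant's `consistency_gain`; recognition of unmasked faces that
#' were learned masked (cell mu) shifts toward Pattern B in proportion to
#' `strategy_shift`. Learning-phase models are the base model in both mask
#' conditions (no planted learning-phase effect).
#'
#' @param prototypes A `"pattern_pair"` from [make_prototypes()].
#' @param n Number of participants.
#' @param mix Proportion of eyes-focused (Pattern B) archetypes.
#' @param perturb Perturbation scale (0 = every participant equals the
#'   prototype exactly).
#' @param traits A [trait_model()]. With `perturb = 0` the "neutral traits"
#'   interpretation applies: trait-driven model shifts are still applied
#'   unless the trait means/sds are zero.
#' @param seed Integer seed.
#' @return List of class `"population"`: per participant a list with
#'   `traits` and `models` (named: learn_unmasked, learn_masked, uu, um,
#'   mu, mm), plus the trait table as attribute-free data frame element
#'   `trait_table` and `prototypes`.
#' @export
sample_population <- function(prototypes, n, mix = 0.5, perturb = 0.15,
                              traits = trait_model(), seed = 1) {
  stopifnot(mix >= 0, mix <= 1, perturb >= 0, n >= 1)
  with_seed(seed, {
    n_eyes <- round(mix * n)
    archetype <- sample(rep(c("eyes_focused", "nose_focused"),
                            c(n_eyes, n - n_eyes)))
    clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)
    tt <- data.frame(
      participant_id = sprintf("p%03d", seq_len(n)),
      archetype = archetype,
      strategy_shift = clamp(stats::rnorm(n, traits$strategy_shift_mean,
                                          traits$strategy_shift_sd), 0, 0.9),
      consistency_gain = clamp(stats::rnorm(n, traits$consistency_gain_mean,
                                            traits$consistency_gain_sd), 0, 1.5),
      base_dprime = pmax(stats::rnorm(n, traits$base_dprime_mean,
                                      traits$base_dprime_sd), 0),
      criterion = stats::rnorm(n, 0, traits$criterion_sd))
    lam <- traits$covariate_loading
    zs <- scale(tt$strategy_shift)[, 1L]
    zg <- scale(tt$consistency_gain)[, 1L]
    tt$rspm <- lam * zg + sqrt(max(0, 1 - lam^2)) * stats::rnorm(n)
    tt$working_memory <- lam * zs + sqrt(max(0, 1 - lam^2)) * stats::rnorm(n)
    tt$planning <- 0.5 * lam * zg + stats::rnorm(n)
    tt$attention <- stats::rnorm(n)
    participants <- lapply(seq_len(n), function(i) {
      proto <- if (archetype[i] == "eyes_focused") prototypes$pattern_b
               else prototypes$pattern_a
      base <- perturb_hmm(proto, perturb)
      masked_recog <- sharpen_hmm(blend_hmm(base, prototypes$pattern_b, 0.5),
                                  tt$consistency_gain[i])
      models <- list(
        learn_unmasked = base,
        learn_masked = base,
        uu = base,
        um = masked_recog,
        mu = blend_hmm(base, prototypes$pattern_b, tt$strategy_shift[i]),
        mm = masked_recog)
      list(traits = tt[i, ], models = models)
    })
    names(participants) <- tt$participant_id
    # realized (measurable) condition adjustments; the behavioral couplings
    # act on these rather than on the raw propensity traits, so performance
    # change tracks the adjustment a participant actually makes
    tt$realized_strategy_adjustment <- vapply(participants, function(p)
      hmm_param_distance(p$models$uu, p$models$mu), numeric(1))
    tt$realized_consistency_change <- vapply(participants, function(p)
      fixation_entropies(p$models$uu)$h3_given_2 -
        fixation_entropies(p$models$um)$h3_given_2, numeric(1))
    for (pid in tt$participant_id)
      participants[[pid]]$traits <- tt[tt$participant_id == pid, ]
    structure(list(participants = participants, trait_table = tt,
                   prototypes = prototypes, mix = mix, perturb = perturb,
                   seed = seed),
              class = "population")
  })
}

# Batch ancestral sampling: S sequences with given lengths from one model,
# using the current RNG state. Returns list(xy = list of T x 2 matrices,
# states = list of integer vectors).
#' @noRd
sample_paths_batch <- function(model, lengths) {
  S <- length(lengths)
  maxT <- max(lengths)
  K <- model$n_rois
  st <- matrix(NA_integer_, S, maxT)
  cp_pi <- cumsum(model$prior)
  st[, 1L] <- findInterval(stats::runif(S), cp_pi,
                           rightmost.closed = TRUE) + 1L
  st[, 1L][st[, 1L] > K] <- K
  if (maxT > 1L) {
    cp_A <- apply(model$transitions, 1L, cumsum)   # K x K, column = from-state
    for (t in 2L:maxT) {
      active <- which(lengths >= t)
      if (!length(active)) next
      prev <- st[active, t - 1L]
      u <- stats::runif(length(active))
      for (k in unique(prev)) {
        sel <- prev == k
        nxt <- findInterval(u[sel], cp_A[, k], rightmost.closed = TRUE) + 1L
        nxt[nxt > K] <- K
        st[active[sel], t] <- nxt
      }
    }
  }
  # positions, drawn per state in fixation order
  ord_idx <- which(!is.na(t(st)))                  # column-major over t(st): by sequence
  seq_of <- rep(seq_len(S), each = maxT)[ord_idx]
  t_of <- rep(seq_len(maxT), times = S)[ord_idx]
  states <- t(st)[ord_idx]
  xy <- matrix(0, length(states), 2L)
  for (k in seq_len(K)) {
    rows <- which(states == k)
    if (length(rows))
      xy[rows, ] <- rmvnorm2(length(rows), model$means[k, ],
                             model$covariances[[k]])
  }
  split_idx <- split(seq_along(states), seq_of)
  list(xy = lapply(split_idx, function(ix) xy[ix, , drop = FALSE]),
       states = lapply(split_idx, function(ix) states[ix]))
}

#' Simulate the full experiment
#'
#' Generates fixation sequences for every learning and recognition trial
#' from each participant's condition-specific model, and old/new responses
#' from an equal-variance signal-detection model in which the per-condition
#' sensitivity is `base_dprime + condition offset + coupling x trait`.
#' Response times are log-normal with condition shifts. All planted
#' quantities are returned in `ground_truth`.
#'
#' @param design An [experiment_design()].
#' @param population A [sample_population()] result of matching size.
#' @param coupling List with `strategy` (d-prime units per unit of realized
#'   model adjustment toward Pattern B, applied in cell mu) and
#'   `consistency` (d-prime units per bit of realized transition-entropy
#'   reduction, applied in cell um); the planted couplings make larger
#'   strategy adjustment predict smaller performance impairment.
#' @param dprime_offsets Named condition offsets on d-prime
#'   (uu/um/mu/mm).
#' @param rt_meanlog_offsets Named condition offsets on log RT.
#' @param learn_fix_mean,recog_fix_mean Mean fixations per learning /
#'   recognition trial (truncated-at-1 Poisson).
#' @param fixation_cells Cells for which fixation sequences are generated
#'   (default all six); responses are always generated for every
#'   recognition cell. Restricting this speeds up replicate studies that
#'   only score a subset of cells.
#' @param seed Integer seed; the same seed reproduces the dataset exactly.
#' @return List of class `"synthetic_dataset"`: `fixations` (nested list
#'   participant -> cell -> list of `fixseq`; learning cells
#'   `learn_unmasked`/`learn_masked`, recognition cells uu/um/mu/mm),
#'   `responses` (per-trial data frame), `covariates`, `ground_truth`,
#'   `design`.
#' @export
simulate_experiment <- function(design, population,
                                coupling = list(strategy = 3.5,
                                                consistency = 0.6),
                                dprime_offsets = c(uu = 0, um = -0.45,
                                                   mu = -0.55, mm = -0.35),
                                rt_meanlog_offsets = c(uu = 0, um = 0.10,
                                                      mu = 0.08, mm = 0.04),
                                learn_fix_mean = 15, recog_fix_mean = 6,
                                fixation_cells = c("learn_unmasked",
                                                   "learn_masked",
                                                   "uu", "um", "mu", "mm"),
                                seed = 1) {
  n <- design$n_participants
  if (length(population$participants) != n)
    stop("population size does not match design")
  tt <- population$trait_table
  conds <- c("uu", "um", "mu", "mm")
  n_old_cell <- design$targets_per_condition_per_block * design$n_blocks
  with_seed(seed, {
    fixations <- vector("list", n)
    names(fixations) <- tt$participant_id
    resp_list <- vector("list", n)
    d_cell_tab <- matrix(0, n, 4L, dimnames = list(tt$participant_id, conds))
    for (i in seq_len(n)) {
      pid <- tt$participant_id[i]
      part <- population$participants[[pid]]
      faces <- assign_faces(design, i)
      # planted condition sensitivities: the couplings act on the realized
      # adjustments so performance change tracks measurable strategy change
      d_cell <- pmax(0, part$traits$base_dprime + dprime_offsets[conds] +
        c(0,
          coupling$consistency *
            (part$traits$realized_consistency_change -
               mean(tt$realized_consistency_change)),
          coupling$strategy *
            (part$traits$realized_strategy_adjustment -
               mean(tt$realized_strategy_adjustment)),
          0))
      names(d_cell) <- conds
      d_cell_tab[i, ] <- d_cell
      crit <- part$traits$criterion
      cells <- list()
      # learning phase: targets only, grouped by learning-mask condition
      targ <- faces[faces$role == "target", ]
      for (lm in c("unmasked", "masked")) {
        cname <- paste0("learn_", lm)
        if (!cname %in% fixation_cells) next
        sel <- targ[substr(targ$condition, 1L, 1L) == substr(lm, 1L, 1L), ]
        lens <- pmax(1L, stats::rpois(nrow(sel), learn_fix_mean))
        paths <- sample_paths_batch(part$models[[cname]], lens)
        cells[[cname]] <- lapply(seq_len(nrow(sel)), function(j)
          new_fixseq(pid, paste0("L", sel$face_id[j]), "learning", lm,
                     "not_applicable", paths$xy[[j]], rep(250, lens[j])))
      }
      # recognition phase: targets and foils per cell
      resp_cell <- vector("list", 4L)
      for (ci in seq_along(conds)) {
        cc <- conds[ci]
        sel <- faces[faces$condition == cc, ]
        lm <- if (substr(cc, 1L, 1L) == "u") "unmasked" else "masked"
        rm_ <- if (substr(cc, 2L, 2L) == "u") "unmasked" else "masked"
        if (cc %in% fixation_cells) {
          lens <- pmax(1L, stats::rpois(nrow(sel), recog_fix_mean))
          paths <- sample_paths_batch(part$models[[cc]], lens)
          cells[[cc]] <- lapply(seq_len(nrow(sel)), function(j)
            new_fixseq(pid, paste0("R", sel$face_id[j]), "recognition",
                       lm, rm_, paths$xy[[j]], rep(250, lens[j])))
        }
        is_old <- sel$role == "target"
        p_yes <- ifelse(is_old,
                        stats::pnorm(d_cell[cc] / 2 - crit),
                        stats::pnorm(-d_cell[cc] / 2 - crit))
        said_yes <- stats::runif(nrow(sel)) < p_yes
        rt <- stats::rlnorm(nrow(sel),
                            meanlog = log(900) + rt_meanlog_offsets[cc],
                            sdlog = 0.3)
        resp_cell[[ci]] <- data.frame(
          participant_id = pid, trial_id = paste0("R", sel$face_id),
          block = sel$block, learn_mask = lm, recog_mask = rm_,
          condition = cc, is_old = is_old, response = said_yes,
          correct = said_yes == is_old, rt_ms = round(rt, 1))
      }
      fixations[[pid]] <- cells
      resp_list[[i]] <- do.call(rbind, resp_cell)
    }
    responses <- do.call(rbind, resp_list)
    rownames(responses) <- NULL
    covars <- tt[, c("participant_id", "rspm", "working_memory",
                     "planning", "attention")]
    structure(list(fixations = fixations, responses = responses,
                   covariates = covars,
                   ground_truth = list(traits = tt,
                                       d_cell = d_cell_tab,
                                       coupling = coupling,
                                       dprime_offsets = dprime_offsets,
                                       rt_meanlog_offsets = rt_meanlog_offsets,
                                       prototypes = population$prototypes,
                                       n_old_per_cell = n_old_cell,
                                       seed = seed),
                   design = design),
              class = "synthetic_dataset")
  })
}

#' Write a synthetic dataset to disk
#'
#' Writes the fixation CSV, a responses CSV, a covariates CSV, and a
#' ground-truth JSON under `dir`.
#'
#' @param dataset A `"synthetic_dataset"`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  seqs <- unlist(lapply(dataset$fixations, function(cells)
    unlist(cells, recursive = FALSE)), recursive = FALSE)
  write_fixations(seqs, file.path(dir, "fixations.csv"))
  utils::write.csv(dataset$responses, file.path(dir, "responses.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(dataset$covariates, file.path(dir, "covariates.csv"),
                   row.names = FALSE, quote = FALSE)
  gt <- dataset$ground_truth
  gt$prototypes <- NULL
  jsonlite::write_json(gt, file.path(dir, "ground_truth.json"),
                       digits = NA, auto_unbox = TRUE, dataframe = "columns")
  invisible(dir)
}
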