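# End-to-end analysis pipeline: simulate (or load) -> fit individual HMMs ->
# cluster into representative patterns per phase -> A-B scale and entropy
# metrics -> signal-detection summaries -> planned contrasts and
# strategy-change vs performance-change correlations.

#' Pipeline configuration
#'
#' Collects every analysis setting behind one object. Defaults mirror the
#' reference analysis (ROI range 1-10 with 5 restarts; two representative
#' patterns per phase; entropies in bits; half-count d-prime correction);
#' smaller ROI ranges / restart and virtual-sample counts give proportionally
#' faster runs with the same structure.
#'
#' @param seed Master seed for simulation and fitting.
#' @param design An [experiment_design()].
#' @param mix,perturb Population composition passed to [sample_population()].
#' @param roi_range,n_restarts,vb_max_iter,vb_tol VBEM settings.
#' @param vhem VHEM settings, a [vhem_config()].
#' @param entropy_base Base for entropies (2 = bits).
#' @param dprime_correction `"half_count"` or `"none"`.
#' @param min_sequences_per_cell Participant-cells with fewer fixation
#'   sequences are excluded from eye-movement (not behavioral) analyses.
#' @param covariates Covariate column names partialled out in the partial
#'   correlations.
#' @param fixations_csv,responses_csv,covariates_csv Optional input paths;
#'   when absent a synthetic dataset is generated from `design`.
#' @param out_dir Optional output directory for CSV/JSON artifacts.
#' @return List of class `"pipeline_config"`.
#' @export
pipeline_config <- function(seed = 1, design = experiment_design(),
                            mix = 0.5, perturb = 0.15,
                            roi_range = 1:10, n_restarts = 5,
                            vb_max_iter = 300, vb_tol = 1e-6,
                            vhem = vhem_config(),
                            entropy_base = 2,
                            dprime_correction = "half_count",
                            min_sequences_per_cell = 10,
                            covariates = c("rspm", "working_memory",
                                           "planning", "attention"),
                            fixations_csv = NULL, responses_csv = NULL,
                            covariates_csv = NULL, out_dir = NULL) {
  structure(as.list(environment()), class = "pipeline_config")
}

#' Read a pipeline configuration from YAML or JSON
#'
#' Scalar fields override the [pipeline_config()] defaults; `design` and
#' `vhem` sub-maps are passed to their constructors.
#'
#' @param path Config file (`.yaml`/`.yml` or `.json`).
#' @return A `"pipeline_config"`.
#' @export
read_pipeline_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
         else jsonlite::read_json(path, simplifyVector = TRUE)
  args <- list()
  if (!is.null(raw$design)) args$design <- do.call(experiment_design, raw$design)
  if (!is.null(raw$vhem)) args$vhem <- do.call(vhem_config, raw$vhem)
  for (nm in setdiff(names(raw), c("design", "vhem"))) args[[nm]] <- raw[[nm]]
  do.call(pipeline_config, args)
}

# Order a clustered pattern pair so that "A" is the broader, less
# transition-consistent pattern (higher conditional entropy h2|1) and "B"
# the more consistent, eyes-focused one.
#' @noRd
orient_pattern_pair <- function(pp, base = 2) {
  hA <- fixation_entropies(pp$pattern_a, base)$h2_given_1
  hB <- fixation_entropies(pp$pattern_b, base)$h2_given_1
  if (hA >= hB) return(pp)
  tmp <- pp$pattern_a; pp$pattern_a <- pp$pattern_b; pp$pattern_b <- tmp
  pp$assignments[] <- ifelse(pp$assignments == "A", "B", "A")
  pp$responsibilities <- pp$responsibilities[, c(2L, 1L), drop = FALSE]
  pp
}

#' Run the full analysis pipeline
#'
#' Fits per participant two learning-phase HMMs (unmasked/masked) and four
#' recognition-phase HMMs (cells uu/um/mu/mm), clusters each phase's
#' individual models into two representative patterns, and derives the A-B
#' scale, entropy profiles, d-prime / criterion / correct-RT summaries, the
#' three planned mask-use contrasts (um, mu and mm, each against the uu
#' baseline) for every dependent variable, and the correlations between
#' eye-movement change and d-prime change (with and without covariate
#' partialling).
#'
#' @param config A [pipeline_config()].
#' @param dataset Optional pre-built `"synthetic_dataset"`; by default one
#'   is simulated (or read from the configured CSV paths).
#' @return List of class `"pipeline_report"`; see elements `metrics`
#'   (per participant-cell table), `anova`, `contrasts`, `correlations`,
#'   `separation`, `patterns`, `exclusions`, `provenance`.
#' @export
run_pipeline <- function(config = pipeline_config(), dataset = NULL) {
  seeds <- derive_seeds(config$seed, 6)
  if (is.null(dataset)) {
    if (!is.null(config$fixations_csv)) {
      dataset <- load_dataset(config)
    } else {
      proto <- make_prototypes()
      pop <- sample_population(proto, config$design$n_participants,
                               mix = config$mix, perturb = config$perturb,
                               seed = seeds[1])
      dataset <- simulate_experiment(config$design, pop, seed = seeds[2])
    }
  }
  learn_cells <- c("learn_unmasked", "learn_masked")
  recog_cells <- c("uu", "um", "mu", "mm")
  ids <- names(dataset$fixations)

  # --- individual HMMs per participant-cell, with exclusion accounting ----
  fits <- list()
  exclusions <- list()
  fit_seed <- derive_seeds(seeds[3], length(ids) * 6L)
  si <- 0L
  for (pid in ids) {
    for (cell in c(learn_cells, recog_cells)) {
      si <- si + 1L
      seqs <- dataset$fixations[[pid]][[cell]]
      if (length(seqs) < config$min_sequences_per_cell) {
        exclusions[[length(exclusions) + 1L]] <- data.frame(
          participant_id = pid, cell = cell, n_sequences = length(seqs),
          reason = "too few sequences")
        next
      }
      fits[[paste(pid, cell, sep = ".")]] <-
        select_n_rois(seqs, config$roi_range, n_restarts = config$n_restarts,
                      seed = fit_seed[si], max_iter = config$vb_max_iter,
                      tol = config$vb_tol)
    }
  }
  exclusions <- if (length(exclusions)) do.call(rbind, exclusions)
                else data.frame(participant_id = character(0),
                                cell = character(0),
                                n_sequences = integer(0),
                                reason = character(0))

  # --- cluster each phase's models into two representative patterns ------
  cluster_phase <- function(cells, phase_seed) {
    keys <- names(fits)[sub("^[^.]*\\.", "", names(fits)) %in% cells]
    models <- lapply(fits[keys], `[[`, "model")
    names(models) <- keys
    k_med <- median_roi_count(models)
    pp <- cluster_vhem(models, 2, k_med, config = config$vhem,
                       seed = phase_seed)
    orient_pattern_pair(pp, config$entropy_base)
  }
  pat_learn <- cluster_phase(learn_cells, seeds[4])
  pat_recog <- cluster_phase(recog_cells, seeds[5])

  # --- per participant-cell metrics --------------------------------------
  metr <- list()
  for (key in names(fits)) {
    pid <- sub("\\.[^.]*$", "", key)
    cell <- sub("^[^.]*\\.", "", key)
    pat <- if (cell %in% learn_cells) pat_learn else pat_recog
    seqs <- dataset$fixations[[pid]][[cell]]
    ab <- ab_scale(seqs, pat$pattern_a, pat$pattern_b)
    en <- fixation_entropies(fits[[key]]$model, config$entropy_base)
    is_learn <- cell %in% learn_cells
    metr[[key]] <- data.frame(
      participant_id = pid, cell = cell,
      phase = if (is_learn) "learning" else "recognition",
      learn_mask = if (is_learn) sub("learn_", "", cell)
                   else if (substr(cell, 1, 1) == "u") "unmasked" else "masked",
      recog_mask = if (is_learn) "not_applicable"
                   else if (substr(cell, 2, 2) == "u") "unmasked" else "masked",
      n_rois = fits[[key]]$n_rois_selected,
      ab_scale = ab$value, h1 = en$h1, h2_given_1 = en$h2_given_1,
      h3_given_2 = en$h3_given_2,
      assignment = unname(pat$assignments[key]))
  }
  metrics <- do.call(rbind, metr)
  rownames(metrics) <- NULL

  # --- behavioral summaries ----------------------------------------------
  resp <- dataset$responses
  perf <- do.call(rbind, lapply(split(resp, resp[c("condition",
                                                   "participant_id")]),
    function(d) {
      if (nrow(d) == 0L) return(NULL)
      old <- d[d$is_old, ]; new <- d[!d$is_old, ]
      ds <- dprime(sum(old$response), nrow(old), sum(new$response), nrow(new),
                   correction = config$dprime_correction)
      data.frame(participant_id = d$participant_id[1],
                 condition = d$condition[1],
                 dprime = ds$dprime, criterion = ds$criterion,
                 mean_correct_rt = mean(d$rt_ms[d$correct]))
    }))
  rownames(perf) <- NULL

  # --- wide tables per dependent variable --------------------------------
  wide <- function(df, value, cellcol = "condition") {
    out <- matrix(NA_real_, length(ids), 4L,
                  dimnames = list(ids, recog_cells))
    for (r in seq_len(nrow(df)))
      out[df$participant_id[r], df[[cellcol]][r]] <- df[[value]][r]
    out
  }
  rec_metrics <- metrics[metrics$phase == "recognition", ]
  dv_tables <- list(
    dprime = wide(perf, "dprime"),
    rt = wide(perf, "mean_correct_rt"),
    ab_scale = wide(rec_metrics, "ab_scale", "cell"),
    h1 = wide(rec_metrics, "h1", "cell"),
    h2_given_1 = wide(rec_metrics, "h2_given_1", "cell"),
    h3_given_2 = wide(rec_metrics, "h3_given_2", "cell"))

  # --- 2x2 ANOVAs and the three planned contrasts ------------------------
  anova_res <- list()
  contrast_res <- list()
  scenarios <- c(um = "mask at recognition", mu = "mask at learning",
                 mm = "mask at both phases")
  for (dv in names(dv_tables)) {
    tab <- dv_tables[[dv]]
    cc <- stats::complete.cases(tab)
    anova_res[[dv]] <- rm_anova_2x2(tab[cc, , drop = FALSE])
    for (sc in names(scenarios)) {
      keep <- stats::complete.cases(tab[, c("uu", sc)])
      res <- paired_contrast(tab[keep, sc], tab[keep, "uu"])
      contrast_res[[paste(dv, sc, sep = ".")]] <- data.frame(
        dv = dv, scenario = sc, contrast = scenarios[[sc]],
        n = sum(keep), t = res$statistic, df = res$df,
        p_value = res$p_value, cohens_d = res$effect_size,
        d_ci_low = res$effect_ci[1], d_ci_high = res$effect_ci[2],
        mean_diff = res$mean_diff)
    }
  }
  contrasts <- do.call(rbind, contrast_res)
  rownames(contrasts) <- NULL

  # --- strategy-change vs performance-change correlations ----------------
  covtab <- dataset$covariates
  rownames(covtab) <- covtab$participant_id
  cor_rows <- list()
  for (sc in c("um", "mu", "mm")) {
    d_imp <- dv_tables$dprime[, "uu"] - dv_tables$dprime[, sc]
    for (dv in c("ab_scale", "h1", "h2_given_1", "h3_given_2")) {
      change <- dv_tables[[dv]][, "uu"] - dv_tables[[dv]][, sc]
      keep <- stats::complete.cases(cbind(d_imp, change))
      if (sum(keep) < 8L) next
      na_cor <- list(r = NA_real_, df = NA_integer_, p_value = NA_real_)
      plain <- tryCatch(correlation(d_imp[keep], change[keep]),
                        error = function(e) na_cor)
      covs <- intersect(config$covariates, names(covtab))
      part <- if (length(covs))
        tryCatch(correlation(d_imp[keep], change[keep],
                             covtab[ids[keep], covs, drop = FALSE]),
                 error = function(e) na_cor)
      else na_cor
      cor_rows[[paste(sc, dv)]] <- data.frame(
        scenario = sc, change_measure = dv, n = sum(keep),
        r = plain$r, df = plain$df, p_value = plain$p_value,
        partial_r = part$r, partial_df = part$df %||% NA_integer_,
        partial_p = part$p_value)
    }
  }
  correlations <- do.call(rbind, cor_rows)
  rownames(correlations) <- NULL

  # --- pattern separation (recognition phase) ----------------------------
  seq_by_key <- lapply(names(pat_recog$assignments), function(key) {
    pid <- sub("\\.[^.]*$", "", key)
    cell <- sub("^[^.]*\\.", "", key)
    dataset$fixations[[pid]][[cell]]
  })
  names(seq_by_key) <- names(pat_recog$assignments)
  separation <- pattern_separation(seq_by_key, pat_recog)

  report <- structure(list(
    metrics = metrics, performance = perf, dv_tables = dv_tables,
    anova = anova_res, contrasts = contrasts, correlations = correlations,
    separation = separation,
    patterns = list(learning = pat_learn, recognition = pat_recog),
    fits = fits, exclusions = exclusions,
    n_cells_analyzed = length(fits),
    n_cells_excluded = nrow(exclusions),
    provenance = list(seed = config$seed,
                      roi_range = config$roi_range,
                      n_restarts = config$n_restarts,
                      vhem = unclass(config$vhem)[c("virtual_length",
                                                    "virtual_samples",
                                                    "n_restarts")],
                      entropy_base = config$entropy_base,
                      dprime_correction = config$dprime_correction,
                      package_version =
                        as.character(utils::packageVersion("gazehmm")))),
    class = "pipeline_report")
  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

# Assemble a dataset from the configured CSV inputs.
#' @noRd
load_dataset <- function(config) {
  seqs <- read_fixations(config$fixations_csv)
  cell_of <- function(s) {
    if (s$phase == "learning") paste0("learn_", s$learn_mask)
    else paste0(substr(s$learn_mask, 1, 1), substr(s$recog_mask, 1, 1))
  }
  fixations <- list()
  for (s in seqs) fixations[[s$participant_id]][[cell_of(s)]] <-
    c(fixations[[s$participant_id]][[cell_of(s)]], list(s))
  responses <- utils::read.csv(config$responses_csv,
                               stringsAsFactors = FALSE)
  if (is.null(responses$condition))
    responses$condition <- paste0(substr(responses$learn_mask, 1, 1),
                                  substr(responses$recog_mask, 1, 1))
  covariates <- if (!is.null(config$covariates_csv))
    utils::read.csv(config$covariates_csv, stringsAsFactors = FALSE)
  else data.frame(participant_id = unique(responses$participant_id))
  list(fixations = fixations, responses = responses, covariates = covariates)
}

#' Write the report bundle to a directory
#'
#' Tabular outputs as CSV, pattern HMMs as JSON, and a JSON summary of the
#' tests and provenance.
#'
#' @param report A `"pipeline_report"`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(report$metrics, file.path(dir, "metrics.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(report$performance, file.path(dir, "performance.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(report$contrasts, file.path(dir, "contrasts.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(report$correlations, file.path(dir, "correlations.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(report$exclusions, file.path(dir, "exclusions.csv"),
                   row.names = FALSE, quote = FALSE)
  write_clustering_report(report$separation,
                          file.path(dir, "pattern_separation.csv"))
  for (ph in names(report$patterns)) {
    write_hmm_json(report$patterns[[ph]]$pattern_a,
                   file.path(dir, paste0("pattern_A_", ph, ".json")))
    write_hmm_json(report$patterns[[ph]]$pattern_b,
                   file.path(dir, paste0("pattern_B_", ph, ".json")))
  }
  anova_flat <- lapply(report$anova, function(effects)
    lapply(effects, function(e)
      list(F = e$statistic, df = e$df, p = e$p_value,
           eta_p_sq = e$effect_size, eta_ci_90 = e$effect_ci)))
  jsonlite::write_json(list(anova = anova_flat,
                            separation = list(
                              F = report$separation$f_stat,
                              df = report$separation$df,
                              p = report$separation$p_value,
                              eta_p_sq = report$separation$effect_size),
                            provenance = report$provenance),
                       file.path(dir, "report.json"),
                       digits = NA, auto_unbox = TRUE)
  invisible(dir)
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("<pipeline_report>\n")
  cat(sprintf("  participant-cells analyzed: %d (excluded: %d)\n",
              x$n_cells_analyzed, x$n_cells_excluded))
  cat(sprintf("  recognition patterns: %d A / %d B (separation F = %.1f)\n",
              sum(x$patterns$recognition$assignments == "A"),
              sum(x$patterns$recognition$assignments == "B"),
              x$separation$f_stat))
  cat("  planned contrasts (t vs uu baseline):\n")
  for (r in seq_len(nrow(x$contrasts)))
    cat(sprintf("    %-10s %-3s t(%d) = %7.3f, p = %.4g\n",
                x$contrasts$dv[r], x$contrasts$scenario[r],
                x$contrasts$df[r], x$contrasts$t[r], x$contrasts$p_value[r]))
  invisible(x)
}

#' Gridded fixation-density summary with ROI assignments
#'
#' A 2-D histogram of fixation positions over the face box plus the decoded
#' (most probable) ROI label of every fixation, for report figures.
#'
#' @param model A `gaussian_hmm`.
#' @param seqs List of `fixseq` objects.
#' @param face_box Face width/height in pixels (the grid spans
#'   `[-w/2, w/2] x [-h/2, h/2]`; fixations outside are clamped to the
#'   border cells).
#' @param bins Number of grid cells per axis.
#' @return List of class `"heatmap_summary"`: `counts` (bins x bins matrix,
#'   summing to the total fixation count), `xbreaks`, `ybreaks`,
#'   `assignments` (list of integer ROI label vectors, one per sequence).
#' @export
make_heatmap_summary <- function(model, seqs, face_box = c(256, 256),
                                 bins = 32) {
  if (length(seqs) == 0L) stop("need at least one sequence")
  xy <- do.call(rbind, lapply(seqs, fix_xy))
  xb <- seq(-face_box[1] / 2, face_box[1] / 2, length.out = bins + 1L)
  yb <- seq(-face_box[2] / 2, face_box[2] / 2, length.out = bins + 1L)
  ix <- pmin(pmax(findInterval(xy[, 1L], xb, all.inside = TRUE), 1L), bins)
  iy <- pmin(pmax(findInterval(xy[, 2L], yb, all.inside = TRUE), 1L), bins)
  counts <- matrix(0L, bins, bins)
  for (r in seq_along(ix))
    counts[ix[r], iy[r]] <- counts[ix[r], iy[r]] + 1L
  structure(list(counts = counts, xbreaks = xb, ybreaks = yb,
                 assignments = lapply(seqs, function(s)
                   decode_rois(model, s))),
            class = "heatmap_summary")
}
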