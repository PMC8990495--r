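# Fixation-sequence container and CSV interchange.
#
# A fixation sequence is one trial's ordered fixations in a face-centered
# coordinate frame: origin at the midpoint between the two eye centers,
# x to the viewer's right, y downward, units pixels. Presentation position on
# the screen (e.g. quadrant placement) is assumed to have been subtracted
# upstream, so ROIs are anatomical rather than screen-anchored.

#' Construct a fixation sequence for a single trial
#'
#' @param participant_id,trial_id Opaque identifiers (coerced to character).
#' @param phase `"learning"` or `"recognition"`.
#' @param learn_mask Mask condition at learning: `"unmasked"` or `"masked"`.
#' @param recog_mask Mask condition at recognition: `"unmasked"`, `"masked"`,
#'   or `"not_applicable"` (required for learning-phase trials).
#' @param x,y Fixation coordinates in pixels, face-centered (origin midway
#'   between the eye centers, y increasing downward).
#' @param duration Fixation durations in milliseconds, strictly positive.
#'   Durations are carried for completeness but ignored by the HMM, whose
#'   emissions are positions only.
#'
#' @return An object of class `"fixseq"`: a list with the identifier fields
#'   and a numeric matrix `fixations` with columns `x`, `y`, `duration`.
#' @export
#' @examples
#' fx <- fixation_sequence("p1", "t1", "learning", "unmasked",
#'                         x = c(0, 10), y = c(5, -3), duration = c(200, 250))
#' nrow(fx$fixations)
fixation_sequence <- function(participant_id, trial_id, phase,
                              learn_mask, recog_mask = "not_applicable",
                              x, y, duration) {
  phase <- match.arg(phase, c("learning", "recognition"))
  learn_mask <- match.arg(learn_mask, c("unmasked", "masked"))
  recog_mask <- match.arg(recog_mask, c("unmasked", "masked", "not_applicable"))
  if (phase == "learning" && recog_mask != "not_applicable")
    stop("learning-phase sequences must have recog_mask = 'not_applicable'")
  if (phase == "recognition" && recog_mask == "not_applicable")
    stop("recognition-phase sequences need a recognition mask condition")
  n <- length(x)
  if (n == 0L) stop("fixation sequence must contain at least one fixation")
  if (length(y) != n || length(duration) != n)
    stop("x, y and duration must have equal length")
  if (!all(is.finite(x)) || !all(is.finite(y)))
    stop("fixation coordinates must be finite")
  if (!all(is.finite(duration)) || any(duration <= 0))
    stop("fixation durations must be strictly positive")
  structure(
    list(participant_id = as.character(participant_id),
         trial_id = as.character(trial_id),
         phase = phase, learn_mask = learn_mask, recog_mask = recog_mask,
         fixations = cbind(x = as.numeric(x), y = as.numeric(y),
                           duration = as.numeric(duration))),
    class = "fixseq")
}

#' @export
print.fixseq <- function(x, ...) {
  cat(sprintf("<fixseq> participant %s, trial %s (%s, learn %s / recog %s): %d fixations\n",
              x$participant_id, x$trial_id, x$phase, x$learn_mask,
              x$recog_mask, nrow(x$fixations)))
  invisible(x)
}

# Trusted fast-path constructor used by the generator (inputs already
# validated); keeps the public constructor's checks out of hot loops.
#' @noRd
new_fixseq <- function(participant_id, trial_id, phase, learn_mask,
                       recog_mask, xy, duration) {
  structure(
    list(participant_id = participant_id, trial_id = trial_id,
         phase = phase, learn_mask = learn_mask, recog_mask = recog_mask,
         fixations = cbind(x = xy[, 1L], y = xy[, 2L], duration = duration)),
    class = "fixseq")
}

# Extract the T x 2 position matrix the HMM operates on.
#' @noRd
fix_xy <- function(seq) {
  if (inherits(seq, "fixseq")) seq$fixations[, c("x", "y"), drop = FALSE]
  else if (is.matrix(seq)) seq[, 1:2, drop = FALSE]
  else stop("expected a fixseq or a numeric matrix of positions")
}

#' Read fixation sequences from CSV
#'
#' Expects the columns `participant_id, trial_id, phase, learn_mask,
#' recog_mask, fix_index, x, y, duration_ms` with `fix_index` 1-based and rows
#' sorted within trial.
#'
#' @param path CSV file path.
#' @return A list of [fixation_sequence()] objects, one per trial.
#' @export
read_fixations <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("participant_id", "trial_id", "phase", "learn_mask", "recog_mask",
            "fix_index", "x", "y", "duration_ms")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("fixation CSV is missing columns: ", paste(missing, collapse = ", "))
  key <- paste(df$participant_id, df$trial_id, sep = "\r")
  out <- lapply(split(seq_len(nrow(df)), factor(key, levels = unique(key))),
                function(idx) {
    rows <- df[idx[order(df$fix_index[idx])], ]
    fixation_sequence(rows$participant_id[1], rows$trial_id[1], rows$phase[1],
                      rows$learn_mask[1], rows$recog_mask[1],
                      x = rows$x, y = rows$y, duration = rows$duration_ms)
  })
  names(out) <- NULL
  out
}

#' Write fixation sequences to CSV
#'
#' Inverse of [read_fixations()]; writes the canonical long-format fixation
#' table.
#'
#' @param seqs List of `fixseq` objects.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_fixations <- function(seqs, path) {
  rows <- lapply(seqs, function(s) {
    n <- nrow(s$fixations)
    data.frame(participant_id = s$participant_id, trial_id = s$trial_id,
               phase = s$phase, learn_mask = s$learn_mask,
               recog_mask = s$recog_mask, fix_index = seq_len(n),
               x = s$fixations[, "x"], y = s$fixations[, "y"],
               duration_ms = s$fixations[, "duration"])
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
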