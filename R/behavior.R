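## Movement analysis: binarise a frame-difference energy series and label
## trials rest vs active around stimulus onset.

#' Binarise a frame-difference energy series
#'
#' Movement is declared on frames whose inter-frame pixel-difference energy
#' exceeds a threshold. Frame 0 has no predecessor and is defined
#' non-moving.
#'
#' @param energy non-negative numeric vector, one value per frame.
#' @param threshold energy threshold (strictly exceeded = moving).
#' @param frameRate Hz.
#' @return A [MotionTrace-class].
#' @export
motionBinary <- function(energy, threshold, frameRate = 30.98) {
  if (any(energy < 0)) validationError("energies must be non-negative")
  moving <- energy > threshold
  moving[1L] <- FALSE
  new("MotionTrace", moving = moving, frameRate = as.numeric(frameRate))
}

#' Classify trials as rest or active
#'
#' A trial is a rest trial iff no movement frame falls within the guard
#' window `[onset - g, onset + g]` (inclusive at both ends), with
#' `g = round(guardMs / 1000 * frameRate)`; all other trials are active.
#' Trials whose guard window extends outside the trial are unclassifiable
#' (`NA`).
#'
#' @param motion a [MotionTrace-class] (or logical vector) covering the
#'   whole session, trials concatenated in time order.
#' @param framesPerTrial frames per trial.
#' @param stimOnsetFrame 0-based stimulus-onset frame within each trial.
#' @param guardMs guard half-width in ms (default 400).
#' @return Factor vector (`"rest"` / `"active"`, `NA` = unclassifiable),
#'   one per trial.
#' @export
classifyTrials <- function(motion, framesPerTrial, stimOnsetFrame,
                           guardMs = 400) {
  fr <- if (is(motion, "MotionTrace")) motion@frameRate else 30.98
  moving <- if (is(motion, "MotionTrace")) motion@moving else as.logical(motion)
  if (length(moving) %% framesPerTrial != 0L)
    stop("motion trace length is not a multiple of 'framesPerTrial'")
  nT <- length(moving) %/% framesPerTrial
  g <- msToFrames(guardMs, fr)
  lab <- rep(NA_character_, nT)
  lo <- stimOnsetFrame - g
  hi <- stimOnsetFrame + g
  for (tr in seq_len(nT)) {
    if (lo < 0L || hi >= framesPerTrial) next  # guard outside trial bounds
    off <- (tr - 1L) * framesPerTrial
    lab[tr] <- if (any(moving[off + (lo:hi) + 1L])) "active" else "rest"
  }
  factor(lab, levels = c("rest", "active"))
}
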