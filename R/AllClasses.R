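#' @import methods
NULL

#' Raw per-ROI fluorescence organised as trials
#'
#' A `TrialTrace` holds one ROI's raw fluorescence for one imaging session as
#' a frames x trials matrix, together with the acquisition frame rate and the
#' stimulus-onset frame shared by all trials. Frame indices are 0-based
#' throughout the package: `stimOnsetFrame` equals the number of pre-stimulus
#' frames, and frame `f` lives in matrix row `f + 1`.
#'
#' @slot values numeric matrix, frames x trials, raw fluorescence (a.u.).
#' @slot frameRate acquisition rate in Hz.
#' @slot stimOnsetFrame 0-based index of the first stimulus frame.
#' @slot roiId character identifier of the ROI.
#' @slot brainArea `"cerebellum"` or `"s1"`; selects the dF/F recipe.
#'
#' @seealso [trialTrace()], [dffS1()], [dffCerebellar()]
#' @export
setClass("TrialTrace",
  slots = c(
    values = "matrix",
    frameRate = "numeric",
    stimOnsetFrame = "integer",
    roiId = "character",
    brainArea = "character"
  )
)

setValidity("TrialTrace", function(object) {
  msg <- character()
  if (!is.numeric(object@values) || length(dim(object@values)) != 2L)
    msg <- c(msg, "'values' must be a numeric frames x trials matrix")
  if (length(object@frameRate) != 1L || !is.finite(object@frameRate) ||
      object@frameRate <= 0)
    msg <- c(msg, "'frameRate' must be a single positive number")
  if (length(object@stimOnsetFrame) != 1L || is.na(object@stimOnsetFrame) ||
      object@stimOnsetFrame < 0L || object@stimOnsetFrame >= nrow(object@values))
    msg <- c(msg, "'stimOnsetFrame' must lie in [0, frames_per_trial)")
  if (!object@brainArea %in% c("cerebellum", "s1"))
    msg <- c(msg, "'brainArea' must be \"cerebellum\" or \"s1\"")
  if (length(msg)) msg else TRUE
})

#' Construct a TrialTrace
#'
#' @param values numeric frames x trials matrix of raw fluorescence.
#' @param frameRate acquisition rate (Hz).
#' @param stimOnsetFrame 0-based stimulus-onset frame (number of pre-stimulus
#'   frames).
#' @param roiId ROI identifier.
#' @param brainArea `"s1"` (default) or `"cerebellum"`.
#' @return A [TrialTrace-class] object.
#' @examples
#' tt <- trialTrace(matrix(100, 50, 4), frameRate = 30.98, stimOnsetFrame = 10)
#' nFrames(tt)
#' @export
trialTrace <- function(values, frameRate, stimOnsetFrame, roiId = "roi1",
                       brainArea = c("s1", "cerebellum")) {
  brainArea <- match.arg(brainArea)
  if (is.vector(values)) values <- matrix(values, ncol = 1L)
  new("TrialTrace", values = values, frameRate = as.numeric(frameRate),
      stimOnsetFrame = as.integer(stimOnsetFrame), roiId = as.character(roiId),
      brainArea = brainArea)
}

#' dF/F session for one ROI
#'
#' Output of the preprocessing recipes: the dF/F matrix plus the baseline
#' fluorescence F0, the baseline noise sigma, and the signal-to-noise ratio.
#' For the barrel-cortex (S1) recipe an ROI whose F0 falls below zero after
#' background subtraction is rejected (`rejected = TRUE`, empty `dff`).
#'
#' @slot dff numeric matrix, frames x trials (empty when rejected).
#' @slot f0 baseline fluorescence (a.u. for S1 whole-session baseline;
#'   per-trial 20th-percentile baselines are stored as a vector for the
#'   cerebellar recipe).
#' @slot sigma baseline noise in dF/F units (NA when not computed).
#' @slot snr dimensionless signal-to-noise ratio (NA when not computed).
#' @slot rejected logical; TRUE iff the ROI failed the F0 >= 0 rule.
#' @slot reason character; why the ROI was rejected ("" otherwise).
#' @slot frameRate Hz.
#' @slot stimOnsetFrame 0-based stimulus-onset frame.
#' @slot roiId ROI identifier.
#' @export
setClass("DffSession",
  slots = c(
    dff = "matrix",
    f0 = "numeric",
    sigma = "numeric",
    snr = "numeric",
    rejected = "logical",
    reason = "character",
    frameRate = "numeric",
    stimOnsetFrame = "integer",
    roiId = "character"
  )
)

setValidity("DffSession", function(object) {
  msg <- character()
  if (!is.na(object@sigma) && object@sigma < 0)
    msg <- c(msg, "'sigma' must be >= 0")
  if (!is.na(object@snr) && !is.na(object@sigma) && object@sigma > 0 &&
      object@snr < 0)
    msg <- c(msg, "'snr' must be >= 0 when sigma > 0")
  if (length(msg)) msg else TRUE
})

#' Inferred calcium events for one ROI
#'
#' Per-frame, per-trial non-negative event amplitudes from AR(1)
#' deconvolution, together with the binary raster of events that survive the
#' minimum-amplitude threshold `sMin` (3 sigma in the standard pipeline).
#'
#' @slot amplitudes numeric matrix, frames x trials, inferred event sizes
#'   (dF/F units, >= 0).
#' @slot binary logical matrix, frames x trials; TRUE iff the amplitude meets
#'   `sMin`.
#' @slot sMin minimum event amplitude used for binarisation.
#' @slot gamma AR(1) per-frame decay used by the solver.
#' @export
setClass("EventRaster",
  slots = c(
    amplitudes = "matrix",
    binary = "matrix",
    sMin = "numeric",
    gamma = "numeric"
  )
)

setValidity("EventRaster", function(object) {
  msg <- character()
  if (any(object@amplitudes < -1e-9, na.rm = TRUE))
    msg <- c(msg, "event amplitudes must be non-negative")
  if (!identical(dim(object@amplitudes), dim(object@binary)))
    msg <- c(msg, "'amplitudes' and 'binary' must share dimensions")
  if (any(object@binary & object@amplitudes < object@sMin - 1e-9))
    msg <- c(msg, "binary events must carry amplitude >= sMin")
  if (length(msg)) msg else TRUE
})

#' Per-frame event probability profile
#'
#' The proportion of trials containing at least one binary event at each
#' frame (P_event), with its mean and SD across frames and the derived
#' evoked-window threshold mean + 3 SD.
#'
#' @slot p numeric vector, one proportion in \[0, 1\] per frame.
#' @slot pMean mean of `p` across frames.
#' @slot pSd standard deviation of `p` across frames.
#' @slot threshold `pMean + 3 * pSd`.
#' @slot nTrials number of trials entering the proportions.
#' @export
setClass("PEventProfile",
  slots = c(
    p = "numeric",
    pMean = "numeric",
    pSd = "numeric",
    threshold = "numeric",
    nTrials = "integer"
  )
)

setValidity("PEventProfile", function(object) {
  msg <- character()
  if (any(object@p < 0 | object@p > 1))
    msg <- c(msg, "'p' must lie in [0, 1]")
  if (object@threshold < object@pMean - 1e-12)
    msg <- c(msg, "'threshold' must be >= mean")
  if (length(msg)) msg else TRUE
})

#' Evoked-event window
#'
#' The contiguous span of frames whose P_event exceeds mean + 3 SD, selected
#' at or after stimulus onset. Frames are 0-based and the span is half-open:
#' `[startFrame, endFrame)`.
#'
#' @slot startFrame first frame of the window (0-based).
#' @slot endFrame one past the last frame (half-open).
#' @slot durationMs window duration in ms, `(end - start) / frameRate * 1000`
#'   rounded to the nearest ms.
#' @slot frameRate Hz.
#' @export
setClass("EvokedWindow",
  slots = c(
    startFrame = "integer",
    endFrame = "integer",
    durationMs = "numeric",
    frameRate = "numeric"
  )
)

setValidity("EvokedWindow", function(object) {
  if (object@endFrame <= object@startFrame)
    "'endFrame' must exceed 'startFrame'" else TRUE
})

#' Binary movement trace
#'
#' Per-frame indicator of animal movement, sample-synchronous with the
#' imaging acquisition.
#'
#' @slot moving logical vector, TRUE on frames with movement.
#' @slot frameRate Hz.
#' @export
setClass("MotionTrace",
  slots = c(moving = "logical", frameRate = "numeric")
)

#' Intrinsic-signal activation map
#'
#' Trial-averaged summed dR/R image, its in-mask z-score map, the binary
#' activation image before and after 5x5 median filtering, and the activation
#' area in pixels and normalised by the cranial-window mask area.
#'
#' @slot drr trial-mean summed dR/R image (out-of-mask pixels zeroed).
#' @slot zmap z-score image (z over in-mask pixels; 0 outside the mask).
#' @slot binaryRaw logical image, `z < zCut` within the mask, before median
#'   filtering.
#' @slot binary logical image after 5x5 median filtering.
#' @slot mask logical cranial-window mask.
#' @slot areaPx number of TRUE pixels in `binary`.
#' @slot areaRawPx number of TRUE pixels in `binaryRaw`.
#' @slot areaNorm `areaPx / sum(mask)`.
#' @export
setClass("ActivationMap",
  slots = c(
    drr = "matrix",
    zmap = "matrix",
    binaryRaw = "matrix",
    binary = "matrix",
    mask = "matrix",
    areaPx = "integer",
    areaRawPx = "integer",
    areaNorm = "numeric"
  )
)

setValidity("ActivationMap", function(object) {
  msg <- character()
  if (any(object@binary & !object@mask))
    msg <- c(msg, "binary activation must lie inside the mask")
  if (object@areaNorm < 0 || object@areaNorm > 1)
    msg <- c(msg, "'areaNorm' must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' Outcome of the normality-gated test selection
#'
#' Records which statistical design was requested, the per-sample normality
#' and variance-equality gates, the test the decision table selected, and its
#' statistic, p value, and significance label.
#'
#' @slot design one of `"paired"`, `"unpaired"`, `"categorical"`,
#'   `"factorial"`.
#' @slot normalA,normalB logical normality verdicts (NA when not applicable).
#' @slot equalVar logical; F-ratio-test verdict (NA when not applicable).
#' @slot chosenTest name of the selected test.
#' @slot statistic test statistic.
#' @slot pValue p value.
#' @slot label significance label: `***`, `**`, `*` or `n.s.`.
#' @slot details list with the underlying htest / ANOVA table.
#' @export
setClass("TestDecision",
  slots = c(
    design = "character",
    normalA = "logical",
    normalB = "logical",
    equalVar = "logical",
    chosenTest = "character",
    statistic = "numeric",
    pValue = "numeric",
    label = "character",
    details = "list"
  )
)

#' Synthetic-session configuration
#'
#' Parameters of the forward model used by [simulateCalciumSession()]:
#' AR(1)-decaying transients driven by Poisson spontaneous events plus a
#' stimulus-locked evoked event per trial (with probability `evokedProb` and
#' uniform latency jitter), scaled multiplicatively onto a baseline with
#' additive Gaussian noise; evoked amplitudes on post-induction trials are
#' multiplied by `plasticityFactor`.
#'
#' @slot nRois,nTrialsPre,nTrialsPost,framesPerTrial counts (all >= 1).
#' @slot frameRate Hz.
#' @slot stimOnsetFrame 0-based stimulus-onset frame.
#' @slot gamma AR(1) per-frame decay, in (0, 1).
#' @slot spontRate spontaneous event rate (events/s).
#' @slot evokedProb probability of an evoked event per trial, in \[0, 1\].
#' @slot evokedLatencyMs mean evoked latency after stimulus onset (ms).
#' @slot latencyJitterMs half-width of the uniform latency jitter (ms).
#' @slot ampMean,ampSd event amplitude distribution (dF/F units).
#' @slot plasticityFactor multiplier on post-induction evoked amplitudes (> 0).
#' @slot baselineF baseline fluorescence (a.u.).
#' @slot noiseSd additive Gaussian noise SD (fluorescence units).
#' @slot seed integer seed; identical seed gives bit-identical output.
#' @seealso [synthSessionConfig()]
#' @export
setClass("SynthSessionConfig",
  slots = c(
    nRois = "integer", nTrialsPre = "integer", nTrialsPost = "integer",
    framesPerTrial = "integer", frameRate = "numeric",
    stimOnsetFrame = "integer", gamma = "numeric", spontRate = "numeric",
    evokedProb = "numeric", evokedLatencyMs = "numeric",
    latencyJitterMs = "numeric", ampMean = "numeric", ampSd = "numeric",
    plasticityFactor = "numeric", baselineF = "numeric", noiseSd = "numeric",
    seed = "integer"
  )
)

setValidity("SynthSessionConfig", function(object) {
  msg <- character()
  num <- c(frameRate = object@frameRate, gamma = object@gamma,
           spontRate = object@spontRate, evokedProb = object@evokedProb,
           evokedLatencyMs = object@evokedLatencyMs,
           latencyJitterMs = object@latencyJitterMs, ampMean = object@ampMean,
           ampSd = object@ampSd, plasticityFactor = object@plasticityFactor,
           baselineF = object@baselineF, noiseSd = object@noiseSd)
  if (any(!is.finite(num)))
    msg <- c(msg, paste0("non-finite value for: ",
                         paste(names(num)[!is.finite(num)], collapse = ", ")))
  cnt <- c(nRois = object@nRois, nTrialsPre = object@nTrialsPre,
           nTrialsPost = object@nTrialsPost,
           framesPerTrial = object@framesPerTrial)
  if (any(is.na(cnt)) || any(cnt < 1L))
    msg <- c(msg, "all counts must be >= 1")
  if (is.finite(object@gamma) && (object@gamma <= 0 || object@gamma >= 1))
    msg <- c(msg, "'gamma' must lie strictly in (0, 1)")
  if (is.finite(object@evokedProb) &&
      (object@evokedProb < 0 || object@evokedProb > 1))
    msg <- c(msg, "'evokedProb' must lie in [0, 1]")
  if (is.finite(object@plasticityFactor) && object@plasticityFactor <= 0)
    msg <- c(msg, "'plasticityFactor' must be > 0")
  if (is.na(object@stimOnsetFrame) || object@stimOnsetFrame < 0L ||
      object@stimOnsetFrame >= object@framesPerTrial)
    msg <- c(msg, "'stimOnsetFrame' must lie in [0, framesPerTrial)")
  if (length(msg)) msg else TRUE
})

## ---- show methods -----------------------------------------------------

setMethod("show", "TrialTrace", function(object) {
  cat("TrialTrace '", object@roiId, "' (", object@brainArea, "): ",
      nrow(object@values), " frames x ", ncol(object@values), " trials @ ",
      format(object@frameRate), " Hz, stimulus at frame ",
      object@stimOnsetFrame, "\n", sep = "")
})

setMethod("show", "DffSession", function(object) {
  if (object@rejected) {
    cat("DffSession '", object@roiId, "': REJECTED (", object@reason, ")\n",
        sep = "")
  } else {
    cat("DffSession '", object@roiId, "': ", nrow(object@dff), " frames x ",
        ncol(object@dff), " trials; F0 = ",
        format(object@f0[1], digits = 4),
        if (length(object@f0) > 1L) " (per trial)" else "",
        ", sigma = ", format(object@sigma, digits = 3),
        ", SNR = ", format(object@snr, digits = 3), "\n", sep = "")
  }
})

setMethod("show", "EventRaster", function(object) {
  cat("EventRaster: ", nrow(object@amplitudes), " frames x ",
      ncol(object@amplitudes), " trials; ", sum(object@binary),
      " events >= sMin = ", format(object@sMin, digits = 3),
      " (gamma = ", format(object@gamma, digits = 4), ")\n", sep = "")
})

setMethod("show", "PEventProfile", function(object) {
  cat("PEventProfile over ", length(object@p), " frames, ", object@nTrials,
      " trials; mean = ", format(object@pMean, digits = 3),
      ", threshold (mean + 3 SD) = ", format(object@threshold, digits = 3),
      "\n", sep = "")
})

setMethod("show", "EvokedWindow", function(object) {
  cat("EvokedWindow: frames [", object@startFrame, ", ", object@endFrame,
      ") = ", object@durationMs, " ms @ ", format(object@frameRate),
      " Hz\n", sep = "")
})

setMethod("show", "MotionTrace", function(object) {
  cat("MotionTrace: ", length(object@moving), " frames @ ",
      format(object@frameRate), " Hz, ", sum(object@moving),
      " moving\n", sep = "")
})

setMethod("show", "ActivationMap", function(object) {
  cat("ActivationMap: ", nrow(object@drr), " x ", ncol(object@drr),
      " px; area = ", object@areaPx, " px (",
      format(100 * object@areaNorm, digits = 3), "% of mask)\n", sep = "")
})

setMethod("show", "TestDecision", function(object) {
  cat("TestDecision [", object@design, "]: ", object@chosenTest,
      "; statistic = ", format(object@statistic, digits = 4),
      ", p = ", format(object@pValue, digits = 4), " (", object@label,
      ")\n", sep = "")
})
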