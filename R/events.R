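## Event-level analysis: spontaneous-event detection by derivative and
## prominence rules, the per-frame event probability profile P_event, the
## evoked-event window, responsive-trial selection, persistent cells, and
## EPSP amplitude/latency metrics.

## topographic prominence of peak i: walk out to the nearest higher samples
## on each side, track the minimum along each walk, prominence = height
## minus the higher of the two side minima
peakProminence <- function(x, i) {
  n <- length(x)
  leftMin <- x[i]
  j <- i - 1L
  while (j >= 1L && x[j] <= x[i]) {
    leftMin <- min(leftMin, x[j])
    j <- j - 1L
  }
  if (j < 1L) leftMin <- min(x[seq_len(i)])
  rightMin <- x[i]
  j <- i + 1L
  while (j <= n && x[j] <= x[i]) {
    rightMin <- min(rightMin, x[j])
    j <- j + 1L
  }
  if (j > n) rightMin <- min(x[i:n])
  x[i] - max(leftMin, rightMin)
}

localMaxima <- function(x) {
  n <- length(x)
  if (n < 3L) return(integer())
  which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n]) + 1L
}

#' Detect spontaneous calcium events
#'
#' Implements the derivative/prominence rules for smoothed dF/F: frames
#' where both the first and second finite differences reach `dThresh`
#' (0.04 dF/F per frame) form the candidate set F_idx; peaks with
#' topographic prominence >= `prominence` (0.1 dF/F) are kept when they lie
#' within `matchMs` (200 ms) of some F_idx frame; each event's onset is the
#' first frame, scanning backward from the peak, where the first difference
#' drops below `onsetThresh` (0.05); a 1 s window of dF/F following onset is
#' extracted (zero-padded and flagged when it overruns the trial).
#'
#' @param dff numeric vector: one trial of smoothed dF/F (cerebellar
#'   recipe).
#' @param frameRate Hz.
#' @param dThresh first/second-difference threshold (dF/F per frame).
#' @param prominence minimum peak prominence (dF/F).
#' @param matchMs maximum peak-to-F_idx distance (ms; two-sided).
#' @param onsetThresh backward-scan first-difference threshold.
#' @return A data.frame with 0-based `peakFrame`, `onsetFrame`, `truncated`,
#'   and an attached `"windows"` attribute (events x frames matrix of the
#'   1 s post-onset dF/F).
#' @export
detectSpontaneousEvents <- function(dff, frameRate, dThresh = 0.04,
                                    prominence = 0.1, matchMs = 200,
                                    onsetThresh = 0.05) {
  x <- as.numeric(dff)
  n <- length(x)
  d1 <- c(NA, diff(x))
  d2 <- c(NA, diff(d1))
  fidx <- which(d1 >= dThresh & d2 >= dThresh)  # 1-based
  peaks <- localMaxima(x)
  peaks <- peaks[vapply(peaks, function(i) peakProminence(x, i),
                        numeric(1)) >= prominence]
  tolF <- msToFrames(matchMs, frameRate)
  if (length(fidx)) {
    peaks <- peaks[vapply(peaks, function(p)
      any(abs(p - fidx) <= tolF), logical(1))]
  } else {
    peaks <- integer()
  }
  winLen <- secondsToFrames(1, frameRate)
  onset <- integer(length(peaks))
  truncated <- logical(length(peaks))
  windows <- matrix(0, length(peaks), winLen)
  for (k in seq_along(peaks)) {
    p <- peaks[k]
    o <- p
    while (o > 1L && !is.na(d1[o]) && d1[o] >= onsetThresh) o <- o - 1L
    onset[k] <- o
    span <- o:min(n, o + winLen - 1L)
    windows[k, seq_along(span)] <- x[span]
    truncated[k] <- length(span) < winLen
  }
  out <- data.frame(peakFrame = peaks - 1L, onsetFrame = onset - 1L,
                    truncated = truncated)
  attr(out, "windows") <- windows
  out
}

#' Average spontaneous-event windows within, then across, ROIs
#'
#' @param roiWindows list of events x frames matrices (one per ROI, from the
#'   `"windows"` attribute of [detectSpontaneousEvents()]); ROIs with no
#'   events are skipped.
#' @return Numeric vector: the population-average event waveform.
#' @export
spontaneousPopulationAverage <- function(roiWindows) {
  perRoi <- lapply(roiWindows, function(w) {
    if (is.null(w) || nrow(w) == 0L) NULL else colMeans(w)
  })
  perRoi <- perRoi[!vapply(perRoi, is.null, logical(1))]
  if (!length(perRoi)) stop("no ROI contributed any spontaneous event")
  colMeans(do.call(rbind, perRoi))
}

#' Per-frame event probability profile (P_event)
#'
#' For each frame, the proportion of trials containing at least one binary
#' event at that frame; the evoked-window threshold is the mean plus three
#' standard deviations of the profile across all frames of the trial-time
#' axis.
#'
#' @param raster an [EventRaster-class] (or logical frames x trials matrix)
#'   with at least two trials.
#' @return A [PEventProfile-class].
#' @export
computePEvent <- function(raster) {
  b <- if (is(raster, "EventRaster")) raster@binary else raster
  if (is.null(dim(b)) || ncol(b) < 2L)
    stop("P_event requires a raster with >= 2 trials")
  p <- rowMeans(b > 0)
  m <- mean(p)
  s <- stats::sd(p)
  new("PEventProfile", p = p, pMean = m, pSd = s, threshold = m + 3 * s,
      nTrials = ncol(b))
}

#' Evoked-event window from a P_event profile
#'
#' Among maximal runs of consecutive frames with `p` strictly above the
#' mean + 3 SD threshold, selects the longest run starting at or after the
#' stimulus-onset frame (earliest such run on ties). The window duration is
#' the frame count converted to ms and rounded (12 frames at 30.98 Hz gives
#' the canonical 387 ms window). When no supra-threshold run starts at or
#' after stimulus onset a classed error `"caplast_no_evoked_window"` is
#' raised.
#'
#' @param profile a [PEventProfile-class].
#' @param stimOnsetFrame 0-based stimulus-onset frame.
#' @param frameRate Hz.
#' @return An [EvokedWindow-class].
#' @export
evokedWindow <- function(profile, stimOnsetFrame, frameRate) {
  stopifnot(is(profile, "PEventProfile"))
  runs <- runsTrue(profile@p > profile@threshold)
  runs <- runs[runs$start >= stimOnsetFrame, , drop = FALSE]
  if (!nrow(runs))
    stop(errorCondition(
      "no evoked window: no supra-threshold run at or after stimulus onset",
      class = c("caplast_no_evoked_window", "error")))
  len <- runs$end - runs$start
  best <- runs[order(-len, runs$start)[1L], ]
  new("EvokedWindow", startFrame = as.integer(best$start),
      endFrame = as.integer(best$end),
      durationMs = framesToMs(best$end - best$start, frameRate),
      frameRate = frameRate)
}

#' Select trials with an event inside the evoked window
#'
#' Returns the indices of trials containing at least one binary event in
#' `[startFrame, endFrame)`. A neuron is "responsive" iff this set is
#' non-empty.
#'
#' @param raster an [EventRaster-class].
#' @param window an [EvokedWindow-class].
#' @return Integer vector of 1-based trial indices.
#' @export
selectEvokedTrials <- function(raster, window) {
  stopifnot(is(raster, "EventRaster"), is(window, "EvokedWindow"))
  if (window@endFrame > nrow(raster@binary))
    stop("evoked window exceeds the trial length")
  rows <- (window@startFrame + 1L):window@endFrame
  which(colSums(raster@binary[rows, , drop = FALSE]) > 0)
}

#' Persistent cells across two conditions
#'
#' Cells responsive (possessing an evoked event) in both conditions: the set
#' intersection of the two responder sets over a common ROI universe.
#'
#' @param respondersA,respondersB vectors of cell identifiers.
#' @return The intersection, in the order of `respondersA`.
#' @export
persistentCells <- function(respondersA, respondersB) {
  respondersA[respondersA %in% respondersB]
}

#' EPSP amplitude and latency
#'
#' Amplitude: maximum of the post-pulse segment minus the mean of the 20 ms
#' immediately preceding pulse onset. Latency: time from pulse onset to the
#' first sample where the baseline-subtracted potential exceeds 10% of the
#' amplitude. A non-positive amplitude leaves the latency undefined
#' (`NA`, flagged).
#'
#' @param sweep data.frame with columns `timeMs` and `mV`.
#' @param pulseOnsetMs pulse onset (ms); at least 20 ms of pre-pulse samples
#'   are required.
#' @return A list: `amplitudeMv`, `latencyMs`, `baselineMv`, `flagged`.
#' @export
epspMetrics <- function(sweep, pulseOnsetMs) {
  stopifnot(all(c("timeMs", "mV") %in% names(sweep)))
  pre <- sweep$timeMs >= pulseOnsetMs - 20 & sweep$timeMs < pulseOnsetMs
  if (!any(sweep$timeMs < pulseOnsetMs) || sum(pre) < 2L ||
      min(sweep$timeMs) > pulseOnsetMs - 20)
    stop("need >= 20 ms of pre-pulse baseline samples")
  baseline <- mean(sweep$mV[pre])
  post <- sweep$timeMs >= pulseOnsetMs
  amp <- max(sweep$mV[post]) - baseline
  if (amp <= 0)
    return(list(amplitudeMv = amp, latencyMs = NA_real_,
                baselineMv = baseline, flagged = TRUE))
  tPost <- sweep$timeMs[post]
  vPost <- sweep$mV[post] - baseline
  cross <- which(vPost > 0.1 * amp)[1L]
  list(amplitudeMv = amp, latencyMs = tPost[cross] - pulseOnsetMs,
       baselineMv = baseline, flagged = FALSE)
}
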