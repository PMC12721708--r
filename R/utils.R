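## Shared numeric helpers: percentile convention, frame/time conversion,
## run-length utilities, seeded substreams, validation conditions.

#' Midpoint-anchored percentile
#'
#' Percentile with linear interpolation between order statistics anchored at
#' probabilities (k - 0.5)/n (MATLAB's `prctile` convention;
#' `stats::quantile` type 5). This single convention is used for every
#' percentile in the package: F0 baselines (1st / 20th), the baseline-noise
#' sigma (1st percentile of sliding-window SDs), and the SNR numerator
#' (95th percentile of dF/F).
#'
#' @param x numeric vector.
#' @param p percentile in \[0, 100\].
#' @return The p-th percentile of `x`.
#' @examples
#' percentileMid(1:10, 20)
#' @export
percentileMid <- function(x, p) {
  if (!length(x)) stop("cannot take a percentile of an empty vector")
  unname(stats::quantile(x, probs = p / 100, type = 5, names = FALSE))
}

#' Frame/time conversions
#'
#' Durations are converted to frame counts by rounding to the nearest frame:
#' `round(seconds * frameRate)`. At 30.98 Hz a 5 s window is 155 frames and a
#' 12-frame span is 387 ms; at 30 Hz a 1 s baseline is 30 frames.
#'
#' @param seconds,ms durations.
#' @param n number of frames.
#' @param frameRate Hz.
#' @return An integer frame count, or a duration in ms rounded to the
#'   nearest ms.
#' @examples
#' secondsToFrames(5, 30.98)   # 155
#' framesToMs(12, 30.98)       # 387
#' @export
secondsToFrames <- function(seconds, frameRate) {
  as.integer(round(seconds * frameRate))
}

#' @rdname secondsToFrames
#' @export
msToFrames <- function(ms, frameRate) {
  as.integer(round(ms / 1000 * frameRate))
}

#' @rdname secondsToFrames
#' @export
framesToMs <- function(n, frameRate) {
  round(n / frameRate * 1000)
}

#' 0-based frames covered by a ms response window
#'
#' Frames `f` (0-based) with
#' `startMs <= (f - stimOnsetFrame) / frameRate * 1000 < endMs` (half-open).
#'
#' @param startMs,endMs window bounds relative to stimulus onset (ms).
#' @param stimOnsetFrame 0-based stimulus-onset frame.
#' @param frameRate Hz.
#' @param nFramesTotal frames per trial; frames are clipped-checked against it.
#' @return Integer vector of 0-based frame indices.
#' @export
windowFrameIndices <- function(startMs, endMs, stimOnsetFrame, frameRate,
                               nFramesTotal) {
  if (endMs <= startMs) stop("'endMs' must exceed 'startMs'")
  f <- seq.int(0L, nFramesTotal - 1L)
  rel <- (f - stimOnsetFrame) / frameRate * 1000
  idx <- f[rel >= startMs & rel < endMs]
  lastNeeded <- stimOnsetFrame + (endMs - 1e-9) / 1000 * frameRate
  if (lastNeeded >= nFramesTotal)
    stop("response window [", startMs, ", ", endMs,
         ") ms exceeds the trial length")
  idx
}

## maximal runs of TRUE in a logical vector; returns 0-based half-open spans
runsTrue <- function(x) {
  r <- rle(as.logical(x))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  keep <- r$values & !is.na(r$values)
  data.frame(start = starts[keep], end = ends[keep])
}

## derive n reproducible sub-seeds (< 2^31) from one master seed, so that
## independent noise/event/jitter streams do not perturb one another
subSeeds <- function(seed, n) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv()))
            rm(".Random.seed", envir = globalenv()))
  set.seed(as.integer(seed))
  sample.int(.Machine$integer.max, n)
}

## run code under a local seed without disturbing the caller's RNG state
withSeed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv()))
            rm(".Random.seed", envir = globalenv()))
  set.seed(as.integer(seed))
  force(code)
}

## classed validation error used across the synthetic generators
validationError <- function(...) {
  stop(errorCondition(paste0(...),
                      class = c("caplast_validation_error", "error")))
}

#' Centered boxcar smoothing with shrinking edges
#'
#' Moving-average low-pass filter with a centred window; at the series edges
#' the window shrinks to the available samples, so constant series are exact
#' fixed points everywhere.
#'
#' @param x numeric vector.
#' @param width odd window width in samples (default 5, the cerebellar
#'   recipe's smoothing window).
#' @return Smoothed numeric vector of the same length.
#' @export
boxcarSmooth <- function(x, width = 5L) {
  n <- length(x)
  if (width < 1L || width %% 2L == 0L) stop("'width' must be odd and >= 1")
  h <- (width - 1L) %/% 2L
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - h, 1L)
  hi <- pmin(seq_len(n) + h, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}
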