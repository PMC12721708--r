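## Trace preprocessing: artifact interpolation, background subtraction,
## Savitzky-Golay smoothing, the two dF/F recipes, baseline noise sigma,
## SNR, and rigid motion correction.

#' Interpolate single-frame stimulus artifacts
#'
#' Replaces each artifact frame by the linear interpolation (mean) of its two
#' neighbouring frames, per trial. Artifact frames must be interior frames.
#'
#' @param trace a [TrialTrace-class].
#' @param artifactFrames 0-based frame indices, applied to every trial; or a
#'   two-column matrix (frame, trial) of 0-based frame / 1-based trial pairs.
#' @return The corrected [TrialTrace-class].
#' @examples
#' tt <- trialTrace(matrix(c(2, 10, 4), 3, 1), 30.98, 0)
#' traceMatrix(interpolateArtifacts(tt, 1))[2, 1]  # 3
#' @export
interpolateArtifacts <- function(trace, artifactFrames) {
  stopifnot(is(trace, "TrialTrace"))
  v <- trace@values
  nF <- nrow(v)
  if (is.matrix(artifactFrames)) {
    pairs <- artifactFrames
  } else {
    if (!length(artifactFrames)) return(trace)
    pairs <- cbind(rep(as.integer(artifactFrames), each = ncol(v)),
                   rep(seq_len(ncol(v)), length(artifactFrames)))
  }
  if (any(pairs[, 1] < 1L) || any(pairs[, 1] > nF - 2L))
    stop("artifact frames must be interior (two neighbours required)")
  for (i in seq_len(nrow(pairs))) {
    f <- pairs[i, 1] + 1L  # to 1-based row
    tr <- pairs[i, 2]
    v[f, tr] <- (v[f - 1L, tr] + v[f + 1L, tr]) / 2
  }
  methods::initialize(trace, values = v)
}

#' Subtract the background fluorescence level
#'
#' Subtracts a single scalar - the 1st percentile of a background trace
#' recorded from a cell-free ROI - from every frame of every trial.
#'
#' @param trace a [TrialTrace-class].
#' @param backgroundTrace numeric vector of background fluorescence.
#' @return The background-subtracted [TrialTrace-class].
#' @export
subtractBackground <- function(trace, backgroundTrace) {
  stopifnot(is(trace, "TrialTrace"))
  if (!length(backgroundTrace)) stop("background trace must be non-empty")
  b <- percentileMid(backgroundTrace, 1)
  methods::initialize(trace, values = trace@values - b)
}

#' First-order Savitzky-Golay smoothing
#'
#' Replaces each sample by the value at its own position of the least-squares
#' line fitted over a centred window (default 51 points). In the interior
#' this equals the window mean; at the edges the window shrinks to the
#' available samples and the line is fitted over the truncated window, so
#' linear signals are fixed points everywhere.
#'
#' @param x numeric vector (length >= `window`).
#' @param window odd window length in samples (default 51).
#' @param order polynomial order; only order 1 is supported.
#' @return Smoothed numeric vector.
#' @export
savGolSmooth <- function(x, window = 51L, order = 1L) {
  if (order != 1L) stop("only first-order smoothing is supported")
  if (window %% 2L == 0L || window < 3L) stop("'window' must be odd and >= 3")
  n <- length(x)
  if (n < window) stop("series shorter than the smoothing window")
  h <- (window - 1L) %/% 2L
  out <- boxcarSmooth(x, window)  # interior: symmetric order-1 fit = mean
  for (i in c(seq_len(h), seq.int(n - h + 1L, n))) {
    lo <- max(1L, i - h)
    hi <- min(n, i + h)
    j <- lo:hi
    jc <- j - mean(j)
    beta <- sum(jc * x[j]) / sum(jc^2)
    out[i] <- mean(x[j]) + beta * (i - mean(j))
  }
  out
}

## concatenate trials into one session-long vector (time order = trial order)
sessionVector <- function(m) as.vector(m)

#' Barrel-cortex (S1) dF/F recipe
#'
#' Smooths the concatenated session trace with a 51-point first-order
#' Savitzky-Golay filter, takes the 1st percentile of the smoothed trace as
#' F0, and returns `dff = (smoothed - F0) / F0`. ROIs whose F0 is negative
#' after background subtraction are rejected (signal inversion); F0 exactly
#' zero is an error. When the session is long enough (>= the sliding-noise
#' window) the baseline noise sigma and SNR are filled in via
#' [noiseSigma()] and [sessionSnr()].
#'
#' @param trace a background-subtracted, artifact-corrected
#'   [TrialTrace-class].
#' @param window Savitzky-Golay window (frames; default 51).
#' @param noiseWindowSeconds sliding window for sigma (s; default 5).
#' @return A [DffSession-class].
#' @examples
#' tt <- trialTrace(matrix(100, 200, 2), 30.98, 20)
#' dffS1(tt)                        # constant trace: dff all zero
#' @export
dffS1 <- function(trace, window = 51L, noiseWindowSeconds = 5) {
  stopifnot(is(trace, "TrialTrace"))
  v <- trace@values
  sess <- sessionVector(v)
  sm <- savGolSmooth(sess, window = window)
  f0 <- percentileMid(sm, 1)
  if (f0 < 0) {
    return(new("DffSession", dff = matrix(numeric(0), 0, 0), f0 = f0,
               sigma = NA_real_, snr = NA_real_, rejected = TRUE,
               reason = "F0 < 0 after background subtraction",
               frameRate = trace@frameRate,
               stimOnsetFrame = trace@stimOnsetFrame, roiId = trace@roiId))
  }
  if (f0 == 0) stop("F0 is exactly zero; dF/F undefined")
  dff <- matrix((sm - f0) / f0, nrow = nrow(v), ncol = ncol(v))
  wFrames <- secondsToFrames(noiseWindowSeconds, trace@frameRate)
  sig <- if (length(sm) >= wFrames)
    noiseSigma(dff, trace@frameRate, noiseWindowSeconds) else NA_real_
  snr <- if (!is.na(sig) && sig > 0) sessionSnr(dff, sig) else NA_real_
  new("DffSession", dff = dff, f0 = f0, sigma = sig, snr = snr,
      rejected = FALSE, reason = "", frameRate = trace@frameRate,
      stimOnsetFrame = trace@stimOnsetFrame, roiId = trace@roiId)
}

#' Cerebellar dF/F recipe
#'
#' Per trial: F0 is the 20th percentile of that trial's raw trace;
#' `dff = (F - F0) / F0` is low-pass filtered with a centred five-frame
#' moving average, and the whole trial is then re-referenced by subtracting
#' the mean of the five frames immediately preceding stimulus onset, which
#' therefore averages to zero afterwards.
#'
#' @param trace a [TrialTrace-class] with `stimOnsetFrame >= 5`.
#' @param smoothFrames moving-average width (default 5).
#' @param baselineFrames pre-stimulus frames to re-reference by (default 5).
#' @return A [DffSession-class]; `f0` holds one baseline per trial.
#' @export
dffCerebellar <- function(trace, smoothFrames = 5L, baselineFrames = 5L) {
  stopifnot(is(trace, "TrialTrace"))
  on0 <- trace@stimOnsetFrame
  if (on0 < baselineFrames)
    stop("stimOnsetFrame must be >= ", baselineFrames,
         " for pre-stimulus re-referencing")
  v <- trace@values
  f0s <- numeric(ncol(v))
  dff <- v
  preRows <- (on0 - baselineFrames + 1L):on0  # 1-based rows of the 5 frames
  for (tr in seq_len(ncol(v))) {
    f0 <- percentileMid(v[, tr], 20)
    if (f0 == 0) stop("per-trial F0 is zero; dF/F undefined (trial ", tr, ")")
    f0s[tr] <- f0
    d <- (v[, tr] - f0) / f0
    d <- boxcarSmooth(d, smoothFrames)
    dff[, tr] <- d - mean(d[preRows])
  }
  new("DffSession", dff = dff, f0 = f0s, sigma = NA_real_, snr = NA_real_,
      rejected = FALSE, reason = "", frameRate = trace@frameRate,
      stimOnsetFrame = on0, roiId = trace@roiId)
}

#' Baseline noise sigma from sliding-window SDs
#'
#' Computes the sample SD of dF/F in every 5 s sliding window (stride one
#' frame; 155 frames at 30.98 Hz) across the concatenated session and takes
#' the 1st percentile of the compiled SDs as sigma.
#'
#' @param dff a [DffSession-class], or a numeric matrix/vector of dF/F.
#' @param frameRate Hz (taken from the session when available).
#' @param windowSeconds sliding-window length (s; default 5).
#' @return sigma, in dF/F units.
#' @export
noiseSigma <- function(dff, frameRate = NULL, windowSeconds = 5) {
  if (is(dff, "DffSession")) {
    frameRate <- dff@frameRate
    dff <- dff@dff
  }
  if (is.null(frameRate)) stop("'frameRate' is required")
  x <- sessionVector(as.matrix(dff))
  w <- secondsToFrames(windowSeconds, frameRate)
  n <- length(x)
  if (n < w) stop("session shorter than the ", windowSeconds, " s window")
  sds <- rollingSd(x, w)
  percentileMid(sds, 1)
}

## sample SD over every length-w window, stride 1; centred cumsums for
## numerical stability at dF/F scale
rollingSd <- function(x, w) {
  x <- x - mean(x)
  cs <- cumsum(c(0, x))
  cs2 <- cumsum(c(0, x^2))
  i <- seq_len(length(x) - w + 1L)
  s <- cs[i + w] - cs[i]
  s2 <- cs2[i + w] - cs2[i]
  v <- (s2 - s^2 / w) / (w - 1L)
  sqrt(pmax(v, 0))
}

#' Session signal-to-noise ratio
#'
#' SNR = 95th percentile of all dF/F samples across trials divided by the
#' baseline noise sigma.
#'
#' @param dff a [DffSession-class] or numeric matrix/vector of dF/F.
#' @param sigma baseline noise (from [noiseSigma()]); must be > 0.
#' @return Dimensionless SNR.
#' @export
sessionSnr <- function(dff, sigma) {
  if (is(dff, "DffSession")) dff <- dff@dff
  if (is.na(sigma) || sigma <= 0) stop("SNR undefined: sigma must be > 0")
  percentileMid(as.vector(dff), 95) / sigma
}

#' Rigid motion correction by whole-frame cross-correlation
#'
#' Estimates, for every frame, the integer (dy, dx) shift maximising the
#' normalised whole-frame cross-correlation with a reference image (the
#' stack mean by default) over a square search radius, breaking ties toward
#' the smaller shift, and translates the frame by the negative of that
#' estimate (vacated pixels are filled with the frame mean).
#'
#' @param stack numeric array height x width x frames.
#' @param reference reference image (default: pixelwise mean of the stack).
#' @param searchRadius maximum absolute shift in pixels (default 5).
#' @return A list with `stack` (corrected array) and `shifts` (frames x 2
#'   integer matrix, columns dy, dx).
#' @export
motionCorrectRigid <- function(stack, reference = NULL, searchRadius = 5L) {
  if (length(dim(stack)) != 3L || dim(stack)[3] < 1L)
    stop("'stack' must be a non-empty height x width x frames array")
  h <- dim(stack)[1]; w <- dim(stack)[2]; nF <- dim(stack)[3]
  if (is.null(reference)) reference <- apply(stack, c(1, 2), mean)
  r <- as.integer(searchRadius)
  cand <- expand.grid(dy = -r:r, dx = -r:r)
  cand <- cand[order(abs(cand$dy) + abs(cand$dx), abs(cand$dy)), ]
  shifts <- matrix(0L, nF, 2L, dimnames = list(NULL, c("dy", "dx")))
  out <- stack
  for (f in seq_len(nF)) {
    img <- stack[, , f]
    best <- -Inf
    bdy <- 0L; bdx <- 0L
    for (k in seq_len(nrow(cand))) {
      dy <- cand$dy[k]; dx <- cand$dx[k]
      ry <- max(1, 1 + dy):min(h, h + dy)
      rx <- max(1, 1 + dx):min(w, w + dx)
      a <- img[ry, rx]
      b <- reference[ry - dy, rx - dx]
      cc <- suppressWarnings(stats::cor(as.vector(a), as.vector(b)))
      if (is.na(cc)) cc <- -Inf
      if (cc > best + 1e-12) {  # strictly better; ties keep smaller shift
        best <- cc; bdy <- dy; bdx <- dx
      }
    }
    shifts[f, ] <- c(bdy, bdx)
    out[, , f] <- translateFrame(img, -bdy, -bdx)
  }
  list(stack = out, shifts = shifts)
}

translateFrame <- function(img, dy, dx) {
  h <- nrow(img); w <- ncol(img)
  out <- matrix(mean(img), h, w)
  ys <- max(1, 1 + dy):min(h, h + dy)
  xs <- max(1, 1 + dx):min(w, w + dx)
  out[ys, xs] <- img[ys - dy, xs - dx]
  out
}
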