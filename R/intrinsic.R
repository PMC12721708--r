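## Intrinsic-signal activation mapping: Gaussian smoothing + 4x block
## downsampling, per-trial summed dR/R images, and the z-thresholded,
## median-filtered activation map with mask-normalised area.

## separable Gaussian blur; truncated kernel renormalised at the edges so
## constant images are exact fixed points
gaussianBlur <- function(img, sigma = 1) {
  if (sigma <= 0) return(img)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-(-r:r)^2 / (2 * sigma^2))
  blur1d <- function(v) {
    n <- length(v)
    num <- stats::filter(c(rep(0, r), v, rep(0, r)), k, sides = 2)
    den <- stats::filter(c(rep(0, r), rep(1, n), rep(0, r)), k, sides = 2)
    (num / den)[(r + 1L):(r + n)]
  }
  tmp <- apply(img, 2L, blur1d)
  t(apply(tmp, 1L, blur1d))
}

## factor x factor block mean; trailing rows/cols that do not fill a block
## are dropped
blockDownsample <- function(img, factor = 4L) {
  h <- (nrow(img) %/% factor) * factor
  w <- (ncol(img) %/% factor) * factor
  img <- img[seq_len(h), seq_len(w), drop = FALSE]
  a <- array(img, dim = c(factor, h %/% factor, factor, w %/% factor))
  apply(a, c(2, 4), mean)
}

#' Spatially preprocess a reflectance stack
#'
#' Smooths every frame with a Gaussian filter (default sigma 1 px) and
#' downsamples it by a factor of four using block means. A cranial-window
#' mask, when supplied, is downsampled by majority vote.
#'
#' @param stack array height x width x frames x trials (or h x w x frames).
#' @param sigma Gaussian SD in pixels.
#' @param factor downsampling factor (default 4).
#' @param mask optional logical mask at full resolution.
#' @return A list with `stack` (downsampled array) and `mask` (downsampled
#'   mask or NULL).
#' @export
preprocessStack <- function(stack, sigma = 1, factor = 4L, mask = NULL) {
  d <- dim(stack)
  if (d[1] < 8L || d[2] < 8L) stop("images must be at least 8 x 8 pixels")
  oneFrame <- function(img) blockDownsample(gaussianBlur(img, sigma), factor)
  if (length(d) == 3L) {
    frames <- lapply(seq_len(d[3]), function(f) oneFrame(stack[, , f]))
    out <- array(unlist(frames), dim = c(dim(frames[[1]]), d[3]))
  } else {
    frames <- lapply(seq_len(d[4]), function(tr)
      lapply(seq_len(d[3]), function(f) oneFrame(stack[, , f, tr])))
    dd <- dim(frames[[1]][[1]])
    out <- array(unlist(frames), dim = c(dd, d[3], d[4]))
  }
  dmask <- if (!is.null(mask))
    blockDownsample(mask * 1, factor) >= 0.5 else NULL
  list(stack = out, mask = dmask)
}

#' Summed stimulus-evoked dR/R image for one trial
#'
#' The baseline image R0 is the average over the 1 s (30 frames at 30 Hz)
#' preceding stimulus onset. Post-stimulus frames are averaged in three
#' 200 ms bins spanning 400-1000 ms after onset; each bin becomes
#' `(bin - R0) / R0` and the three dR/R images are summed into a single
#' stimulus-evoked image.
#'
#' @param stack array height x width x frames x trials.
#' @param trial 1-based trial index.
#' @param stimOnsetFrame 0-based stimulus-onset frame.
#' @param frameRate Hz (default 30).
#' @param mask optional logical mask; R0 must be positive inside it.
#' @param baselineSeconds baseline span (s; default 1).
#' @param startMs,binMs,nBins post-stimulus binning (defaults 400, 200, 3).
#' @return Numeric matrix: the summed dR/R image.
#' @export
drrTrial <- function(stack, trial, stimOnsetFrame, frameRate = 30,
                     mask = NULL, baselineSeconds = 1, startMs = 400,
                     binMs = 200, nBins = 3L) {
  nF <- dim(stack)[3]
  bFrames <- secondsToFrames(baselineSeconds, frameRate)
  if (stimOnsetFrame < bFrames)
    stop("need >= ", bFrames, " pre-stimulus frames for R0")
  baseRows <- (stimOnsetFrame - bFrames + 1L):stimOnsetFrame  # 1-based
  r0 <- apply(stack[, , baseRows, trial, drop = FALSE], c(1, 2), mean)
  inMask <- if (is.null(mask)) TRUE else mask
  if (any(r0[inMask] <= 0))
    stop("R0 must be positive inside the mask")
  binFrames <- msToFrames(binMs, frameRate)
  startFrame <- stimOnsetFrame + msToFrames(startMs, frameRate)
  total <- matrix(0, nrow(r0), ncol(r0))
  for (b in seq_len(nBins)) {
    rows <- startFrame + (b - 1L) * binFrames + seq_len(binFrames)  # 1-based
    if (max(rows) > nF) stop("post-stimulus bins exceed the trial length")
    bin <- apply(stack[, , rows, trial, drop = FALSE], c(1, 2), mean)
    total <- total + (bin - r0) / r0
  }
  total
}

## majority-vote median filter for binary images; the neighbourhood is
## truncated at the image border (median over the valid window)
binaryMedianFilter <- function(b, size = 5L) {
  h <- nrow(b); w <- ncol(b)
  r <- (size - 1L) %/% 2L
  ones <- matrix(0, h, w)
  cnt <- matrix(0, h, w)
  for (dy in -r:r) {
    ys <- max(1, 1 + dy):min(h, h + dy)
    for (dx in -r:r) {
      xs <- max(1, 1 + dx):min(w, w + dx)
      ones[ys, xs] <- ones[ys, xs] + b[ys - dy, xs - dx]
      cnt[ys, xs] <- cnt[ys, xs] + 1
    }
  }
  ones > cnt / 2
}

#' Activation map from per-trial dR/R images
#'
#' Averages the summed dR/R images over trials (>= `minTrials`), zeroes
#' pixels outside the cranial-window mask, z-scores the image over in-mask
#' pixels, thresholds at `z < zCut` (activated cortex darkens: reflectance
#' decreases), cleans speckle with a `medianSize` x `medianSize` median
#' filter, and reports the activated pixel count and its mask-normalised
#' fraction.
#'
#' @param trialImages array height x width x trials of summed dR/R images
#'   (from [drrTrial()]), or a list of matrices.
#' @param mask logical cranial-window mask (non-empty).
#' @param minTrials minimum trial count (default 30).
#' @param zCut z-score threshold (default -1.5).
#' @param medianSize median-filter neighbourhood (default 5).
#' @return An [ActivationMap-class].
#' @export
activationMap <- function(trialImages, mask, minTrials = 30L, zCut = -1.5,
                          medianSize = 5L) {
  if (is.list(trialImages))
    trialImages <- array(unlist(trialImages),
                         dim = c(dim(trialImages[[1]]), length(trialImages)))
  if (!any(mask)) stop("mask is empty")
  nT <- dim(trialImages)[3]
  if (nT < minTrials)
    stop("need at least ", minTrials, " trials (got ", nT, ")")
  drr <- apply(trialImages, c(1, 2), mean)
  drr[!mask] <- 0
  mu <- mean(drr[mask])
  sd_ <- stats::sd(drr[mask])
  if (sd_ == 0) stop("degenerate z-map: zero variance inside the mask")
  z <- matrix(0, nrow(drr), ncol(drr))
  z[mask] <- (drr[mask] - mu) / sd_
  binRaw <- z < zCut & mask
  bin <- binaryMedianFilter(binRaw, medianSize) & mask
  new("ActivationMap", drr = drr, zmap = z, binaryRaw = binRaw, binary = bin,
      mask = mask, areaPx = as.integer(sum(bin)),
      areaRawPx = as.integer(sum(binRaw)),
      areaNorm = sum(bin) / sum(mask))
}
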