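## AR(1) sparse non-negative deconvolution (OASIS-style pool adjacent
## violators) with a minimum-amplitude event threshold, plus an exact
## non-negative least-squares oracle for validation.

#' Estimate the AR(1) decay coefficient
#'
#' Either from a supplied indicator decay time constant,
#' `gamma = exp(-1 / (tauSeconds * frameRate))`, or from the data via the
#' lag-2 / lag-1 autocovariance ratio of the dF/F trace (for an AR(1)
#' transient process the ratio of consecutive autocovariances equals gamma).
#' Estimates are clipped to (0.5, 0.999) with a warning: values at the
#' bounds indicate the trace carries too little transient structure.
#'
#' @param dff numeric vector of dF/F (>= 100 frames) or a
#'   [DffSession-class].
#' @param frameRate Hz.
#' @param tauSeconds optional indicator decay time constant (s); when given,
#'   the closed form is used and `dff` may be missing.
#' @return gamma in (0.5, 0.999).
#' @examples
#' estimateGamma(frameRate = 30.98, tauSeconds = 0.4)  # ~0.9225
#' @export
estimateGamma <- function(dff = NULL, frameRate, tauSeconds = NULL) {
  if (!is.null(tauSeconds))
    return(min(max(exp(-1 / (tauSeconds * frameRate)), 0.5 + 1e-6), 0.999))
  if (is(dff, "DffSession")) dff <- as.vector(dff@dff)
  dff <- as.vector(dff)
  if (length(dff) < 100L) stop("need >= 100 frames to estimate gamma")
  ac <- stats::acf(dff, lag.max = 2, plot = FALSE, demean = TRUE)$acf
  g <- ac[3] / ac[2]
  if (!is.finite(g))
    stop("gamma estimate is non-finite; supply 'tauSeconds' instead")
  if (g <= 0.5 || g >= 0.999) {
    warning("gamma estimate ", format(g, digits = 4),
            " outside (0.5, 0.999); clipped")
    g <- min(max(g, 0.5 + 1e-6), 0.999)
  }
  g
}

## Thresholded OASIS for one trial: minimise ||c - y||^2 subject to
## s[t] = c[t] - gamma*c[t-1] being 0 or >= sMin, via greedy pool merging.
## Pools carry (v, w, t, l): running weighted sum, weight, start, length.
oasisCore <- function(y, gamma, sMin) {
  n <- length(y)
  v <- numeric(n); w <- numeric(n); tt <- integer(n); l <- integer(n)
  np <- 0L
  for (i in seq_len(n)) {
    np <- np + 1L
    v[np] <- y[i]; w[np] <- 1; tt[np] <- i; l[np] <- 1L
    while (np > 1L &&
           v[np] / w[np] < gamma^l[np - 1L] * v[np - 1L] / w[np - 1L] + sMin) {
      g <- gamma^l[np - 1L]
      v[np - 1L] <- v[np - 1L] + g * v[np]
      w[np - 1L] <- w[np - 1L] + g^2 * w[np]
      l[np - 1L] <- l[np - 1L] + l[np]
      np <- np - 1L
    }
  }
  c_ <- numeric(n)
  for (p in seq_len(np)) {
    hgt <- max(v[p] / w[p], 0)
    k <- seq_len(l[p]) - 1L
    c_[tt[p] + k] <- hgt * gamma^k
  }
  s <- c_ - gamma * c(0, c_[-n])
  s[s < 1e-12] <- 0
  list(c = c_, s = s)
}

#' Thresholded AR(1) deconvolution (OASIS-style)
#'
#' Solves, per trial, for the sparsest non-negative impulse train `s` with
#' `c[t] = gamma * c[t-1] + s[t]` approximating the dF/F trace in least
#' squares, using pool-adjacent-violators segment merging with the event
#' constraint that every emitted impulse has amplitude at least `sMin`
#' (3 sigma in the standard pipeline); sub-threshold impulses are merged
#' back into their preceding segment rather than emitted. The binary raster
#' marks the surviving events.
#'
#' @param dff a [DffSession-class] or a numeric frames x trials matrix /
#'   vector of dF/F.
#' @param gamma AR(1) decay per frame, in (0, 1).
#' @param sMin minimum event amplitude (dF/F units; typically
#'   `3 * noiseSigma(...)`). Default 0 disables thresholding.
#' @param censorFinalFrame logical; when TRUE (default) an impulse placed on
#'   the last frame of a trial is never binarised as an event: with no
#'   subsequent frame, the AR(1) decay that distinguishes a transient from a
#'   terminal noise spike is unobservable, so such detections are
#'   unfalsifiable. The inferred amplitude is still reported.
#' @return An [EventRaster-class].
#' @examples
#' y <- as.numeric(stats::filter(c(0, 0, 1, 0, 0, 0), 0.9, "recursive"))
#' eventAmplitudes(oasisAR1(y, 0.9))[3]  # recovers the impulse of 1 at frame 2
#' @export
oasisAR1 <- function(dff, gamma, sMin = 0, censorFinalFrame = TRUE) {
  if (is(dff, "DffSession")) dff <- dff@dff
  if (is.vector(dff)) dff <- matrix(dff, ncol = 1L)
  if (!is.finite(gamma) || gamma <= 0 || gamma >= 1)
    stop("'gamma' must lie strictly in (0, 1)")
  if (!is.finite(sMin) || sMin < 0) stop("'sMin' must be finite and >= 0")
  if (any(!is.finite(dff))) stop("dF/F must be finite")
  amps <- matrix(0, nrow(dff), ncol(dff))
  for (tr in seq_len(ncol(dff)))
    amps[, tr] <- oasisCore(dff[, tr], gamma, sMin)$s
  tol <- 1e-9
  bin <- if (sMin > 0) amps >= sMin - tol else amps > tol
  if (censorFinalFrame && nrow(bin) > 1L) bin[nrow(bin), ] <- FALSE
  new("EventRaster", amplitudes = amps, binary = bin,
      sMin = as.numeric(sMin), gamma = as.numeric(gamma))
}

#' Exact non-negative least-squares deconvolution oracle
#'
#' Solves `min ||G s - y||^2, s >= 0` where `G` is the explicit
#' lower-triangular AR(1) impulse-response design matrix
#' (`G[i, j] = gamma^(i-j)` for `i >= j`). O(T^2) memory; a validation
#' oracle for [oasisAR1()], capped at 500 frames.
#'
#' @param y numeric dF/F vector for one trial (length <= 500).
#' @param gamma AR(1) decay per frame.
#' @return Numeric vector of non-negative event amplitudes.
#' @export
deconvMatrixOracle <- function(y, gamma) {
  n <- length(y)
  if (n > 500L) stop("oracle capped at 500 frames (O(T^2) memory)")
  if (!is.finite(gamma) || gamma <= 0 || gamma >= 1)
    stop("'gamma' must lie strictly in (0, 1)")
  i <- matrix(seq_len(n), n, n)
  expo <- i - t(i)
  G <- ifelse(expo >= 0, gamma^expo, 0)
  as.vector(pracma::lsqnonneg(G, y)$x)
}

#' Reconstruct dF/F from an event raster
#'
#' Convolves inferred impulses with the AR(1) kernel:
#' `c[t] = gamma * c[t-1] + s[t]`.
#'
#' @param raster an [EventRaster-class] (or numeric impulse matrix/vector).
#' @param gamma AR(1) decay (taken from the raster when available).
#' @return Numeric matrix of reconstructed traces.
#' @export
reconstructFromEvents <- function(raster, gamma = NULL) {
  if (is(raster, "EventRaster")) {
    gamma <- raster@gamma
    raster <- raster@amplitudes
  }
  if (is.vector(raster)) raster <- matrix(raster, ncol = 1L)
  if (is.null(gamma)) stop("'gamma' is required")
  apply(raster, 2L, function(s)
    as.numeric(stats::filter(s, gamma, method = "recursive")))
}
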