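## Ground-truthed synthetic data: calcium sessions, movement traces,
## reflectance stacks and EPSP sweeps. The forward models implement exactly
## the structure the analysis assumes, so every downstream stage can be
## tested against known truth.

#' Build a synthetic-session configuration
#'
#' Defaults describe the acquisition the pipeline targets: 20 s trials at
#' 30.98 Hz with one stimulus per trial after a 5 s baseline,
#' GCaMP6f-like AR(1) decay (indicator time constant about 400 ms), sparse
#' spontaneous activity, and a stimulus-locked evoked event with jittered
#' latency. See [SynthSessionConfig-class] for slot meanings.
#'
#' @param nRois,nTrialsPre,nTrialsPost,framesPerTrial counts.
#' @param frameRate Hz.
#' @param stimOnsetFrame 0-based stimulus-onset frame.
#' @param gamma AR(1) decay per frame, in (0, 1).
#' @param spontRate spontaneous event rate (events/s).
#' @param evokedProb per-trial probability of an evoked event.
#' @param evokedLatencyMs mean evoked latency (ms after stimulus onset).
#' @param latencyJitterMs uniform jitter half-width (ms).
#' @param ampMean,ampSd event amplitude mean/SD (dF/F units).
#' @param plasticityFactor multiplier on post-induction evoked amplitudes.
#' @param baselineF baseline fluorescence (a.u.).
#' @param noiseSd additive Gaussian noise SD (fluorescence units).
#' @param seed integer master seed.
#' @return A validated [SynthSessionConfig-class].
#' @examples
#' cfg <- synthSessionConfig(nRois = 2, nTrialsPre = 5, nTrialsPost = 5,
#'                           framesPerTrial = 200, seed = 7)
#' @export
synthSessionConfig <- function(nRois = 10L, nTrialsPre = 30L,
                               nTrialsPost = 30L, framesPerTrial = 620L,
                               frameRate = 30.98, stimOnsetFrame = 155L,
                               gamma = exp(-1 / (0.4 * 30.98)),
                               spontRate = 0.1, evokedProb = 0.6,
                               evokedLatencyMs = 50, latencyJitterMs = 30,
                               ampMean = 0.5, ampSd = 0.1,
                               plasticityFactor = 1, baselineF = 100,
                               noiseSd = 2, seed = 1L) {
  nums <- c(frameRate, gamma, spontRate, evokedProb, evokedLatencyMs,
            latencyJitterMs, ampMean, ampSd, plasticityFactor, baselineF,
            noiseSd)
  if (any(!is.finite(nums)))
    validationError("synthSessionConfig: all numeric parameters must be finite")
  obj <- try(new("SynthSessionConfig",
    nRois = as.integer(nRois), nTrialsPre = as.integer(nTrialsPre),
    nTrialsPost = as.integer(nTrialsPost),
    framesPerTrial = as.integer(framesPerTrial),
    frameRate = as.numeric(frameRate),
    stimOnsetFrame = as.integer(stimOnsetFrame), gamma = as.numeric(gamma),
    spontRate = as.numeric(spontRate), evokedProb = as.numeric(evokedProb),
    evokedLatencyMs = as.numeric(evokedLatencyMs),
    latencyJitterMs = as.numeric(latencyJitterMs),
    ampMean = as.numeric(ampMean), ampSd = as.numeric(ampSd),
    plasticityFactor = as.numeric(plasticityFactor),
    baselineF = as.numeric(baselineF), noiseSd = as.numeric(noiseSd),
    seed = as.integer(seed)), silent = TRUE)
  if (inherits(obj, "try-error"))
    validationError("synthSessionConfig: ", attr(obj, "condition")$message)
  maxLat <- stimOnsetFrame +
    msToFrames(evokedLatencyMs + latencyJitterMs, frameRate)
  if (maxLat >= framesPerTrial)
    validationError("evoked latency + jitter exceeds the trial length")
  obj
}

#' Simulate a calcium-imaging session with ground truth
#'
#' Forward model per ROI and trial: events place non-negative impulses
#' `s[t]`; the latent transient follows `c[t] = gamma * c[t-1] + s[t]`; the
#' recorded fluorescence is `F[t] = baselineF * (1 + c[t]) + eps[t]` with
#' `eps ~ N(0, noiseSd^2)`. Spontaneous impulse counts are Poisson per frame
#' at rate `spontRate / frameRate`; with probability `evokedProb` one evoked
#' impulse is inserted at the stimulus-onset frame plus a jittered latency
#' (uniform on +/- `latencyJitterMs`, rounded to the nearest frame).
#' Evoked amplitudes on post-induction trials are multiplied by
#' `plasticityFactor`. The master seed feeds independent substreams for
#' spontaneous events, evoked occurrence, jitter, amplitudes and noise, so
#' changing the noise level never moves an event.
#'
#' @param config a [SynthSessionConfig-class] from [synthSessionConfig()].
#' @return A list with `traces` (list of [TrialTrace-class], one per ROI;
#'   trial columns 1..nTrialsPre are pre-induction), `truth` (list:
#'   `events` data.frame with roi/trial/frame/amplitude/evoked,
#'   `evokedFlags` nTrials x nRois logical matrix, `plasticityFactor`,
#'   `preTrials`/`postTrials` index vectors) and `config`.
#' @examples
#' sim <- simulateCalciumSession(synthSessionConfig(nRois = 1,
#'   nTrialsPre = 3, nTrialsPost = 3, framesPerTrial = 150, seed = 2))
#' head(sim$truth$events)
#' @export
simulateCalciumSession <- function(config) {
  stopifnot(is(config, "SynthSessionConfig"))
  validObject(config)
  nT <- config@nTrialsPre + config@nTrialsPost
  nF <- config@framesPerTrial
  nR <- config@nRois
  seeds <- subSeeds(config@seed, 5L)

  lambda <- config@spontRate / config@frameRate
  spontCounts <- withSeed(seeds[1],
    array(stats::rpois(nF * nT * nR, lambda), dim = c(nF, nT, nR)))
  evokedFlags <- withSeed(seeds[2],
    matrix(stats::runif(nT * nR) < config@evokedProb, nrow = nT, ncol = nR))
  jitterMs <- withSeed(seeds[3],
    matrix(stats::runif(nT * nR, -config@latencyJitterMs,
                        config@latencyJitterMs), nrow = nT, ncol = nR))
  nSpont <- sum(spontCounts)
  amps <- withSeed(seeds[4], {
    list(spont = pmax(stats::rnorm(nSpont, config@ampMean, config@ampSd), 0),
         evoked = pmax(matrix(stats::rnorm(nT * nR, config@ampMean,
                                           config@ampSd), nT, nR), 0))
  })
  noise <- withSeed(seeds[5],
    array(stats::rnorm(nF * nT * nR, 0, config@noiseSd), dim = c(nF, nT, nR)))

  postTrials <- if (config@nTrialsPost > 0L)
    seq.int(config@nTrialsPre + 1L, nT) else integer()
  traces <- vector("list", nR)
  evRoi <- vector("list", nR)
  spontIdx <- 0L
  for (r in seq_len(nR)) {
    s <- matrix(0, nF, nT)
    recs <- list()
    for (tr in seq_len(nT)) {
      cnt <- spontCounts[, tr, r]
      kTot <- sum(cnt)
      if (kTot > 0L) {
        frames0 <- rep.int(seq_len(nF) - 1L, cnt)
        a <- amps$spont[spontIdx + seq_len(kTot)]
        spontIdx <- spontIdx + kTot
        for (k in seq_len(kTot)) s[frames0[k] + 1L, tr] <-
          s[frames0[k] + 1L, tr] + a[k]
        recs[[length(recs) + 1L]] <- data.frame(
          trial = tr, frame = frames0, amplitude = a, evoked = FALSE)
      }
      if (evokedFlags[tr, r]) {
        lat <- config@evokedLatencyMs + jitterMs[tr, r]
        f0 <- config@stimOnsetFrame + msToFrames(lat, config@frameRate)
        a <- amps$evoked[tr, r]
        if (tr %in% postTrials) a <- a * config@plasticityFactor
        s[f0 + 1L, tr] <- s[f0 + 1L, tr] + a
        recs[[length(recs) + 1L]] <- data.frame(
          trial = tr, frame = f0, amplitude = a, evoked = TRUE)
      }
    }
    cMat <- apply(s, 2L, function(col)
      as.numeric(stats::filter(col, config@gamma, method = "recursive")))
    fMat <- config@baselineF * (1 + cMat) + noise[, , r]
    traces[[r]] <- trialTrace(fMat, config@frameRate, config@stimOnsetFrame,
                              roiId = sprintf("roi%03d", r), brainArea = "s1")
    ev <- if (length(recs)) do.call(rbind, recs) else
      data.frame(trial = integer(), frame = integer(),
                 amplitude = numeric(), evoked = logical())
    if (nrow(ev)) ev <- ev[order(ev$trial, ev$frame), , drop = FALSE]
    evRoi[[r]] <- data.frame(roi = rep(r, nrow(ev)), ev)
  }
  events <- do.call(rbind, evRoi)
  rownames(events) <- NULL
  list(traces = traces,
       truth = list(events = events, evokedFlags = evokedFlags,
                    plasticityFactor = config@plasticityFactor,
                    preTrials = seq_len(config@nTrialsPre),
                    postTrials = postTrials),
       config = config)
}

#' Binary movement trace from movement bouts
#'
#' Builds a per-frame binary movement trace that is 1 exactly on the frames
#' covered by the supplied bouts. Bouts are 0-based, half-open
#' `[start, end)` spans and must be non-overlapping.
#'
#' @param nFrames total number of frames.
#' @param bouts two-column matrix (start, end), 0-based half-open; may have
#'   zero rows.
#' @param frameRate Hz (metadata on the returned trace).
#' @return A [MotionTrace-class].
#' @examples
#' simulateMotionTrace(100, rbind(c(10, 20)))
#' @export
simulateMotionTrace <- function(nFrames, bouts = matrix(integer(), ncol = 2),
                                frameRate = 30.98) {
  bouts <- matrix(as.integer(bouts), ncol = 2L)
  if (nrow(bouts)) {
    if (any(bouts[, 1] < 0L) || any(bouts[, 2] > nFrames) ||
        any(bouts[, 2] <= bouts[, 1]))
      validationError("bouts must be non-empty spans within [0, nFrames)")
    o <- order(bouts[, 1])
    bouts <- bouts[o, , drop = FALSE]
    if (nrow(bouts) > 1L &&
        any(bouts[-1L, 1] < bouts[-nrow(bouts), 2]))
      validationError("movement bouts must not overlap")
  }
  moving <- logical(nFrames)
  for (i in seq_len(nrow(bouts)))
    moving[(bouts[i, 1] + 1L):bouts[i, 2]] <- TRUE
  new("MotionTrace", moving = moving, frameRate = as.numeric(frameRate))
}

#' Sample random non-overlapping movement bouts
#'
#' @param nFrames total number of frames.
#' @param nBouts number of bouts to attempt (overlapping candidates are
#'   dropped).
#' @param lenRange inclusive range of bout lengths in frames.
#' @param seed integer seed.
#' @return Two-column integer matrix (start, end), 0-based half-open,
#'   sorted and non-overlapping.
#' @export
simulateMovementBouts <- function(nFrames, nBouts = 5L, lenRange = c(5L, 30L),
                                  seed = 1L) {
  withSeed(seed, {
    lens <- sample(seq.int(lenRange[1], lenRange[2]), nBouts, replace = TRUE)
    starts <- sample.int(max(nFrames - max(lens), 1L), nBouts) - 1L
    b <- cbind(starts, starts + lens)
    b <- b[order(b[, 1]), , drop = FALSE]
    keep <- rep(TRUE, nrow(b))
    lastEnd <- -1L
    for (i in seq_len(nrow(b))) {
      if (b[i, 1] <= lastEnd) keep[i] <- FALSE else lastEnd <- b[i, 2]
    }
    b <- b[keep, , drop = FALSE]
    b[b[, 2] <= nFrames, , drop = FALSE]
  })
}

#' Simulate an intrinsic-signal reflectance stack
#'
#' Trials have a baseline period followed by a post-stimulus period during
#' which reflectance inside a circular activation disc drops by a fixed
#' relative depth (a reflectance decrease marks activated cortex), with
#' additive Gaussian noise everywhere.
#'
#' @param height,width image size (pixels).
#' @param nTrials number of trials.
#' @param center disc centre, (row, col), 1-based pixels.
#' @param radius disc radius (pixels).
#' @param depth fractional reflectance decrease inside the disc (e.g. 0.05).
#' @param noiseSd additive Gaussian noise SD (reflectance units).
#' @param baselineR baseline reflectance level.
#' @param frameRate Hz (30 for intrinsic imaging).
#' @param baselineFrames frames before stimulus onset (default 30 = 1 s).
#' @param postFrames frames after stimulus onset (default 30 = 1 s).
#' @param seed integer seed.
#' @return A list with `stack` (array height x width x frames x trials),
#'   `stimOnsetFrame` (0-based), `frameRate`, and `truth` (list: `mask`
#'   logical disc image, `center`, `radius`, `depth`, `areaPx`).
#' @export
simulateReflectanceStack <- function(height = 64L, width = 64L, nTrials = 30L,
                                     center = c(32, 32), radius = 10,
                                     depth = 0.05, noiseSd = 0,
                                     baselineR = 1, frameRate = 30,
                                     baselineFrames = 30L, postFrames = 30L,
                                     seed = 1L) {
  if (center[1] - radius < 1 || center[1] + radius > height ||
      center[2] - radius < 1 || center[2] + radius > width)
    validationError("activation disc extends outside the image")
  rr <- matrix(seq_len(height), height, width)
  cc <- matrix(seq_len(width), height, width, byrow = TRUE)
  mask <- (rr - center[1])^2 + (cc - center[2])^2 <= radius^2
  nF <- baselineFrames + postFrames
  stack <- array(baselineR, dim = c(height, width, nF, nTrials))
  post <- seq.int(baselineFrames + 1L, nF)
  for (tr in seq_len(nTrials))
    for (f in post)
      stack[, , f, tr][mask] <- baselineR * (1 - depth)
  if (noiseSd > 0) {
    stack <- stack + withSeed(seed,
      array(stats::rnorm(length(stack), 0, noiseSd), dim = dim(stack)))
  }
  list(stack = stack, stimOnsetFrame = as.integer(baselineFrames),
       frameRate = frameRate,
       truth = list(mask = mask, center = center, radius = radius,
                    depth = depth, areaPx = sum(mask)))
}

#' Simulate a membrane-potential sweep with one EPSP
#'
#' Double-exponential EPSP
#' `V(t) = baseline + A * (exp(-(t-t0)/tauDecay) - exp(-(t-t0)/tauRise)) / k`
#' for `t >= t0`, normalised so the peak equals `amplitudeMv`, plus optional
#' Gaussian noise. At least 20 ms of pre-onset baseline is required so that
#' amplitude/latency metrics are defined.
#'
#' @param amplitudeMv peak EPSP amplitude (mV).
#' @param onsetMs EPSP onset time (ms, must be >= 20).
#' @param riseTauMs,decayTauMs rise and decay time constants (ms),
#'   `decayTauMs > riseTauMs`.
#' @param baselineMv resting potential (mV).
#' @param noiseSd Gaussian noise SD (mV).
#' @param rateHz sampling rate (Hz).
#' @param durationMs sweep duration (ms).
#' @param seed integer seed.
#' @return A list with `sweep` (data.frame: timeMs, mV) and `truth`
#'   (amplitudeMv, onsetMs, peakTimeMs).
#' @export
simulateEpspSweep <- function(amplitudeMv = 5, onsetMs = 100, riseTauMs = 2,
                              decayTauMs = 20, baselineMv = -70, noiseSd = 0,
                              rateHz = 10000, durationMs = 400, seed = 1L) {
  if (onsetMs < 20)
    validationError("'onsetMs' must be >= 20 ms (baseline window unavailable)")
  if (decayTauMs <= riseTauMs)
    validationError("'decayTauMs' must exceed 'riseTauMs'")
  dtMs <- 1000 / rateHz
  timeMs <- seq(0, durationMs, by = dtMs)
  tRel <- timeMs - onsetMs
  g <- ifelse(tRel >= 0,
              exp(-tRel / decayTauMs) - exp(-tRel / riseTauMs), 0)
  tPeak <- riseTauMs * decayTauMs / (decayTauMs - riseTauMs) *
    log(decayTauMs / riseTauMs)
  gPeak <- exp(-tPeak / decayTauMs) - exp(-tPeak / riseTauMs)
  v <- baselineMv + amplitudeMv * g / gPeak
  if (noiseSd > 0)
    v <- v + withSeed(seed, stats::rnorm(length(v), 0, noiseSd))
  list(sweep = data.frame(timeMs = timeMs, mV = v),
       truth = list(amplitudeMv = amplitudeMv, onsetMs = onsetMs,
                    peakTimeMs = onsetMs + tPeak))
}
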