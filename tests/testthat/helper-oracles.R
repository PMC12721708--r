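## Independent oracles used across the suite. These are deliberately naive
## implementations (sorting, explicit loops, dense grids) that never share
## code with the package paths they check.

## sort-based percentile with midpoint anchoring: order statistic k sits at
## probability (k - 0.5) / n; linear interpolation between neighbours
sortPercentileOracle <- function(x, p) {
  s <- sort(x)
  n <- length(s)
  q <- p / 100
  if (q <= 0.5 / n) return(s[1])
  if (q >= (n - 0.5) / n) return(s[n])
  k <- floor(q * n + 0.5)
  frac <- q * n + 0.5 - k
  s[k] + frac * (s[k + 1] - s[k])
}

## explicit sliding-window sample SDs, stride 1
rollingSdOracle <- function(x, w) {
  vapply(seq_len(length(x) - w + 1L), function(i) stats::sd(x[i:(i + w - 1L)]),
         numeric(1))
}

## brute-force truncated-window majority median for binary images
binaryMedianOracle <- function(b, size = 5L) {
  r <- (size - 1L) %/% 2L
  h <- nrow(b); w <- ncol(b)
  out <- b
  for (y in seq_len(h)) for (x in seq_len(w)) {
    win <- b[max(1, y - r):min(h, y + r), max(1, x - r):min(w, x + r)]
    out[y, x] <- sum(win) > length(win) / 2
  }
  out
}

## noiseless AR(1) trace from an impulse vector (independent of the
## package's stats::filter path)
ar1TraceOracle <- function(s, gamma) {
  c_ <- numeric(length(s))
  for (t in seq_along(s)) c_[t] <- if (t == 1) s[t] else gamma * c_[t - 1] + s[t]
  c_
}

## synthetic sessions at the study conditions; recovery statistics against
## ground truth with a +-2 frame matching tolerance
eventRecoveryStats <- function(seed, framesPerTrial = 310L, nPre = 10L,
                               nPost = 10L, spontRate = 0.1,
                               evokedProb = 0.8, noiseSd = 2,
                               stimOnsetFrame = 155L) {
  cfg <- synthSessionConfig(nRois = 1L, nTrialsPre = nPre, nTrialsPost = nPost,
                            framesPerTrial = framesPerTrial,
                            stimOnsetFrame = stimOnsetFrame,
                            spontRate = spontRate, evokedProb = evokedProb,
                            evokedLatencyMs = 50, latencyJitterMs = 30,
                            ampMean = 0.5, ampSd = 0.1, noiseSd = noiseSd,
                            seed = seed)
  sim <- simulateCalciumSession(cfg)
  dff <- (traceMatrix(sim$traces[[1]]) - cfg@baselineF) / cfg@baselineF
  sig <- noiseSigma(dff, cfg@frameRate)
  er <- oasisAR1(dff, cfg@gamma, sMin = 3 * sig)
  ev <- sim$truth$events
  b <- eventBinary(er)
  hit <- 0L
  for (i in seq_len(nrow(ev))) {
    rows <- max(1L, ev$frame[i] - 1L):min(nrow(b), ev$frame[i] + 3L)
    if (any(b[rows, ev$trial[i]])) hit <- hit + 1L
  }
  det <- which(b, arr.ind = TRUE)
  fp <- 0L
  for (i in seq_len(nrow(det))) {
    tf <- ev$frame[ev$trial == det[i, 2]]
    if (!length(tf) || min(abs(tf - (det[i, 1] - 1L))) > 2) fp <- fp + 1L
  }
  durationS <- framesPerTrial * (nPre + nPost) / cfg@frameRate
  list(recall = if (nrow(ev)) hit / nrow(ev) else NA_real_,
       fpPerS = fp / durationS, sim = sim, raster = er, sigma = sig,
       snr = sessionSnr(dff, sig), cfg = cfg)
}
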