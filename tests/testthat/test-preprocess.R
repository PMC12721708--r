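test_that("artifact frames are replaced by their neighbour mean", {
  tt <- trialTrace(matrix(c(2, 10, 4), 3, 1), 30.98, 0)
  expect_equal(traceMatrix(interpolateArtifacts(tt, 1))[, 1], c(2, 3, 4))
  expect_identical(traceMatrix(interpolateArtifacts(tt, integer())),
                   traceMatrix(tt))
  expect_error(interpolateArtifacts(tt, 0), "interior")
  expect_error(interpolateArtifacts(tt, 2), "interior")
})

test_that("interpolation error on a smooth trace is bounded by curvature", {
  t <- seq(0, 4 * pi, length.out = 300)
  smooth <- sin(t)
  set.seed(21)
  bad <- sort(sample(2:298, 20))
  corrupted <- smooth
  corrupted[bad + 1L] <- corrupted[bad + 1L] + 5   # 0-based frame bad
  tt <- interpolateArtifacts(trialTrace(matrix(corrupted, ncol = 1), 30.98, 0),
                             bad)
  maxCurv <- max(abs(diff(smooth, differences = 2)))
  expect_lt(max(abs(traceMatrix(tt)[, 1] - smooth)), maxCurv)
})

test_that("background subtraction removes the P1 of the background trace", {
  tt <- trialTrace(matrix(100, 50, 2), 30.98, 5)
  out <- subtractBackground(tt, rep(7, 100))
  expect_true(all(traceMatrix(out) == 93))
  # a single low outlier dominates the 1st percentile
  bg <- c(rep(50, 99), -100)
  expect_equal(traceMatrix(subtractBackground(tt, bg))[1, 1],
               100 - sortPercentileOracle(bg, 1))
  expect_error(subtractBackground(tt, numeric(0)), "non-empty")
})

test_that("Savitzky-Golay smoothing preserves constants and lines", {
  expect_equal(savGolSmooth(rep(2.5, 100)), rep(2.5, 100))
  ramp <- 0.3 * (1:120) - 4
  expect_equal(savGolSmooth(ramp), ramp, tolerance = 1e-10)
  expect_error(savGolSmooth(rnorm(30)), "shorter")
  expect_error(savGolSmooth(rnorm(100), order = 2), "first-order")
})

test_that("smoothing a noisy constant reduces interior variance ~51-fold", {
  set.seed(22)
  x <- rnorm(5000)
  sm <- savGolSmooth(x)[100:4900]
  ratio <- stats::var(x) / stats::var(sm)
  expect_gt(ratio, 35)
  expect_lt(ratio, 70)
})

test_that("S1 dF/F recipe: baseline, rejection and zero-division rules", {
  const <- dffS1(trialTrace(matrix(80, 200, 2), 30.98, 20))
  expect_equal(baselineF0(const), 80)
  expect_true(all(dffMatrix(const) == 0))
  neg <- dffS1(trialTrace(matrix(-5, 200, 2), 30.98, 20))
  expect_true(isRejected(neg))
  expect_match(neg@reason, "F0 < 0")
  expect_error(dffS1(trialTrace(matrix(0, 200, 2), 30.98, 20)), "zero")
})

test_that("S1 dF/F matches an independent per-point implementation", {
  set.seed(23)
  s <- numeric(200)
  s[c(40, 120)] <- c(0.5, 0.8)
  f <- 100 * (1 + ar1TraceOracle(s, 0.92))
  got <- dffS1(trialTrace(matrix(f, ncol = 1), 30.98, 10))
  # oracle: per-point least-squares line over the truncated window
  smOracle <- vapply(seq_along(f), function(i) {
    j <- max(1, i - 25):min(length(f), i + 25)
    unname(predict(lm(y ~ x, data.frame(x = j, y = f[j])),
                   data.frame(x = i)))
  }, numeric(1))
  f0 <- sortPercentileOracle(smOracle, 1)
  expect_equal(dffMatrix(got)[, 1], (smOracle - f0) / f0, tolerance = 1e-8)
})

test_that("cerebellar dF/F re-references to the pre-stimulus baseline", {
  const <- dffCerebellar(trialTrace(matrix(50, 100, 3), 30.98, 10))
  expect_true(all(dffMatrix(const) == 0))
  set.seed(24)
  tt <- trialTrace(matrix(100 + rnorm(300, sd = 5), 100, 3), 30.98, 10)
  d <- dffCerebellar(tt)
  for (tr in 1:3) {
    expect_equal(mean(dffMatrix(d)[6:10, tr]), 0, tolerance = 1e-12)
    expect_equal(baselineF0(d)[tr],
                 sortPercentileOracle(traceMatrix(tt)[, tr], 20))
  }
  expect_error(dffCerebellar(trialTrace(matrix(50, 100, 1), 30.98, 3)),
               ">= 5")
})

test_that("noise sigma equals the P1 of enumerated sliding-window SDs", {
  expect_equal(noiseSigma(matrix(0.3, 200, 1), 30.98), 0)
  # piecewise session: quiet first half, active second half
  set.seed(25)
  quiet <- rnorm(300, sd = 0.01)
  active <- 0.5 * sin(seq(0, 20, length.out = 300)) + rnorm(300, sd = 0.1)
  x <- c(quiet, active)
  sig <- noiseSigma(x, 30.98)
  expect_equal(sig, sortPercentileOracle(rollingSdOracle(x, 155), 1),
               tolerance = 1e-10)
  expect_lt(sig, 2 * stats::sd(quiet))       # sigma reflects the quiet epoch
  expect_lt(sig, stats::sd(x))               # never exceeds the global SD
  expect_error(noiseSigma(rnorm(100), 30.98), "shorter")
})

test_that("sigma never exceeds the session SD on simulated sessions", {
  for (s in 1:5) {
    r <- eventRecoveryStats(700 + s, framesPerTrial = 155L, nPre = 3L,
                            nPost = 3L, stimOnsetFrame = 50L)
    dff <- (traceMatrix(r$sim$traces[[1]]) - 100) / 100
    expect_lte(r$sigma, stats::sd(as.vector(dff)))
  }
})

test_that("SNR is the P95/sigma ratio and scales linearly", {
  set.seed(26)
  x <- rnorm(20000)
  expect_equal(sessionSnr(x, 1), stats::qnorm(0.95), tolerance = 0.03)
  expect_equal(sessionSnr(3 * x, 1), 3 * sessionSnr(x, 1), tolerance = 1e-12)
  expect_error(sessionSnr(x, 0), "sigma")
})

test_that("event amplitude raises the SNR monotonically", {
  snrAt <- function(amp) {
    cfg <- synthSessionConfig(nRois = 1, nTrialsPre = 5, nTrialsPost = 5,
                              framesPerTrial = 200, spontRate = 0.5,
                              evokedProb = 1, ampMean = amp, ampSd = 0,
                              noiseSd = 2, seed = 27)
    sim <- simulateCalciumSession(cfg)
    dff <- (traceMatrix(sim$traces[[1]]) - 100) / 100
    sessionSnr(dff, noiseSigma(dff, 30.98))
  }
  vals <- vapply(c(0.1, 0.3, 0.6), snrAt, numeric(1))
  expect_true(all(diff(vals) > 0))
})

test_that("rigid motion correction recovers known integer shifts", {
  set.seed(28)
  ref <- matrix(rnorm(40 * 40), 40, 40)
  stack <- array(0, dim = c(40, 40, 3))
  stack[, , 1] <- ref
  # frame shifted by (dy, dx) = (2, 3): img[y, x] = ref[y - 2, x - 3]
  shifted <- matrix(mean(ref), 40, 40)
  shifted[3:40, 4:40] <- ref[1:38, 1:37]
  stack[, , 2] <- shifted
  stack[, , 3] <- 5 * ref + 2     # intensity-scaled: correlation invariant
  out <- motionCorrectRigid(stack, reference = ref, searchRadius = 4)
  expect_equal(out$shifts[1, ], c(dy = 0L, dx = 0L))
  expect_equal(out$shifts[2, ], c(dy = 2L, dx = 3L))
  expect_equal(out$shifts[3, ], c(dy = 0L, dx = 0L))
  # correction restores the original up to the cropped border
  expect_equal(out$stack[5:36, 5:36, 2], ref[5:36, 5:36], tolerance = 1e-12)
  expect_error(motionCorrectRigid(array(0, dim = c(4, 4, 0))), "non-empty")
})
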