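test_that("invalid configurations are rejected with validation errors", {
  expect_error(synthSessionConfig(gamma = 1.2), class = "caplast_validation_error")
  expect_error(synthSessionConfig(gamma = NaN), class = "caplast_validation_error")
  expect_error(synthSessionConfig(evokedProb = 1.4), class = "caplast_validation_error")
  expect_error(synthSessionConfig(nRois = 0), class = "caplast_validation_error")
  expect_error(synthSessionConfig(plasticityFactor = -1), class = "caplast_validation_error")
  expect_error(synthSessionConfig(evokedLatencyMs = 1e6), class = "caplast_validation_error")
})

test_that("a source-free, noise-free session is constant at baseline", {
  cfg <- synthSessionConfig(nRois = 2, nTrialsPre = 3, nTrialsPost = 3,
                            framesPerTrial = 120, stimOnsetFrame = 30,
                            spontRate = 0, evokedProb = 0, noiseSd = 0,
                            seed = 5)
  sim <- simulateCalciumSession(cfg)
  for (tt in sim$traces)
    expect_true(all(traceMatrix(tt) == cfg@baselineF))
  expect_identical(nrow(sim$truth$events), 0L)
})

test_that("a single noiseless event decays as a*gamma^k exactly", {
  cfg <- synthSessionConfig(nRois = 1, nTrialsPre = 1, nTrialsPost = 1,
                            framesPerTrial = 150, spontRate = 0,
                            evokedProb = 1, latencyJitterMs = 0, ampSd = 0,
                            ampMean = 0.4, noiseSd = 0, gamma = 0.9,
                            stimOnsetFrame = 50, evokedLatencyMs = 50,
                            seed = 6)
  sim <- simulateCalciumSession(cfg)
  f <- traceMatrix(sim$traces[[1]])[, 1]
  ev <- sim$truth$events[sim$truth$events$trial == 1, ]
  onset <- ev$frame + 1L  # 1-based row
  k <- 0:20
  expect_equal(f[onset + k], cfg@baselineF * (1 + 0.4 * 0.9^k),
               tolerance = 1e-12)
  expect_true(all(f[seq_len(onset - 1L)] == cfg@baselineF))
})

test_that("spontaneous event counts follow the Poisson budget", {
  # 100 trials x 20 s at 1 event/s: expect ~2000 events, tolerance 3*sqrt(2000)
  cfg <- synthSessionConfig(nRois = 1, nTrialsPre = 50, nTrialsPost = 50,
                            framesPerTrial = 620, spontRate = 1,
                            evokedProb = 0, noiseSd = 0, seed = 7)
  sim <- simulateCalciumSession(cfg)
  expected <- 100 * 620 / 30.98
  expect_lt(abs(nrow(sim$truth$events) - expected), 3 * sqrt(expected))
})

test_that("seeds are reproducible and noise does not move events", {
  cfg1 <- synthSessionConfig(nRois = 2, nTrialsPre = 4, nTrialsPost = 4,
                             framesPerTrial = 150, stimOnsetFrame = 50,
                             seed = 11)
  a <- simulateCalciumSession(cfg1)
  b <- simulateCalciumSession(cfg1)
  expect_identical(traceMatrix(a$traces[[1]]), traceMatrix(b$traces[[1]]))
  expect_identical(a$truth$events, b$truth$events)
  # same seed, different noise level: event placement identical
  cfgNoiseless <- synthSessionConfig(nRois = 2, nTrialsPre = 4,
                                     nTrialsPost = 4, framesPerTrial = 150,
                                     stimOnsetFrame = 50, noiseSd = 0,
                                     seed = 11)
  c_ <- simulateCalciumSession(cfgNoiseless)
  expect_identical(a$truth$events, c_$truth$events)
})

test_that("event mass is conserved through the AR(1) recursion", {
  cfg <- synthSessionConfig(nRois = 1, nTrialsPre = 5, nTrialsPost = 5,
                            framesPerTrial = 200, spontRate = 0.5,
                            evokedProb = 0.7, noiseSd = 0, seed = 12)
  sim <- simulateCalciumSession(cfg)
  dff <- (traceMatrix(sim$traces[[1]]) - cfg@baselineF) / cfg@baselineF
  # sum over s[t] = c[t] - gamma*c[t-1] equals total injected amplitude
  impulseMass <- sum(apply(dff, 2, function(col)
    sum(col - cfg@gamma * c(0, col[-length(col)]))))
  expect_equal(impulseMass, sum(sim$truth$events$amplitude),
               tolerance = 1e-9)
})

test_that("doubling the amplitude doubles the noiseless evoked response", {
  mk <- function(amp) {
    cfg <- synthSessionConfig(nRois = 1, nTrialsPre = 4, nTrialsPost = 4,
                              framesPerTrial = 150, spontRate = 0,
                              evokedProb = 1, latencyJitterMs = 0,
                              ampMean = amp, ampSd = 0, noiseSd = 0,
                              stimOnsetFrame = 50, seed = 13)
    f <- traceMatrix(simulateCalciumSession(cfg)$traces[[1]])
    mean(f[60, ]) - cfg@baselineF
  }
  expect_equal(mk(0.6) / mk(0.3), 2, tolerance = 1e-9)
})

test_that("post-induction evoked amplitudes scale by the plasticity factor", {
  cfg <- synthSessionConfig(nRois = 1, nTrialsPre = 6, nTrialsPost = 6,
                            framesPerTrial = 150, spontRate = 0,
                            evokedProb = 1, latencyJitterMs = 0, ampSd = 0,
                            ampMean = 0.5, plasticityFactor = 1.5,
                            noiseSd = 0, stimOnsetFrame = 50, seed = 14)
  ev <- simulateCalciumSession(cfg)$truth$events
  expect_equal(unique(ev$amplitude[ev$trial <= 6]), 0.5)
  expect_equal(unique(ev$amplitude[ev$trial > 6]), 0.75)
})

test_that("motion traces mark exactly the bout frames", {
  expect_equal(sum(simulateMotionTrace(100)@moving), 0)
  mt <- simulateMotionTrace(100, rbind(c(10, 20)))
  expect_identical(sum(mt@moving), 10L)
  expect_true(all(which(mt@moving) == 11:20))
  expect_error(simulateMotionTrace(100, rbind(c(10, 20), c(15, 30))),
               class = "caplast_validation_error")
  expect_error(simulateMotionTrace(100, rbind(c(90, 110))),
               class = "caplast_validation_error")
  bouts <- simulateMovementBouts(500, nBouts = 8, seed = 3)
  mt2 <- simulateMotionTrace(500, bouts)
  expect_identical(sum(mt2@moving), sum(bouts[, 2] - bouts[, 1]))
})

test_that("reflectance stacks carry the stated activation depth", {
  rs0 <- simulateReflectanceStack(height = 32, width = 32, nTrials = 3,
                                  center = c(16, 16), radius = 5, depth = 0,
                                  noiseSd = 0)
  expect_equal(rs0$stack[, , 1, 1], rs0$stack[, , 60, 1])
  rs <- simulateReflectanceStack(height = 32, width = 32, nTrials = 3,
                                 center = c(16, 16), radius = 5,
                                 depth = 0.04, noiseSd = 0)
  img <- drrTrial(rs$stack, 1, rs$stimOnsetFrame)
  expect_equal(unique(round(img[rs$truth$mask], 12)), -3 * 0.04)
  expect_true(all(img[!rs$truth$mask] == 0))
  expect_error(simulateReflectanceStack(center = c(2, 2), radius = 10),
               class = "caplast_validation_error")
})

test_that("EPSP sweeps have the stated peak and baseline", {
  flat <- simulateEpspSweep(amplitudeMv = 0, noiseSd = 0)
  expect_equal(unique(flat$sweep$mV), -70)
  sw <- simulateEpspSweep(amplitudeMv = 5, onsetMs = 100, noiseSd = 0)
  expect_equal(max(sw$sweep$mV) - (-70), 5, tolerance = 1e-4)
  expect_error(simulateEpspSweep(onsetMs = 10),
               class = "caplast_validation_error")
})
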