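test_that("spontaneous detection: silence, one transient, sub-prominence", {
  expect_identical(nrow(detectSpontaneousEvents(rep(0, 200), 30.98)), 0L)
  s <- numeric(200)
  s[80] <- 0.5
  y <- ar1TraceOracle(s, 0.9)
  ev <- detectSpontaneousEvents(y, 30.98)
  expect_identical(nrow(ev), 1L)
  expect_lte(ev$onsetFrame, ev$peakFrame)
  expect_identical(ev$peakFrame, 79L)  # 0-based
  small <- detectSpontaneousEvents(ar1TraceOracle(replace(numeric(200), 80,
                                                          0.05), 0.9), 30.98)
  expect_identical(nrow(small), 0L)
})

test_that("spontaneous detection is translation-equivariant", {
  set.seed(41)
  s <- replace(numeric(300), c(50, 150, 220), c(0.4, 0.7, 0.3))
  y <- ar1TraceOracle(s, 0.9)
  evA <- detectSpontaneousEvents(y, 30.98)
  k <- 25L
  evB <- detectSpontaneousEvents(c(rep(0, k), y[1:(300 - k)]), 30.98)
  expect_identical(evB$peakFrame, evA$peakFrame[evA$peakFrame < 300 - k] + k)
})

test_that("event windows span 1 s and truncation is flagged", {
  s <- replace(numeric(100), 95, 0.5)
  ev <- detectSpontaneousEvents(ar1TraceOracle(s, 0.9), 30.98)
  expect_identical(ncol(attr(ev, "windows")), 31L)  # round(1 s * 30.98)
  expect_true(ev$truncated[1])
  pop <- spontaneousPopulationAverage(list(attr(ev, "windows")))
  expect_identical(length(pop), 31L)
})

test_that("P_event is the per-frame proportion of trials with an event", {
  b <- matrix(FALSE, 30, 3)
  b[11, c(1, 3)] <- TRUE
  p <- computePEvent(new("EventRaster", amplitudes = b * 1, binary = b,
                         sMin = 0, gamma = 0.9))
  expect_equal(pEvent(p)[11], 2 / 3)
  expect_equal(pEvent(p)[1], 0)
  expect_error(computePEvent(matrix(FALSE, 30, 1)), ">= 2")
})

test_that("adding an event never decreases any P_event entry", {
  set.seed(42)
  for (i in 1:20) {
    b <- matrix(runif(200) < 0.1, 20, 10)
    p0 <- pEvent(computePEvent(b))
    empty <- which(!b, arr.ind = TRUE)
    pick <- empty[sample(nrow(empty), 1), ]
    b[pick[1], pick[2]] <- TRUE
    expect_true(all(pEvent(computePEvent(b)) >= p0))
  }
})

test_that("evoked window duration follows the frame->ms rule", {
  mkProfile <- function(hotFrames, nFrames = 400, nTrials = 20) {
    b <- matrix(FALSE, nFrames, nTrials)
    b[hotFrames + 1L, 1:18] <- TRUE
    computePEvent(b)
  }
  w12 <- evokedWindow(mkProfile(40:51), 30, 30.98)
  expect_identical(w12@durationMs, 387)
  expect_identical(w12@startFrame, 40L)
  expect_identical(w12@endFrame, 52L)
  w1 <- evokedWindow(mkProfile(40), 30, 30.98)
  expect_identical(w1@durationMs, 32)
})

test_that("evoked window fails cleanly without a supra-threshold run", {
  b <- matrix(FALSE, 60, 5)   # no events at all: threshold 0, p == 0
  expect_error(evokedWindow(computePEvent(b), 10, 30.98),
               class = "caplast_no_evoked_window")
  # supra-threshold run entirely before stimulus onset does not count
  b2 <- matrix(FALSE, 60, 20)
  b2[5:8, 1:15] <- TRUE
  expect_error(evokedWindow(computePEvent(b2), 30, 30.98),
               class = "caplast_no_evoked_window")
})

test_that("responsive-trial selection matches a brute-force scan", {
  set.seed(43)
  b <- matrix(runif(600) < 0.08, 30, 20)
  er <- new("EventRaster", amplitudes = b * 1, binary = b, sMin = 0,
            gamma = 0.9)
  w <- new("EvokedWindow", startFrame = 10L, endFrame = 16L,
           durationMs = framesToMs(6, 30.98), frameRate = 30.98)
  got <- selectEvokedTrials(er, w)
  brute <- which(vapply(1:20, function(tr) any(b[11:16, tr]), logical(1)))
  expect_identical(got, brute)
  empty <- new("EventRaster", amplitudes = matrix(0, 30, 20),
               binary = matrix(FALSE, 30, 20), sMin = 0, gamma = 0.9)
  expect_identical(length(selectEvokedTrials(empty, w)), 0L)
  full <- new("EventRaster", amplitudes = matrix(1, 30, 20),
              binary = matrix(TRUE, 30, 20), sMin = 0, gamma = 0.9)
  expect_identical(selectEvokedTrials(full, w), 1:20)
})

test_that("persistent cells are the set intersection of responders", {
  expect_identical(persistentCells(c("a", "b"), c("c", "d")), character(0))
  expect_identical(persistentCells(1:5, 1:5), 1:5)
  set.seed(44)
  a <- sample(100, 30)
  b <- sample(100, 40)
  got <- persistentCells(a, b)
  expect_identical(got, a[vapply(a, function(x) x %in% b, logical(1))])
})

test_that("EPSP metrics recover amplitude and analytic latency", {
  sw <- simulateEpspSweep(amplitudeMv = 5, onsetMs = 100, riseTauMs = 2,
                          decayTauMs = 20, noiseSd = 0)
  m <- epspMetrics(sw$sweep, 100)
  expect_equal(m$amplitudeMv, 5, tolerance = 1e-4)
  # dense-grid oracle for the 10% crossing of the double exponential
  tg <- seq(0, 30, by = 1e-4)
  g <- exp(-tg / 20) - exp(-tg / 2)
  crossing <- tg[which(g / max(g) > 0.1)[1]]
  expect_lt(abs(m$latencyMs - crossing), 0.11)  # within one sample (0.1 ms)
  # a flat sweep has non-positive amplitude and undefined latency
  flat <- epspMetrics(data.frame(timeMs = seq(0, 200, 0.1), mV = -70), 100)
  expect_true(flat$flagged)
  expect_true(is.na(flat$latencyMs))
  expect_error(epspMetrics(data.frame(timeMs = 95:200, mV = 0), 100), "20 ms")
})
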