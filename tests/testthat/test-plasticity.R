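test_that("response windows: presets and AUC/amplitude basics", {
  expect_equal(responseWindow("default"), c(0, 700))
  expect_equal(responseWindow("late"), c(650, 850))
  expect_equal(responseWindow("sst_dreadd"), c(0, 1750))
  expect_error(responseWindow("bogus"), "unknown")
  expect_equal(responseAUC(rep(0.2, 100), c(0, 700), 30.98, 10), 0.14)
  expect_equal(responseAUC(rep(0, 100), c(0, 700), 30.98, 10), 0)
  expect_error(responseAUC(rep(0.2, 20), c(0, 700), 30.98, 10), "exceeds")
  x <- rep(0, 100); x[12:14] <- c(0, 0.3, 0.1)
  expect_equal(responseAmplitude(x, c(0, 700), 30.98, 10), 0.3)
  expect_equal(responseAmplitude(rep(0.4, 100), c(0, 700), 30.98, 10), 0.4)
})

test_that("AUC equals mean x duration and is linear", {
  set.seed(51)
  for (i in 1:50) {
    x <- rnorm(100)
    idx <- windowFrameIndices(0, 700, 10, 30.98, 100)
    expect_equal(responseAUC(x, c(0, 700), 30.98, 10),
                 sum(x[idx + 1]) / length(idx) * 0.7, tolerance = 1e-12)
    y <- rnorm(100)
    expect_equal(responseAUC(2 * x + 3 * y, c(0, 700), 30.98, 10),
                 2 * responseAUC(x, c(0, 700), 30.98, 10) +
                 3 * responseAUC(y, c(0, 700), 30.98, 10), tolerance = 1e-12)
    expect_gte(responseAmplitude(x, c(0, 700), 30.98, 10),
               responseAUC(x, c(0, 700), 30.98, 10) / 0.7)
  }
})

noiselessNeurons <- function(factor, nNeurons = 3) {
  cfg <- synthSessionConfig(nRois = nNeurons, nTrialsPre = 5, nTrialsPost = 5,
                            framesPerTrial = 120, spontRate = 0,
                            evokedProb = 1, latencyJitterMs = 0, ampSd = 0,
                            plasticityFactor = factor, noiseSd = 0,
                            stimOnsetFrame = 30, seed = 52)
  sim <- simulateCalciumSession(cfg)
  lapply(seq_len(nNeurons), function(r) {
    dff <- (traceMatrix(sim$traces[[r]]) - 100) / 100
    list(id = paste0("n", r), mouse = "m1", dffPre = dff[, 1:5],
         dffPost = dff[, 6:10], trialsPre = 1:5, trialsPost = 1:5)
  })
}

test_that("noiseless plasticity factors are recovered exactly", {
  tab <- quantifyPlasticity(noiselessNeurons(1.5), c(0, 700), 30.98, 30)
  expect_equal(tab$ratioAUC, rep(1.5, 3), tolerance = 1e-9)
  expect_equal(tab$ampPost / tab$ampPre, rep(1.5, 3), tolerance = 1e-9)
  null <- quantifyPlasticity(noiselessNeurons(1.0), c(0, 700), 30.98, 30)
  expect_equal(null$ratioAUC, rep(1, 3), tolerance = 1e-9)
})

test_that("neurons without responsive trials in an epoch are excluded", {
  neurons <- noiselessNeurons(1.2)
  neurons[[2]]$trialsPost <- integer()
  tab <- quantifyPlasticity(neurons, c(0, 700), 30.98, 30)
  expect_identical(nrow(tab), 2L)
  expect_identical(attr(tab, "excluded"), "n2")
  # adding trials back can only add neurons, never remove
  neurons[[2]]$trialsPost <- 1:2
  tab2 <- quantifyPlasticity(neurons, c(0, 700), 30.98, 30)
  expect_true(all(tab$neuron %in% tab2$neuron))
  expect_identical(nrow(tab2), 3L)
})

test_that("mouse summary averages persistent cells per animal", {
  neurons <- noiselessNeurons(1.5, nNeurons = 4)
  neurons[[3]]$mouse <- neurons[[4]]$mouse <- "m2"
  tab <- quantifyPlasticity(neurons, c(0, 700), 30.98, 30)
  ms <- mouseSummary(tab)
  expect_identical(ms$mouse, c("m1", "m2"))
  expect_equal(ms$ratioAUC, c(1.5, 1.5), tolerance = 1e-9)
})

test_that("time-binned AUC uses half-open 10-min bins", {
  dff <- matrix(0.2, 60, 4)
  nb <- list(list(dff = dff, trialTimesMin = c(0, 5, 10, 25)))
  out <- timeBinnedAUC(nb, c(0, 700), 30.98, 10, totalMin = 40)
  expect_equal(out$nCells, c(1, 1, 1, 0))
  # constant responses give identical populated bin means
  expect_equal(out$meanAUC[1], out$meanAUC[2], tolerance = 1e-12)
  expect_equal(out$meanAUC[1], 0.14, tolerance = 1e-12)
  expect_true(is.na(out$meanAUC[4]))  # empty bin is missing, not zero
  # a trial at exactly 10 min falls in bin [10, 20)
  nb10 <- list(list(dff = dff[, 1, drop = FALSE], trialTimesMin = 10))
  out10 <- timeBinnedAUC(nb10, c(0, 700), 30.98, 10, totalMin = 20)
  expect_equal(out10$nCells, c(0, 1))
})

test_that("per-mouse normalisation and the one-sample test against 1", {
  allOne <- normalizeByMouse(c(2, 3, 4), c(2, 3, 4))
  expect_equal(allOne$statistic, 0)
  expect_equal(allOne$pValue, 1)
  degen <- normalizeByMouse(c(4, 4, 4), c(2, 2, 2))   # ratios all 2
  expect_true(degen$degenerate)
  expect_true(is.na(degen$pValue))
  set.seed(53)
  for (i in 1:20) {
    r <- 1 + rnorm(8, sd = 0.2)
    got <- normalizeByMouse(r, rep(1, 8))
    tOracle <- (mean(r) - 1) / (stats::sd(r) / sqrt(8))
    expect_equal(got$statistic, tOracle, tolerance = 1e-12)
  }
  expect_warning(z <- normalizeByMouse(c(1, 2, 3), c(1, 2, 0)), "zero baseline")
  expect_identical(z$n, 2L)
})
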