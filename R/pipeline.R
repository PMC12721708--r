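## End-to-end orchestration over synthetic cohorts: simulate -> preprocess
## -> deconvolve -> detect -> quantify plasticity (-> rest-trial filter ->
## per-mouse statistics), writing every intermediate plus a manifest with
## parameters, seeds and per-file checksums.

#' Default pipeline configuration
#'
#' Returns the parameter list consumed by [runPipeline()]. Synthetic-session
#' parameters follow [synthSessionConfig()]; the pipeline-level defaults
#' keep the smoke-scale cohort small (2 mice x 4 ROIs x 10+10 trials of
#' 310 frames) while every stage runs exactly as at full scale.
#'
#' @param ... overrides of any field of the returned list.
#' @return Named list of parameters.
#' @export
pipelineConfig <- function(...) {
  cfg <- list(
    nMice = 2L, nRois = 4L, nTrialsPre = 10L, nTrialsPost = 10L,
    framesPerTrial = 310L, frameRate = 30.98, stimOnsetFrame = 155L,
    gamma = exp(-1 / (0.4 * 30.98)), spontRate = 0.1, evokedProb = 0.8,
    evokedLatencyMs = 50, latencyJitterMs = 30, ampMean = 0.5, ampSd = 0.1,
    plasticityFactor = 1.3, baselineF = 100, noiseSd = 1,
    indicatorTauSeconds = 0.4, sigmaMultiplier = 3,
    window = c(0, 700), guardMs = 400, motionThreshold = 0.5,
    restFilter = TRUE, alpha = 0.05)
  over <- list(...)
  cfg[names(over)] <- over
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' Fields in the file override the defaults of [pipelineConfig()]; unknown
#' fields are rejected so typos fail loudly.
#'
#' @param path YAML file with a flat mapping of parameter overrides.
#' @return Named list of parameters, as [pipelineConfig()].
#' @export
readPipelineConfig <- function(path) {
  over <- yaml::read_yaml(path)
  base <- pipelineConfig()
  unknown <- setdiff(names(over), names(base))
  if (length(unknown))
    stop("unknown pipeline parameters: ", paste(unknown, collapse = ", "))
  base[names(over)] <- over
  base
}

#' Run the full synthetic-cohort pipeline
#'
#' Simulates `nMice` calcium sessions, preprocesses every ROI with the S1
#' dF/F recipe, deconvolves with the 3 sigma-thresholded AR(1) solver,
#' derives each ROI's evoked-event window from its P_event profile, selects
#' responsive trials pre and post induction, quantifies plasticity (AUC and
#' amplitude) over persistent cells, classifies rest versus active trials
#' from a simulated movement trace and re-quantifies on the rest subset,
#' and normalises mouse-level AUC ratios with a one-sample test against 1.
#' Every stage writes its artifact into `outDir`; `manifest.json` records
#' parameters, seeds, stage file names and MD5 checksums.
#'
#' @param config list from [pipelineConfig()].
#' @param outDir output directory (created if missing).
#' @param seed master seed; per-mouse and motion substreams derive from it.
#' @return Invisibly, a list with `plasticity`, `plasticityRest`,
#'   `mouseStats`, `manifest`.
#' @export
runPipeline <- function(config = pipelineConfig(), outDir, seed = 1L) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  mouseSeeds <- subSeeds(seed, config$nMice + 1L)
  motionSeed <- mouseSeeds[config$nMice + 1L]
  files <- character()
  neurons <- list()
  neuronsRest <- list()
  dffRows <- list()
  eventRows <- list()
  windowInfo <- list()
  preIdx <- seq_len(config$nTrialsPre)
  nT <- config$nTrialsPre + config$nTrialsPost

  for (m in seq_len(config$nMice)) {
    scfg <- synthSessionConfig(
      nRois = config$nRois, nTrialsPre = config$nTrialsPre,
      nTrialsPost = config$nTrialsPost,
      framesPerTrial = config$framesPerTrial, frameRate = config$frameRate,
      stimOnsetFrame = config$stimOnsetFrame, gamma = config$gamma,
      spontRate = config$spontRate, evokedProb = config$evokedProb,
      evokedLatencyMs = config$evokedLatencyMs,
      latencyJitterMs = config$latencyJitterMs, ampMean = config$ampMean,
      ampSd = config$ampSd, plasticityFactor = config$plasticityFactor,
      baselineF = config$baselineF, noiseSd = config$noiseSd,
      seed = mouseSeeds[m])
    sim <- simulateCalciumSession(scfg)
    sessionFile <- file.path(outDir, sprintf("session_mouse%02d.csv", m))
    writeSession(sim$traces, sessionFile)
    files <- c(files, sessionFile, sidecarPath(sessionFile))

    ## per-session movement trace, sample-synchronous with imaging
    bouts <- simulateMovementBouts(config$framesPerTrial * nT,
                                   nBouts = 3L * nT %/% 2L,
                                   lenRange = c(5L, 40L),
                                   seed = motionSeed + m)
    motion <- simulateMotionTrace(config$framesPerTrial * nT, bouts,
                                  config$frameRate)
    labels <- classifyTrials(motion, config$framesPerTrial,
                             config$stimOnsetFrame, config$guardMs)
    restTrials <- which(labels == "rest")

    for (r in seq_len(config$nRois)) {
      roiId <- sprintf("m%02d_roi%03d", m, r)
      dffObj <- tryCatch(dffS1(sim$traces[[r]]), error = function(e) e)
      if (inherits(dffObj, "error") || isRejected(dffObj)) {
        dffRows[[roiId]] <- data.frame(mouse = m, roi = r, f0 = NA,
                                       sigma = NA, snr = NA, rejected = TRUE)
        next
      }
      sig <- noiseSigmaValue(dffObj)
      dffRows[[roiId]] <- data.frame(
        mouse = m, roi = r, f0 = baselineF0(dffObj), sigma = sig,
        snr = snrValue(dffObj), rejected = FALSE)
      gamma <- estimateGamma(frameRate = config$frameRate,
                             tauSeconds = config$indicatorTauSeconds)
      raster <- oasisAR1(dffObj, gamma,
                         sMin = config$sigmaMultiplier * sig)
      eventRows[[roiId]] <- data.frame(
        mouse = m, roi = r, nEvents = sum(eventBinary(raster)))
      profile <- computePEvent(raster)
      win <- tryCatch(
        evokedWindow(profile, config$stimOnsetFrame, config$frameRate),
        caplast_no_evoked_window = function(e) NULL)
      if (is.null(win)) {
        windowInfo[[roiId]] <- data.frame(mouse = m, roi = r,
                                          startFrame = NA, endFrame = NA,
                                          durationMs = NA)
        next
      }
      windowInfo[[roiId]] <- data.frame(
        mouse = m, roi = r, startFrame = win@startFrame,
        endFrame = win@endFrame, durationMs = win@durationMs)
      responsive <- selectEvokedTrials(raster, win)
      d <- dffMatrix(dffObj)
      mkNeuron <- function(keep) {
        list(id = roiId, mouse = sprintf("mouse%02d", m),
             dffPre = d[, preIdx, drop = FALSE],
             dffPost = d[, -preIdx, drop = FALSE],
             trialsPre = intersect(responsive, intersect(preIdx, keep)),
             trialsPost = setdiff(intersect(responsive, keep), preIdx) -
               config$nTrialsPre)
      }
      neurons[[roiId]] <- mkNeuron(seq_len(nT))
      neuronsRest[[roiId]] <- mkNeuron(restTrials)
    }
  }

  writeStage <- function(df, name) {
    f <- file.path(outDir, name)
    utils::write.csv(df, f, row.names = FALSE)
    f
  }
  files <- c(files,
             writeStage(do.call(rbind, dffRows), "dff_summary.csv"),
             writeStage(do.call(rbind, eventRows), "event_counts.csv"),
             writeStage(do.call(rbind, windowInfo), "evoked_windows.csv"))

  tab <- quantifyPlasticity(neurons, config$window, config$frameRate,
                            config$stimOnsetFrame)
  tabRest <- quantifyPlasticity(neuronsRest, config$window,
                                config$frameRate, config$stimOnsetFrame)
  tabRest$subset <- "rest"
  files <- c(files, writeStage(tab, "plasticity.csv"),
             writeStage(tabRest, "plasticity_rest.csv"))

  ms <- mouseSummary(tab)
  stats_ <- if (nrow(ms) >= 2L)
    normalizeByMouse(stats::setNames(ms$aucPost, ms$mouse),
                     stats::setNames(ms$aucPre, ms$mouse)) else
    list(ratios = ms$ratioAUC, n = nrow(ms), statistic = NA, pValue = NA,
         degenerate = TRUE, excluded = character(), label = "n.s.")
  statsFile <- file.path(outDir, "mouse_stats.json")
  jsonlite::write_json(stats_[c("ratios", "n", "statistic", "pValue",
                                "label")],
                       statsFile, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  files <- c(files, statsFile)

  manifest <- list(
    package = "caplast",
    version = as.character(utils::packageVersion("caplast")),
    seed = seed, parameters = config,
    stages = c("simulate", "preprocess", "deconv", "detect", "behavior",
               "plasticity", "stats"),
    files = basename(files),
    checksums = as.list(stats::setNames(unname(tools::md5sum(files)),
                                        basename(files))))
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(plasticity = tab, plasticityRest = tabRest,
                 mouseStats = stats_, manifest = manifest))
}
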