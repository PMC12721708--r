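## Plasticity quantification: windowed AUC and amplitude on trial-averaged
## dF/F, pre/post comparison over persistent cells, 10-min binned
## trajectories, and per-animal normalisation with a one-sample test
## against 1.

#' Named response windows
#'
#' Post-stimulus analysis windows in ms: `"default"` 0-700 (standard AUC and
#' amplitude window), `"late"` 650-850 (late-phase modulation), and
#' `"sst_dreadd"` 0-1750 (prolonged responses under chemogenetic
#' manipulation).
#'
#' @param name preset name, or `NULL` to use `startMs`/`endMs`.
#' @param startMs,endMs explicit bounds (ms relative to stimulus onset).
#' @return Numeric vector `c(startMs, endMs)`.
#' @examples
#' responseWindow("late")  # c(650, 850)
#' @export
responseWindow <- function(name = NULL, startMs = 0, endMs = 700) {
  presets <- list(default = c(0, 700), late = c(650, 850),
                  sst_dreadd = c(0, 1750))
  w <- if (!is.null(name)) {
    if (!name %in% names(presets)) stop("unknown window preset: ", name)
    presets[[name]]
  } else c(startMs, endMs)
  if (w[2] <= w[1]) stop("window end must exceed its start")
  w
}

#' Area under the curve of a trial-averaged response
#'
#' AUC = mean dF/F over the window's frames multiplied by the window
#' duration in seconds (the AUC is thus directly proportional to the mean
#' response). Reported in dF/F x s.
#'
#' @param dffAvg numeric vector: trial-averaged dF/F over one trial's
#'   frames.
#' @param window `c(startMs, endMs)` from [responseWindow()].
#' @param frameRate Hz.
#' @param stimOnsetFrame 0-based stimulus-onset frame.
#' @return AUC in dF/F x s.
#' @examples
#' responseAUC(rep(0.2, 100), c(0, 700), 30.98, 10)  # 0.14
#' @export
responseAUC <- function(dffAvg, window, frameRate, stimOnsetFrame) {
  idx <- windowFrameIndices(window[1], window[2], stimOnsetFrame, frameRate,
                            length(dffAvg))
  mean(dffAvg[idx + 1L]) * (window[2] - window[1]) / 1000
}

#' Maximum amplitude of a trial-averaged response
#'
#' The maximum dF/F value within the response window.
#'
#' @inheritParams responseAUC
#' @return Amplitude in dF/F units.
#' @export
responseAmplitude <- function(dffAvg, window, frameRate, stimOnsetFrame) {
  idx <- windowFrameIndices(window[1], window[2], stimOnsetFrame, frameRate,
                            length(dffAvg))
  max(dffAvg[idx + 1L])
}

#' Pre/post plasticity quantification over persistent cells
#'
#' For each neuron with responsive trials in both epochs (persistent cells),
#' trial-averages the selected trials per epoch and computes windowed AUC
#' and amplitude; neurons missing responsive trials in either epoch are
#' excluded and listed in the `"excluded"` attribute.
#'
#' @param neurons list; each element a list with `dffPre`, `dffPost`
#'   (frames x trials dF/F matrices), `trialsPre`, `trialsPost` (1-based
#'   indices of responsive trials), and optionally `mouse` and `id`.
#' @param window `c(startMs, endMs)`.
#' @param frameRate Hz.
#' @param stimOnsetFrame 0-based stimulus-onset frame.
#' @return data.frame with columns `neuron`, `mouse`, `aucPre`, `aucPost`,
#'   `ampPre`, `ampPost`, `ratioAUC` (post/pre); attribute `"excluded"`
#'   holds the names of dropped neurons.
#' @export
quantifyPlasticity <- function(neurons, window, frameRate, stimOnsetFrame) {
  rows <- list()
  excluded <- character()
  for (k in seq_along(neurons)) {
    nb <- neurons[[k]]
    id <- if (!is.null(nb$id)) nb$id else paste0("neuron", k)
    mouse <- if (!is.null(nb$mouse)) nb$mouse else "mouse1"
    if (!length(nb$trialsPre) || !length(nb$trialsPost)) {
      excluded <- c(excluded, id)
      next
    }
    avgPre <- rowMeans(nb$dffPre[, nb$trialsPre, drop = FALSE])
    avgPost <- rowMeans(nb$dffPost[, nb$trialsPost, drop = FALSE])
    aucPre <- responseAUC(avgPre, window, frameRate, stimOnsetFrame)
    aucPost <- responseAUC(avgPost, window, frameRate, stimOnsetFrame)
    rows[[length(rows) + 1L]] <- data.frame(
      neuron = id, mouse = mouse, aucPre = aucPre, aucPost = aucPost,
      ampPre = responseAmplitude(avgPre, window, frameRate, stimOnsetFrame),
      ampPost = responseAmplitude(avgPost, window, frameRate, stimOnsetFrame),
      ratioAUC = if (aucPre != 0) aucPost / aucPre else NA_real_)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(neuron = character(), mouse = character(), aucPre = numeric(),
               aucPost = numeric(), ampPre = numeric(), ampPost = numeric(),
               ratioAUC = numeric())
  rownames(out) <- NULL
  attr(out, "excluded") <- excluded
  out
}

#' Per-mouse summary of a plasticity table
#'
#' Unweighted mean over each mouse's persistent cells, with the normalised
#' post/pre ratio of the mouse-level means.
#'
#' @param table output of [quantifyPlasticity()].
#' @return data.frame, one row per mouse: mean AUC/amplitude pre and post
#'   and `ratioAUC = mean(aucPost) / mean(aucPre)`.
#' @export
mouseSummary <- function(table) {
  sp <- split(table, table$mouse)
  out <- do.call(rbind, lapply(names(sp), function(m) {
    d <- sp[[m]]
    data.frame(mouse = m, n = nrow(d),
               aucPre = mean(d$aucPre), aucPost = mean(d$aucPost),
               ampPre = mean(d$ampPre), ampPost = mean(d$ampPost),
               ratioAUC = mean(d$aucPost) / mean(d$aucPre))
  }))
  rownames(out) <- NULL
  out
}

#' Time-binned AUC trajectory after induction
#'
#' Assigns post-induction trials to half-open 10-min bins by their stimulus
#' time, trial-averages within cells per bin, computes the windowed AUC, and
#' averages across cells. Bins that no cell populates are reported as `NA`,
#' not zero.
#'
#' @param neurons list; each element a list with `dff` (frames x trials) and
#'   `trialTimesMin` (stimulus time of each trial, minutes after the end of
#'   induction).
#' @param window `c(startMs, endMs)`.
#' @param frameRate Hz.
#' @param stimOnsetFrame 0-based stimulus-onset frame.
#' @param binMin bin width in minutes (default 10).
#' @param totalMin trajectory span in minutes (default 60).
#' @return data.frame with `binStartMin`, `binEndMin`, `meanAUC`, `nCells`.
#' @export
timeBinnedAUC <- function(neurons, window, frameRate, stimOnsetFrame,
                          binMin = 10, totalMin = 60) {
  starts <- seq(0, totalMin - binMin, by = binMin)
  perCell <- lapply(neurons, function(nb) {
    vapply(starts, function(s) {
      inBin <- nb$trialTimesMin >= s & nb$trialTimesMin < s + binMin
      if (!any(inBin)) return(NA_real_)
      avg <- rowMeans(nb$dff[, inBin, drop = FALSE])
      responseAUC(avg, window, frameRate, stimOnsetFrame)
    }, numeric(1))
  })
  m <- do.call(rbind, perCell)
  data.frame(binStartMin = starts, binEndMin = starts + binMin,
             meanAUC = colMeans(m, na.rm = TRUE) * ifelse(
               colSums(!is.na(m)) > 0, 1, NA),
             nCells = colSums(!is.na(m)))
}

#' Per-animal normalisation and one-sample test against 1
#'
#' Divides each animal's response in the experimental condition by its
#' baseline response and tests the ratios against the standard value 1 with
#' a one-sample t-test. Animals with a zero baseline are excluded (and
#' listed); zero-variance ratio sets leave the test undefined and are
#' flagged rather than tested.
#'
#' @param conditionMeans named numeric vector, one mean response per mouse.
#' @param baselineMeans matching baseline responses.
#' @return A list: `ratios`, `n`, `statistic`, `pValue`, `degenerate`,
#'   `excluded` (mice dropped for zero baseline), `label`.
#' @export
normalizeByMouse <- function(conditionMeans, baselineMeans) {
  if (length(conditionMeans) != length(baselineMeans))
    stop("condition and baseline must be paired per mouse")
  zero <- baselineMeans == 0
  excluded <- names(conditionMeans)[zero]
  if (any(zero))
    warning("excluding ", sum(zero), " mice with zero baseline")
  ratios <- conditionMeans[!zero] / baselineMeans[!zero]
  n <- length(ratios)
  if (n < 2L)
    return(list(ratios = ratios, n = n, statistic = NA_real_,
                pValue = NA_real_, degenerate = TRUE, excluded = excluded,
                label = "n.s."))
  if (stats::sd(ratios) == 0) {
    if (all(ratios == 1))
      return(list(ratios = ratios, n = n, statistic = 0, pValue = 1,
                  degenerate = FALSE, excluded = excluded, label = "n.s."))
    return(list(ratios = ratios, n = n, statistic = NA_real_,
                pValue = NA_real_, degenerate = TRUE, excluded = excluded,
                label = "n.s."))
  }
  ht <- stats::t.test(ratios, mu = 1)
  list(ratios = ratios, n = n, statistic = unname(ht$statistic),
       pValue = ht$p.value, degenerate = FALSE, excluded = excluded,
       label = significanceLabel(ht$p.value))
}
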