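## Plain-text I/O: trial-structured sessions as CSV with a JSON sidecar of
## acquisition metadata, reflectance stacks as multi-page TIFF.

sidecarPath <- function(path) paste0(path, ".json")

#' Write a session of TrialTraces
#'
#' Writes all ROIs to one long-format CSV (`roi`, `trial`, `frame`,
#' `value`; frames 0-based) plus a JSON sidecar (`<path>.json`) carrying
#' `frame_rate`, `stim_onset_frame`, `brain_area` and the ROI ids. Values
#' are serialised with 17 significant digits, so a write/read round trip is
#' bit-identical.
#'
#' @param traces list of [TrialTrace-class] objects sharing geometry.
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
writeSession <- function(traces, path) {
  stopifnot(length(traces) > 0L, all(vapply(traces, is, logical(1),
                                            "TrialTrace")))
  rows <- lapply(seq_along(traces), function(r) {
    v <- traces[[r]]@values
    data.frame(roi = r,
               trial = rep(seq_len(ncol(v)), each = nrow(v)),
               frame = rep(seq_len(nrow(v)) - 1L, ncol(v)),
               value = sprintf("%.17g", as.vector(v)))
  })
  df <- do.call(rbind, rows)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  meta <- list(frame_rate = traces[[1]]@frameRate,
               stim_onset_frame = traces[[1]]@stimOnsetFrame,
               brain_area = traces[[1]]@brainArea,
               roi_ids = vapply(traces, function(x) x@roiId, character(1)),
               n_frames = nrow(traces[[1]]@values),
               n_trials = ncol(traces[[1]]@values))
  jsonlite::write_json(meta, sidecarPath(path), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

schemaError <- function(...) {
  stop(errorCondition(paste0(...),
                      class = c("caplast_schema_error", "error")))
}

#' Read a session written by [writeSession()]
#'
#' @param path CSV path (the `<path>.json` sidecar must exist).
#' @return List of [TrialTrace-class] objects.
#' @export
readSession <- function(path) {
  if (!file.exists(path)) schemaError("session file not found: ", path)
  if (!file.exists(sidecarPath(path)))
    schemaError("missing metadata sidecar: ", sidecarPath(path))
  meta <- try(jsonlite::read_json(sidecarPath(path), simplifyVector = TRUE),
              silent = TRUE)
  if (inherits(meta, "try-error"))
    schemaError("unreadable metadata sidecar: ", sidecarPath(path))
  for (field in c("frame_rate", "stim_onset_frame", "brain_area", "roi_ids",
                  "n_frames", "n_trials"))
    if (is.null(meta[[field]]))
      schemaError("metadata sidecar lacks required field '", field, "'")
  df <- try(utils::read.csv(path), silent = TRUE)
  if (inherits(df, "try-error") ||
      !all(c("roi", "trial", "frame", "value") %in% names(df)))
    schemaError("malformed session CSV: ", path)
  lapply(seq_along(meta$roi_ids), function(r) {
    d <- df[df$roi == r, ]
    if (nrow(d) != meta$n_frames * meta$n_trials)
      schemaError("ROI ", r, " has ", nrow(d), " samples; expected ",
                  meta$n_frames * meta$n_trials)
    v <- matrix(0, meta$n_frames, meta$n_trials)
    v[cbind(d$frame + 1L, d$trial)] <- d$value
    trialTrace(v, meta$frame_rate, meta$stim_onset_frame,
               roiId = meta$roi_ids[r], brainArea = meta$brain_area)
  })
}

#' Write / read an image stack as multi-page TIFF
#'
#' Frames are stored as 32-bit float pages. Values are written as-is;
#' callers keep reflectance near \[0, 1\] for portability.
#'
#' @param stack array height x width x frames.
#' @param path TIFF path.
#' @return `writeStackTiff`: `path`, invisibly. `readStackTiff`: the array.
#' @export
writeStackTiff <- function(stack, path) {
  pages <- lapply(seq_len(dim(stack)[3]), function(f) stack[, , f])
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  invisible(path)
}

#' @rdname writeStackTiff
#' @export
readStackTiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  array(unlist(pages), dim = c(dim(pages[[1]]), length(pages)))
}
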