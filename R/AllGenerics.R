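#' Accessor generics
#'
#' Small accessor family for the package's S4 containers; prefer these over
#' direct slot access.
#'
#' @param object a package S4 object.
#' @return The corresponding slot value.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("frameRate", function(object) standardGeneric("frameRate"))

#' @rdname accessors
#' @export
setGeneric("stimOnsetFrame", function(object) standardGeneric("stimOnsetFrame"))

#' @rdname accessors
#' @export
setGeneric("traceMatrix", function(object) standardGeneric("traceMatrix"))

#' @rdname accessors
#' @export
setGeneric("dffMatrix", function(object) standardGeneric("dffMatrix"))

#' @rdname accessors
#' @export
setGeneric("baselineF0", function(object) standardGeneric("baselineF0"))

#' @rdname accessors
#' @export
setGeneric("noiseSigmaValue", function(object) standardGeneric("noiseSigmaValue"))

#' @rdname accessors
#' @export
setGeneric("snrValue", function(object) standardGeneric("snrValue"))

#' @rdname accessors
#' @export
setGeneric("isRejected", function(object) standardGeneric("isRejected"))

#' @rdname accessors
#' @export
setGeneric("eventAmplitudes", function(object) standardGeneric("eventAmplitudes"))

#' @rdname accessors
#' @export
setGeneric("eventBinary", function(object) standardGeneric("eventBinary"))

#' @rdname accessors
#' @export
setGeneric("pEvent", function(object) standardGeneric("pEvent"))

#' @rdname accessors
#' @export
setGeneric("nFrames", function(object) standardGeneric("nFrames"))

#' @rdname accessors
#' @export
setGeneric("nTrials", function(object) standardGeneric("nTrials"))

#' @rdname accessors
#' @export
setGeneric("activationArea", function(object) standardGeneric("activationArea"))

#' @rdname accessors
#' @export
setMethod("frameRate", "TrialTrace", function(object) object@frameRate)
#' @rdname accessors
#' @export
setMethod("frameRate", "DffSession", function(object) object@frameRate)
#' @rdname accessors
#' @export
setMethod("frameRate", "MotionTrace", function(object) object@frameRate)
#' @rdname accessors
#' @export
setMethod("frameRate", "EvokedWindow", function(object) object@frameRate)

#' @rdname accessors
#' @export
setMethod("stimOnsetFrame", "TrialTrace", function(object) object@stimOnsetFrame)
#' @rdname accessors
#' @export
setMethod("stimOnsetFrame", "DffSession", function(object) object@stimOnsetFrame)

#' @rdname accessors
#' @export
setMethod("traceMatrix", "TrialTrace", function(object) object@values)

#' @rdname accessors
#' @export
setMethod("dffMatrix", "DffSession", function(object) object@dff)

#' @rdname accessors
#' @export
setMethod("baselineF0", "DffSession", function(object) object@f0)

#' @rdname accessors
#' @export
setMethod("noiseSigmaValue", "DffSession", function(object) object@sigma)

#' @rdname accessors
#' @export
setMethod("snrValue", "DffSession", function(object) object@snr)

#' @rdname accessors
#' @export
setMethod("isRejected", "DffSession", function(object) object@rejected)

#' @rdname accessors
#' @export
setMethod("eventAmplitudes", "EventRaster", function(object) object@amplitudes)

#' @rdname accessors
#' @export
setMethod("eventBinary", "EventRaster", function(object) object@binary)

#' @rdname accessors
#' @export
setMethod("pEvent", "PEventProfile", function(object) object@p)

#' @rdname accessors
#' @export
setMethod("nFrames", "TrialTrace", function(object) nrow(object@values))
#' @rdname accessors
#' @export
setMethod("nFrames", "DffSession", function(object) nrow(object@dff))
#' @rdname accessors
#' @export
setMethod("nFrames", "EventRaster", function(object) nrow(object@amplitudes))

#' @rdname accessors
#' @export
setMethod("nTrials", "TrialTrace", function(object) ncol(object@values))
#' @rdname accessors
#' @export
setMethod("nTrials", "DffSession", function(object) ncol(object@dff))
#' @rdname accessors
#' @export
setMethod("nTrials", "EventRaster", function(object) ncol(object@amplitudes))

#' @rdname accessors
#' @export
setMethod("activationArea", "ActivationMap", function(object)
  c(px = object@areaPx, norm = object@areaNorm))
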