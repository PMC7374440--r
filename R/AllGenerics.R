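#' @rdname SignalRecord-class
#' @param object,x a \linkS4class{SignalRecord} (or other object as
#'   documented for each method).
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))

#' @rdname SignalRecord-class
#' @export
setGeneric("channelRoles", function(x) standardGeneric("channelRoles"))

#' @rdname SignalRecord-class
#' @export
setGeneric("annotations", function(x) standardGeneric("annotations"))

#' @rdname SignalRecord-class
#' @export
setGeneric("signalMatrix", function(x) standardGeneric("signalMatrix"))

#' @rdname SignalRecord-class
#' @export
setGeneric("recordDuration", function(x) standardGeneric("recordDuration"))

#' @rdname EnvelopeSeries-class
#' @export
setGeneric("envelopeValues", function(x) standardGeneric("envelopeValues"))

#' @rdname EnvelopeSeries-class
#' @export
setGeneric("outputRate", function(x) standardGeneric("outputRate"))

#' @rdname CoherenceSpectrum-class
#' @export
setGeneric("frequencies", function(x) standardGeneric("frequencies"))

#' @rdname CoherenceSpectrum-class
#' @export
setGeneric("coherenceValues", function(x) standardGeneric("coherenceValues"))

#' @rdname CoherenceSpectrum-class
#' @export
setGeneric("effectiveSegments", function(x) standardGeneric("effectiveSegments"))

#' @rdname CoherenceSpectrum-class
#' @export
setGeneric("confidenceLimit", function(x) standardGeneric("confidenceLimit"))

#' @rdname ZDiffSpectrum-class
#' @export
setGeneric("zValues", function(x) standardGeneric("zValues"))
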