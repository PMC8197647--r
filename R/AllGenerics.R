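#' @rdname accessors
#' @export
setGeneric("sampleRate", function(x) standardGeneric("sampleRate"))

#' @rdname accessors
#' @export
setGeneric("channelLabel", function(x) standardGeneric("channelLabel"))

#' @rdname accessors
#' @export
setGeneric("signalValues", function(x) standardGeneric("signalValues"))

#' @rdname accessors
#' @export
setGeneric("signalTimes", function(x) standardGeneric("signalTimes"))

#' @rdname accessors
#' @export
setGeneric("sessionMeta", function(x) standardGeneric("sessionMeta"))

#' @rdname accessors
#' @export
setGeneric("sessionEvents", function(x) standardGeneric("sessionEvents"))

#' @rdname accessors
#' @export
setGeneric("sessionSignal", function(x, label) standardGeneric("sessionSignal"))

#' @rdname accessors
#' @export
setGeneric("sessionTracking", function(x) standardGeneric("sessionTracking"))

#' @rdname accessors
#' @export
setGeneric("solutionMap", function(x) standardGeneric("solutionMap"))

#' @rdname accessors
#' @export
setGeneric("trialInfo", function(x) standardGeneric("trialInfo"))

#' @rdname accessors
#' @export
setGeneric("trialZ", function(x) standardGeneric("trialZ"))

#' @rdname accessors
#' @export
setGeneric("binCenters", function(x) standardGeneric("binCenters"))

#' @rdname accessors
#' @export
setGeneric("effectSize", function(x) standardGeneric("effectSize"))

#' @rdname accessors
#' @export
setGeneric("confInt", function(x) standardGeneric("confInt"))

#' @rdname accessors
#' @export
setGeneric("permP", function(x) standardGeneric("permP"))
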