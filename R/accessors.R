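#' Accessors for protophot classes
#'
#' Small accessor layer over the S4 slots: sampling rate, channel label,
#' values and time axis of a \linkS4class{PhotometrySignal}; metadata, event
#' log, channels and tracking of a \linkS4class{PhotometrySession}; trial
#' info, z matrix and bin grid of a \linkS4class{TrialSet}; effect, CI and
#' permutation p of an \linkS4class{EstimationResult}.
#'
#' @param x the object.
#' @param label channel label for \code{sessionSignal}.
#' @return the corresponding component.
#' @name accessors
NULL

#' @rdname accessors
setMethod("sampleRate", "PhotometrySignal", function(x) x@sample_rate)

#' @rdname accessors
setMethod("channelLabel", "PhotometrySignal", function(x) x@channel_label)

#' @rdname accessors
setMethod("signalValues", "PhotometrySignal", function(x) x@values)

#' @rdname accessors
setMethod("signalTimes", "PhotometrySignal", function(x) x@timestamps)

#' @rdname accessors
setMethod("sessionMeta", "PhotometrySession", function(x) x@meta)

#' @rdname accessors
setMethod("sessionEvents", "PhotometrySession", function(x) x@events)

#' @rdname accessors
setMethod("sessionSignal", "PhotometrySession", function(x, label) {
  if (!label %in% names(x@signals))
    stop("session has no channel '", label, "'")
  x@signals[[label]]
})

#' @rdname accessors
setMethod("sessionTracking", "PhotometrySession", function(x) x@tracking)

#' @rdname accessors
setMethod("solutionMap", "EventLog", function(x) x@solution_map)

#' @rdname accessors
setMethod("solutionMap", "PhotometrySession", function(x) x@events@solution_map)

#' @rdname accessors
setMethod("trialInfo", "TrialSet", function(x) x@info)

#' @rdname accessors
setMethod("trialZ", "TrialSet", function(x) x@z)

#' @rdname accessors
setMethod("binCenters", "TrialSet", function(x) x@bin_centers)

#' @rdname accessors
setMethod("effectSize", "EstimationResult", function(x) x@effect)

#' @rdname accessors
setMethod("confInt", "EstimationResult", function(x) c(x@ci_low, x@ci_high))

#' @rdname accessors
setMethod("permP", "EstimationResult", function(x) x@p_perm)
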