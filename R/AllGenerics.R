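#' @include AllClasses.R
NULL

#' @rdname StimulusTimeline-class
#' @param object,x a \code{StimulusTimeline}
#' @export
setGeneric("nBlocks", function(x) standardGeneric("nBlocks"))

#' @rdname StimulusTimeline-class
#' @export
setGeneric("blockOnsets", function(x) standardGeneric("blockOnsets"))

#' @rdname StimulusTimeline-class
#' @export
setGeneric("totalDuration", function(x) standardGeneric("totalDuration"))

#' @rdname StimulusTimeline-class
#' @export
setGeneric("stimulusColor", function(x) standardGeneric("stimulusColor"))

#' @rdname Recording-class
#' @param x a \code{Recording}
#' @export
setGeneric("channelNames", function(x) standardGeneric("channelNames"))

#' @rdname Recording-class
#' @param channel channel label
#' @export
setGeneric("channelSamples", function(x, channel) standardGeneric("channelSamples"))

#' @rdname Recording-class
#' @export
setGeneric("channelRate", function(x, channel) standardGeneric("channelRate"))

#' @rdname Recording-class
#' @export
setGeneric("channelUnits", function(x, channel) standardGeneric("channelUnits"))

#' @rdname Recording-class
#' @export
setGeneric("annotations", function(x) standardGeneric("annotations"))

#' @rdname Recording-class
#' @export
setGeneric("timeline", function(x) standardGeneric("timeline"))

#' @rdname TrialBlock-class
#' @param x a \code{TrialBlock} or \code{ConnectivityMatrix}
#' @export
setGeneric("signalLabels", function(x) standardGeneric("signalLabels"))

#' @rdname SubjectResult-class
#' @param x a \code{SubjectResult}
#' @export
setGeneric("blockAverage", function(x) standardGeneric("blockAverage"))

#' @rdname SubjectResult-class
#' @export
setGeneric("gateWeights", function(x) standardGeneric("gateWeights"))

#' @rdname ConnectivityMatrix-class
#' @param x a \code{ConnectivityMatrix}
#' @export
setGeneric("correlationValues", function(x) standardGeneric("correlationValues"))

#' @rdname ConnectivityMatrix-class
#' @export
setGeneric("significanceMask", function(x) standardGeneric("significanceMask"))

#' @rdname GroupModel-class
#' @param object,x a \code{GroupModel}
#' @export
setGeneric("isIndeterminate", function(x) standardGeneric("isIndeterminate"))
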