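#' @include AllGenerics.R
NULL

#' @rdname StimulusTimeline-class
#' @export
setMethod("nBlocks", "StimulusTimeline", function(x) length(x@blockOnsets))

#' @rdname StimulusTimeline-class
#' @export
setMethod("blockOnsets", "StimulusTimeline", function(x) x@blockOnsets)

#' @rdname StimulusTimeline-class
#' @export
setMethod("totalDuration", "StimulusTimeline", function(x) {
  x@baselineDuration + nBlocks(x) * x@onDuration + sum(x@offDurations) +
    x@recoveryDuration
})

#' @rdname StimulusTimeline-class
#' @export
setMethod("stimulusColor", "StimulusTimeline", function(x) x@color)

setMethod("show", "StimulusTimeline", function(object) {
  cat(sprintf("StimulusTimeline: %d blocks of %gs on, color %s (%g nm, %g lx)\n",
              nBlocks(object), object@onDuration, object@color,
              object@wavelength, object@illuminance))
  cat(sprintf("  baseline %gs | stimulation %gs | recovery %gs | total %gs\n",
              object@baselineDuration,
              nBlocks(object) * object@onDuration + sum(object@offDurations),
              object@recoveryDuration, totalDuration(object)))
})

setMethod("show", "SubjectProfile", function(object) {
  cat(sprintf("SubjectProfile %s: %s, %g y, %d channel amplitudes\n",
              object@subjectId, object@gender, object@age,
              length(object@responseAmplitudes)))
})

#' @rdname Recording-class
#' @export
setMethod("channelNames", "Recording", function(x) names(x@channels))

#' @rdname Recording-class
#' @export
setMethod("channelSamples", "Recording", function(x, channel) {
  ch <- x@channels[[channel]]
  if (is.null(ch)) stop("no channel '", channel, "' in recording")
  ch$samples
})

#' @rdname Recording-class
#' @export
setMethod("channelRate", "Recording", function(x, channel) {
  ch <- x@channels[[channel]]
  if (is.null(ch)) stop("no channel '", channel, "' in recording")
  ch$fs
})

#' @rdname Recording-class
#' @export
setMethod("channelUnits", "Recording", function(x, channel) {
  ch <- x@channels[[channel]]
  if (is.null(ch)) stop("no channel '", channel, "' in recording")
  ch$units
})

#' @rdname Recording-class
#' @export
setMethod("annotations", "Recording", function(x) x@annotations)

#' @rdname Recording-class
#' @export
setMethod("timeline", "Recording", function(x) x@timeline)

setMethod("show", "Recording", function(object) {
  cat(sprintf("Recording with %d channel(s)\n", length(object@channels)))
  for (nm in channelNames(object)) {
    ch <- object@channels[[nm]]
    cat(sprintf("  %-12s %8d samples @ %5g Hz [%s]\n",
                nm, length(ch$samples), ch$fs, ch$units))
  }
  if (!is.null(object@timeline))
    cat(sprintf("  timeline: %d blocks, color %s\n",
                nBlocks(object@timeline), stimulusColor(object@timeline)))
  if (length(object@annotations))
    cat("  annotations:", paste(names(object@annotations), collapse = ", "), "\n")
})

#' @rdname TrialBlock-class
#' @export
setMethod("signalLabels", "TrialBlock", function(x) rownames(x@segment))

setMethod("show", "TrialBlock", function(object) {
  cat(sprintf("TrialBlock at %gs: %d signal(s) x %d samples @ %g Hz%s\n",
              object@onsetTime, nrow(object@segment), ncol(object@segment),
              object@fs,
              if (object@normalized) " (normalized)" else ""))
})

#' @rdname SubjectResult-class
#' @export
setMethod("blockAverage", "SubjectResult", function(x) x@blockAverage)

#' @rdname SubjectResult-class
#' @export
setMethod("gateWeights", "SubjectResult", function(x) x@weight)

setMethod("show", "SubjectResult", function(object) {
  cat(sprintf("SubjectResult %s (color %s): %d signal(s), %d gated\n",
              object@subjectId, object@covariates$color,
              nrow(object@blockAverage), sum(object@weight)))
})

#' @rdname GroupModel-class
#' @export
setMethod("isIndeterminate", "GroupModel", function(x) x@indeterminate)

setMethod("show", "GroupModel", function(object) {
  if (object@indeterminate) {
    cat(sprintf("GroupModel: indeterminate (%d gated subject(s))\n",
                object@nGated))
    return(invisible(NULL))
  }
  cat(sprintf("GroupModel (tau = %g, %d bootstraps, %d gated subjects)\n",
              object@tau, object@nBoot, object@nGated))
  tab <- data.frame(estimate = object@coefficients,
                    lower = object@ci[1L, ], upper = object@ci[2L, ],
                    significant = object@significant)
  print(round(tab, 4))
})

#' @rdname ConnectivityMatrix-class
#' @export
setMethod("signalLabels", "ConnectivityMatrix", function(x) x@labels)

#' @rdname ConnectivityMatrix-class
#' @export
setMethod("correlationValues", "ConnectivityMatrix", function(x) x@rho)

#' @rdname ConnectivityMatrix-class
#' @export
setMethod("significanceMask", "ConnectivityMatrix", function(x) x@mask)

setMethod("show", "ConnectivityMatrix", function(object) {
  p <- length(object@labels)
  kept <- sum(object@mask[upper.tri(object@mask)])
  cat(sprintf("ConnectivityMatrix: %d signals, %d/%d pairs significant\n",
              p, kept, p * (p - 1) / 2))
})

setMethod("show", "NetworkMetrics", function(object) {
  cat(sprintf("NetworkMetrics: rw = %.4f, Tw = %.4f, D = %.4f, Ew = %.4f\n",
              object@rw, object@Tw, object@D, object@Ew))
})

#' Extract the four metrics as a named numeric vector
#'
#' @param x a [NetworkMetrics-class] object
#' @param ... unused
#' @return named numeric vector with elements rw, Tw, D, Ew
#' @export
setMethod("as.numeric", "NetworkMetrics", function(x, ...) {
  c(rw = x@rw, Tw = x@Tw, D = x@D, Ew = x@Ew)
})
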