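#' @import methods
NULL

#' StimulusTimeline: protocol phases and stimulus block timing
#'
#' Represents one session of the intermittent wide-field visual stimulation
#' protocol: a dark baseline, a train of light-on blocks separated by
#' randomized light-off periods, and a dark recovery phase. Times are in
#' seconds from the start of the recording; the first block starts at the end
#' of the baseline and the last block is followed directly by the recovery
#' phase (there is no trailing off period).
#'
#' @slot baselineDuration baseline phase length, seconds
#' @slot recoveryDuration recovery phase length, seconds
#' @slot blockOnsets light-on onset times, seconds, strictly increasing
#' @slot onDuration light-on duration, seconds (common to all blocks)
#' @slot offDurations light-off durations between consecutive blocks,
#'   seconds, length \code{nBlocks - 1}
#' @slot color stimulus color, one of \code{"red"}, \code{"green"},
#'   \code{"blue"}
#' @slot wavelength peak wavelength of the stimulus light, nm
#' @slot illuminance illuminance at eye level, lux
#'
#' @seealso [generateProtocol()]
#' @export
setClass("StimulusTimeline",
  representation(
    baselineDuration = "numeric",
    recoveryDuration = "numeric",
    blockOnsets      = "numeric",
    onDuration       = "numeric",
    offDurations     = "numeric",
    color            = "character",
    wavelength       = "numeric",
    illuminance      = "numeric"
  )
)

setValidity("StimulusTimeline", function(object) {
  msg <- character()
  n <- length(object@blockOnsets)
  if (n < 1L) msg <- c(msg, "at least one stimulus block is required")
  if (n > 1L && any(diff(object@blockOnsets) <= 0))
    msg <- c(msg, "block onsets must be strictly increasing")
  if (length(object@offDurations) != max(n - 1L, 0L))
    msg <- c(msg, "offDurations must have length nBlocks - 1")
  if (object@baselineDuration < 0 || object@recoveryDuration < 0 ||
      object@onDuration <= 0)
    msg <- c(msg, "durations must be positive")
  if (any(object@offDurations <= 0))
    msg <- c(msg, "off durations must be positive")
  if (!object@color %in% c("red", "green", "blue"))
    msg <- c(msg, "color must be one of red, green, blue")
  if (n >= 1L &&
      !isTRUE(all.equal(object@blockOnsets[1L], object@baselineDuration)))
    msg <- c(msg, "first onset must equal the baseline duration")
  if (n > 1L) {
    expected <- object@blockOnsets[-n] + object@onDuration + object@offDurations
    if (max(abs(expected - object@blockOnsets[-1L])) > 1e-9)
      msg <- c(msg, "onsets must chain as onset + on + off")
  }
  if (length(msg)) msg else TRUE
})

#' SubjectProfile: per-subject simulation parameters
#'
#' Holds a subject's demographics together with the per-channel evoked
#' response amplitudes and noise scales used by the signal generators.
#' Amplitudes are in the units of the channel they drive (e.g. micromolar
#' for hemoglobin concentrations, percent for StO2).
#'
#' @slot subjectId subject identifier
#' @slot age age in years
#' @slot gender \code{"male"} or \code{"female"}
#' @slot responseAmplitudes named numeric vector of true evoked amplitudes
#' @slot noiseScales named numeric vector of noise standard deviations
#' @export
setClass("SubjectProfile",
  representation(
    subjectId          = "character",
    age                = "numeric",
    gender             = "character",
    responseAmplitudes = "numeric",
    noiseScales        = "numeric"
  )
)

setValidity("SubjectProfile", function(object) {
  msg <- character()
  if (length(object@age) != 1L || !is.finite(object@age) || object@age <= 0)
    msg <- c(msg, "age must be a single positive number")
  if (!object@gender %in% c("male", "female"))
    msg <- c(msg, "gender must be 'male' or 'female'")
  if (any(!is.finite(object@responseAmplitudes)))
    msg <- c(msg, "response amplitudes must be finite")
  if (length(msg)) msg else TRUE
})

#' Recording: labeled multichannel physiological time series
#'
#' The common container for raw, preprocessed and derived channels. Each
#' channel is a list with elements \code{samples} (numeric vector, NA marks
#' missing), \code{fs} (sampling rate, Hz) and \code{units}. Channels may
#' have different sampling rates (50-Hz fNIRS next to a 2-Hz skin-conductance
#' stream); all channels start at time 0 with sample i at time (i-1)/fs.
#' \code{annotations} carries simulation ground truth (true evoked
#' amplitudes, artifact masks, true respiratory rate and end-tidal CO2
#' traces) used as test oracles; it is empty for ingested data.
#'
#' @slot channels named list of channels
#' @slot timeline the session [StimulusTimeline], or NULL
#' @slot annotations list of ground-truth annotations
#' @export
setClass("Recording",
  representation(
    channels    = "list",
    timeline    = "ANY",
    annotations = "list"
  ),
  prototype(channels = list(), timeline = NULL, annotations = list())
)

setValidity("Recording", function(object) {
  msg <- character()
  ch <- object@channels
  if (length(ch) && is.null(names(ch)))
    msg <- c(msg, "channels must be named")
  for (nm in names(ch)) {
    c1 <- ch[[nm]]
    if (!all(c("samples", "fs", "units") %in% names(c1))) {
      msg <- c(msg, sprintf("channel '%s' must have samples, fs, units", nm))
      next
    }
    if (!is.numeric(c1$fs) || length(c1$fs) != 1L || c1$fs <= 0)
      msg <- c(msg, sprintf("channel '%s' must have fs > 0", nm))
    bad <- !is.finite(c1$samples) & !is.na(c1$samples)
    if (any(bad))
      msg <- c(msg, sprintf("channel '%s' has non-finite samples", nm))
  }
  if (!is.null(object@timeline) && !is(object@timeline, "StimulusTimeline"))
    msg <- c(msg, "timeline must be a StimulusTimeline or NULL")
  # generator contract: total hemoglobin is the sum of oxy and deoxy.
  # Enforced strictly only while the annotation flag set by the generator is
  # present; preprocessing perturbs the identity within filter tolerance.
  groups <- if (isTRUE(object@annotations$tHbExact))
    unique(sub("^(O2Hb|HHb|tHb)_", "", grep("^tHb_", names(ch), value = TRUE)))
  else character()
  for (loc in groups) {
    o <- ch[[paste0("O2Hb_", loc)]]; h <- ch[[paste0("HHb_", loc)]]
    t <- ch[[paste0("tHb_", loc)]]
    if (!is.null(o) && !is.null(h) && !is.null(t) &&
        length(o$samples) == length(t$samples) &&
        length(h$samples) == length(t$samples)) {
      d <- abs(t$samples - (o$samples + h$samples))
      if (any(d > 1e-6, na.rm = TRUE))
        msg <- c(msg, sprintf("tHb_%s != O2Hb_%s + HHb_%s", loc, loc, loc))
    }
  }
  if (length(msg)) msg else TRUE
})

#' TrialBlock: one stimulus-locked 35-s trial segment
#'
#' A signals x samples matrix covering [onset - 5 s, onset + 30 s) on the
#' common 2-Hz analysis grid (70 samples). Interval medians are taken over
#' the seven 3-s windows [1,4], [6,9], [11,14], [16,19], [21,24], [26,29]
#' and [31,34] s relative to segment start; the stimulus (light on at 5 s,
#' off at 25 s) is covered by the four intervals between 6 and 24 s.
#'
#' @slot segment numeric matrix, signals in rows, 70 columns
#' @slot onsetTime stimulus onset, seconds from recording start
#' @slot fs sampling rate of the segment grid, Hz
#' @slot intervalMedians signals x 7 matrix of interval medians (or a
#'   0-column matrix before [intervalMedians()] has been applied)
#' @slot baselineRef per-signal baseline reference subtracted during
#'   normalization (median of the 1-4 s interval)
#' @slot normalized logical, TRUE after [normalizeDetrend()]
#' @export
setClass("TrialBlock",
  representation(
    segment         = "matrix",
    onsetTime       = "numeric",
    fs              = "numeric",
    intervalMedians = "matrix",
    baselineRef     = "numeric",
    normalized      = "logical"
  ),
  prototype(intervalMedians = matrix(numeric(), 0, 0), baselineRef = numeric(),
            normalized = FALSE)
)

setValidity("TrialBlock", function(object) {
  msg <- character()
  if (length(object@fs) != 1L || object@fs <= 0)
    msg <- c(msg, "fs must be a single positive number")
  if (ncol(object@segment) != round(35 * object@fs))
    msg <- c(msg, "segment must span 35 s")
  if (is.null(rownames(object@segment)))
    msg <- c(msg, "segment rows must be named by signal")
  if (ncol(object@intervalMedians) &&
      ncol(object@intervalMedians) != 7L)
    msg <- c(msg, "intervalMedians must have 7 columns")
  if (length(msg)) msg else TRUE
})

#' SubjectResult: per subject/color block-average statistics
#'
#' @slot blockAverage signals x 7 matrix, across-trial medians of the
#'   interval medians
#' @slot pvals signals x 4 matrix, signed-rank p per stimulus interval
#' @slot h named logical, per-signal significance after FDR correction
#' @slot weight named numeric in {0,1}, equal to \code{h}; weights the
#'   subject's block averages in the group model
#' @slot covariates list with elements color, age, gender
#' @slot subjectId subject identifier
#' @export
setClass("SubjectResult",
  representation(
    blockAverage = "matrix",
    pvals        = "matrix",
    h            = "logical",
    weight       = "numeric",
    covariates   = "list",
    subjectId    = "character"
  )
)

setValidity("SubjectResult", function(object) {
  msg <- character()
  if (!identical(unname(object@weight), unname(as.numeric(object@h))))
    msg <- c(msg, "weight must be 0 exactly when h is FALSE and 1 otherwise")
  if (ncol(object@pvals) != 4L)
    msg <- c(msg, "pvals must have one column per stimulus interval (4)")
  if (!all(c("color", "age", "gender") %in% names(object@covariates)))
    msg <- c(msg, "covariates must contain color, age, gender")
  if (length(msg)) msg else TRUE
})

#' GroupModel: group-level quantile-regression fit
#'
#' Median (or general tau) regression of gated subject-level block averages
#' on an intercept and optional color contrasts, age and gender, with
#' subject-resampling bootstrap confidence intervals. A model is
#' indeterminate when fewer than two subjects pass the subject-level gate.
#'
#' @slot coefficients named numeric, point estimates
#' @slot ci 2 x terms matrix of bootstrap percentile bounds
#' @slot nBoot number of bootstrap draws
#' @slot tau estimated quantile
#' @slot terms term names
#' @slot significant named logical, CI excludes zero
#' @slot indeterminate logical
#' @slot nGated number of subjects with nonzero weight
#' @slot bootstrap nBoot x terms matrix of bootstrap coefficient draws
#'   (for derived linear-combination intervals)
#' @export
setClass("GroupModel",
  representation(
    coefficients  = "numeric",
    ci            = "matrix",
    nBoot         = "numeric",
    tau           = "numeric",
    terms         = "character",
    significant   = "logical",
    indeterminate = "logical",
    nGated        = "numeric",
    bootstrap     = "matrix"
  ),
  prototype(bootstrap = matrix(numeric(), 0, 0))
)

setValidity("GroupModel", function(object) {
  if (object@indeterminate) return(TRUE)
  est <- object@coefficients
  lo <- object@ci[1L, ]; hi <- object@ci[2L, ]
  if (any(lo > est + 1e-8) || any(hi < est - 1e-8))
    return("ci must bracket the point estimate")
  TRUE
})

#' ConnectivityMatrix: significance-masked Spearman correlation matrix
#'
#' Symmetric matrix of Spearman rank correlations between stimulus-evoked
#' signal time courses, with entries deleted (masked) where the correlation
#' was not significant after FDR correction. \code{nEff} counts the
#' matrices/trials that contributed to each entry after averaging.
#'
#' @slot labels ordered signal names
#' @slot rho labels x labels numeric matrix; masked entries are NA
#' @slot mask labels x labels logical; TRUE where the entry is retained
#' @slot nEff labels x labels numeric contribution counts
#' @export
setClass("ConnectivityMatrix",
  representation(
    labels = "character",
    rho    = "matrix",
    mask   = "matrix",
    nEff   = "matrix"
  )
)

setValidity("ConnectivityMatrix", function(object) {
  msg <- character()
  p <- length(object@labels)
  if (!all(dim(object@rho) == p) || !all(dim(object@mask) == p) ||
      !all(dim(object@nEff) == p))
    msg <- c(msg, "rho, mask, nEff must be labels x labels")
  else {
    if (any(abs(object@rho - t(object@rho)) > 1e-12, na.rm = TRUE))
      msg <- c(msg, "rho must be symmetric")
    off <- object@rho[upper.tri(object@rho)]
    if (any(abs(off) > 1 + 1e-12, na.rm = TRUE))
      msg <- c(msg, "correlations must lie in [-1, 1]")
    if (any(!is.na(object@rho[!object@mask & upper.tri(object@rho)])))
      msg <- c(msg, "masked entries must carry no value")
  }
  if (length(msg)) msg else TRUE
})

#' NetworkMetrics: weighted complex-network summary of a connectivity graph
#'
#' @slot rw weighted assortativity coefficient, in [-1, 1] (NA when
#'   undefined, e.g. fewer than two edges or constant endpoint strengths)
#' @slot Tw weighted transitivity, >= 0
#' @slot D density, in [0, 1]
#' @slot Ew weighted global efficiency, in [0, 1] for weights <= 1
#' @export
setClass("NetworkMetrics",
  representation(rw = "numeric", Tw = "numeric", D = "numeric",
                 Ew = "numeric")
)

setValidity("NetworkMetrics", function(object) {
  msg <- character()
  if (!is.na(object@rw) && abs(object@rw) > 1 + 1e-9)
    msg <- c(msg, "rw must lie in [-1, 1]")
  if (!is.na(object@Tw) && object@Tw < -1e-12)
    msg <- c(msg, "Tw must be nonnegative")
  if (object@D < -1e-12 || object@D > 1 + 1e-12)
    msg <- c(msg, "D must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})
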