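#' @include AllClasses.R
NULL

#' Write / read a stimulus timeline
#'
#' Timelines are stored as small structured text (YAML): phase durations,
#' block onsets/durations and color metadata.
#'
#' @param timelineObj a [StimulusTimeline-class]
#' @param path file path
#' @return \code{readTimeline} returns a [StimulusTimeline-class]
#' @export
writeTimeline <- function(timelineObj, path) {
  yaml::write_yaml(list(
    baseline_duration = timelineObj@baselineDuration,
    recovery_duration = timelineObj@recoveryDuration,
    block_onsets = timelineObj@blockOnsets,
    on_duration = timelineObj@onDuration,
    off_durations = timelineObj@offDurations,
    color = timelineObj@color,
    wavelength = timelineObj@wavelength,
    illuminance = timelineObj@illuminance), path)
  invisible(path)
}

#' @rdname writeTimeline
#' @export
readTimeline <- function(path) {
  y <- yaml::read_yaml(path)
  new("StimulusTimeline",
      baselineDuration = as.numeric(y$baseline_duration),
      recoveryDuration = as.numeric(y$recovery_duration),
      blockOnsets = as.numeric(y$block_onsets),
      onDuration = as.numeric(y$on_duration),
      offDurations = as.numeric(y$off_durations),
      color = y$color, wavelength = as.numeric(y$wavelength),
      illuminance = as.numeric(y$illuminance))
}

# run-length encode a logical mask into 1-based [start, end] segments
maskToSegments <- function(flag) {
  r <- logicalRuns(flag)
  lapply(seq_len(nrow(r)), function(i)
    list(start = unname(r[i, 1L]), end = unname(r[i, 2L])))
}

segmentsToMask <- function(segs, n) {
  flag <- logical(n)
  for (s in segs) flag[s$start:s$end] <- TRUE
  flag
}

#' Write a recording as delimited text with a metadata sidecar
#'
#' Channels are grouped by sampling rate; each group is one tab-separated
#' file with a time column and one column per channel. The sidecar
#' (\code{metadata.yaml}) records each channel's file, sampling rate,
#' units and length, the timeline, and the ground-truth annotations
#' (artifact masks as run-length segments; clean reference copies and true
#' rate/CO2 traces as additional columns with an annotation role). Numeric
#' values round-trip at full precision.
#'
#' @param recording a [Recording-class]
#' @param dir output directory (created if needed)
#' @return \code{readRecording} returns the reconstructed
#'   [Recording-class]
#' @export
writeRecording <- function(recording, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ann <- recording@annotations
  series <- lapply(recording@channels, function(ch)
    c(ch, list(role = "channel")))
  for (nm in names(ann$cleanChannels)) {
    ref <- recording@channels[[nm]]
    series[[paste0("clean.", nm)]] <-
      list(samples = ann$cleanChannels[[nm]], fs = ref$fs,
           units = ref$units, role = "clean")
  }
  for (nm in intersect(c("trueRR", "truePETCO2"), names(ann))) {
    series[[nm]] <- c(ann[[nm]], list(role = "truth"))
    if (is.null(series[[nm]]$units)) series[[nm]]$units <- ""
  }
  rates <- vapply(series, function(s) s$fs, numeric(1))
  meta <- list(format = "spafnirs-recording-v1", channels = list())
  for (fs in unique(rates)) {
    nms <- names(series)[rates == fs]
    lens <- vapply(nms, function(nm) length(series[[nm]]$samples),
                   integer(1))
    n <- max(lens)
    fileName <- sprintf("series_%gHz.tsv", fs)
    fmt17 <- function(x) ifelse(is.na(x), "NaN", sprintf("%.17g", x))
    cols <- c(list(time = fmt17((seq_len(n) - 1L) / fs)),
              lapply(nms, function(nm) {
                x <- series[[nm]]$samples
                length(x) <- n     # NA padding for shorter channels
                fmt17(x)
              }))
    names(cols) <- c("time", nms)
    data.table::fwrite(data.table::as.data.table(cols),
                       file.path(dir, fileName), sep = "\t",
                       quote = FALSE)
    for (nm in nms)
      meta$channels[[nm]] <- list(file = fileName, fs = fs,
                                  units = series[[nm]]$units,
                                  n = length(series[[nm]]$samples),
                                  role = series[[nm]]$role)
  }
  if (!is.null(recording@timeline))
    writeTimeline(recording@timeline, file.path(dir, "timeline.yaml"))
  extra <- list()
  if (length(ann$trueAmplitudes))
    extra$true_amplitudes <- as.list(ann$trueAmplitudes)
  if (length(ann$artifactMask))
    extra$artifact_mask <- lapply(ann$artifactMask, maskToSegments)
  if (isTRUE(ann$tHbExact)) extra$thb_exact <- TRUE
  meta$annotations <- extra
  yaml::write_yaml(meta, file.path(dir, "metadata.yaml"))
  invisible(dir)
}

#' @rdname writeRecording
#' @param verbose log the number of missing samples per channel
#' @export
readRecording <- function(dir, verbose = FALSE) {
  sidecar <- file.path(dir, "metadata.yaml")
  if (!file.exists(sidecar))
    stop("missing sidecar metadata.yaml in ", dir, call. = FALSE)
  meta <- yaml::read_yaml(sidecar)
  files <- unique(vapply(meta$channels, function(m) m$file, character(1)))
  tables <- lapply(files, function(f) {
    tab <- data.table::fread(file.path(dir, f), sep = "\t", na.strings = "NaN")
    tm <- tab[["time"]]
    if (is.unsorted(tm, strictly = TRUE))
      stop("non-monotone time column in ", f, call. = FALSE)
    described <- c("time", names(meta$channels)[
      vapply(meta$channels, function(m) m$file, character(1)) == f])
    missingDesc <- setdiff(names(tab), described)
    if (length(missingDesc))
      stop("channel column '", missingDesc[1L],
           "' not described in sidecar", call. = FALSE)
    tab
  })
  names(tables) <- files
  channels <- list()
  ann <- list(cleanChannels = list())
  for (nm in names(meta$channels)) {
    m <- meta$channels[[nm]]
    tab <- tables[[m$file]]
    if (!nm %in% names(tab))
      stop("channel '", nm, "' listed in sidecar but absent from ",
           m$file, call. = FALSE)
    x <- as.numeric(tab[[nm]])[seq_len(m$n)]
    nMiss <- sum(is.na(x))
    if (verbose && nMiss)
      message(sprintf("channel %s: %d missing sample(s)", nm, nMiss))
    entry <- list(samples = x, fs = as.numeric(m$fs), units = m$units)
    role <- m$role %||% "channel"
    if (role == "channel") channels[[nm]] <- entry
    else if (role == "clean")
      ann$cleanChannels[[sub("^clean\\.", "", nm)]] <- x
    else ann[[nm]] <- entry
  }
  if (!length(ann$cleanChannels)) ann$cleanChannels <- NULL
  am <- meta$annotations$artifact_mask
  if (length(am)) {
    ann$artifactMask <- lapply(names(am), function(nm)
      segmentsToMask(am[[nm]], length(channels[[nm]]$samples)))
    names(ann$artifactMask) <- names(am)
  }
  if (length(meta$annotations$true_amplitudes))
    ann$trueAmplitudes <- unlist(meta$annotations$true_amplitudes)
  if (isTRUE(meta$annotations$thb_exact)) ann$tHbExact <- TRUE
  tlFile <- file.path(dir, "timeline.yaml")
  tl <- if (file.exists(tlFile)) readTimeline(tlFile) else NULL
  new("Recording", channels = channels, timeline = tl,
      annotations = ann)
}

#' Write a connectivity matrix as labeled delimited text
#'
#' Masked entries are written as empty fields.
#'
#' @param matrixObj a [ConnectivityMatrix-class]
#' @param path output file
#' @export
writeConnectivityMatrix <- function(matrixObj, path) {
  rho <- matrixObj@rho
  rho[!matrixObj@mask & row(rho) != col(rho)] <- NA
  df <- data.table::as.data.table(rho, keep.rownames = "signal")
  data.table::fwrite(df, path, sep = "\t", na = "")
  invisible(path)
}
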