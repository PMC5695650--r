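#' @include utils.R AllClasses.R
NULL

#' Movement-artifact reduction by moving-SD detection and spline subtraction
#'
#' Implements the spline-based movement-artifact reduction scheme for
#' optical signals: (i) samples whose moving standard deviation (centered
#' window of \code{window} seconds) exceeds \code{threshold} times the
#' signal's median moving SD are flagged as artifact segments; (ii) each
#' artifact segment is modeled by a smoothing spline and the model
#' subtracted, which removes both spikes and sudden baseline shifts;
#' (iii) the resulting sub-segments are re-concatenated by constant offset
#' matching at the seams. Non-flagged regions therefore differ from the
#' input only by per-segment constant offsets.
#'
#' @param x numeric signal
#' @param fs sampling rate, Hz
#' @param window moving-SD window, seconds (default 1); must span at least
#'   3 samples
#' @param threshold artifact threshold in multiples of the median moving SD
#'   (default 3)
#' @param splineSmoothing smoothing parameter in [0, 1): the fraction of
#'   the segment's degrees of freedom removed from the smoothing spline
#'   (0 gives a near-interpolating spline, values near 1 a maximally
#'   smooth one); smaller values follow the artifact more faithfully
#'   (default 0.1)
#' @param mergeGap gaps between flagged segments shorter than this many
#'   seconds are merged (default \code{window / 2})
#' @param maxPasses detection and correction are iterated until a pass
#'   flags nothing (at most this many passes), so the procedure is
#'   idempotent on its own output; the reported mask is the union over
#'   passes
#' @return list with \code{corrected} (numeric), and \code{mask}: a list
#'   with \code{flag} (logical vector), \code{segments} (data.frame with
#'   start, end, kind in {"spike", "shift"}), and \code{coverageFraction}
#' @export
maraCorrect <- function(x, fs, window = 1, threshold = 3,
                        splineSmoothing = 0.1, mergeGap = window / 2,
                        maxPasses = 4L) {
  out <- x
  flagAll <- logical(length(x))
  for (pass in seq_len(maxPasses)) {
    res <- maraCorrectOnce(out, fs, window, threshold, splineSmoothing,
                           mergeGap)
    flagAll <- flagAll | res$mask$flag
    out <- res$corrected
    if (res$mask$coverageFraction == 0) break
  }
  runs <- logicalRuns(flagAll)
  kind <- if (nrow(runs)) ifelse((runs[, 2L] - runs[, 1L] + 1L) / fs <=
                                   3 * window, "spike", "shift")
          else character()
  list(corrected = out,
       mask = list(flag = flagAll,
                   segments = data.frame(start = as.integer(runs[, 1L]),
                                         end = as.integer(runs[, 2L]),
                                         kind = kind),
                   coverageFraction = mean(flagAll)))
}

maraCorrectOnce <- function(x, fs, window = 1, threshold = 3,
                            splineSmoothing = 0.1, mergeGap = window / 2) {
  n <- length(x)
  w <- as.integer(round(window * fs))
  stopIfNot(w >= 3L, "window must span at least 3 samples")
  stopIfNot(threshold > 0, "threshold must be > 0")
  msd <- movingSD(x, w)
  ref <- median(msd)
  flag <- msd > threshold * ref
  if (!any(flag)) {
    return(list(corrected = x,
                mask = list(flag = flag,
                            segments = data.frame(start = integer(),
                                                  end = integer(),
                                                  kind = character()),
                            coverageFraction = 0)))
  }
  if (all(flag)) stop("no clean reference segment", call. = FALSE)
  # expand each detection by half a window of context (the moving SD
  # smears artifact onsets), then merge segments separated by short gaps
  runs <- logicalRuns(flag)
  e <- w %/% 2L
  runs[, 1L] <- pmax(runs[, 1L] - e, 1L)
  runs[, 2L] <- pmin(runs[, 2L] + e, n)
  flag <- logical(n)
  for (i in seq_len(nrow(runs))) flag[runs[i, 1L]:runs[i, 2L]] <- TRUE
  if (all(flag)) stop("no clean reference segment", call. = FALSE)
  runs <- logicalRuns(flag)
  if (nrow(runs) > 1L) {
    gap <- as.integer(round(mergeGap * fs))
    keep <- runs[1L, , drop = FALSE]
    for (i in 2:nrow(runs)) {
      if (runs[i, "start"] - keep[nrow(keep), "end"] - 1L <= gap)
        keep[nrow(keep), "end"] <- runs[i, "end"]
      else keep <- rbind(keep, runs[i, , drop = FALSE])
    }
    runs <- keep
    flag <- logical(n)
    for (i in seq_len(nrow(runs))) flag[runs[i, 1L]:runs[i, 2L]] <- TRUE
    if (all(flag)) stop("no clean reference segment", call. = FALSE)
  }
  y <- x
  for (i in seq_len(nrow(runs))) {
    a <- runs[i, 1L]; b <- runs[i, 2L]
    idx <- a:b
    seg <- x[idx]
    model <- if (length(idx) < 8L) seg else {
      df <- max(4, round(length(seg) * (1 - splineSmoothing)))
      fit <- smooth.spline(seq_along(seg), seg, df = min(df, length(seg)))
      predict(fit, seq_along(seg))$y
    }
    y[idx] <- seg - model + mean(model)
  }
  # re-concatenate by constant offset matching at the seams
  bounds <- sort(unique(c(1L, runs[, 1L], runs[, 2L] + 1L, n + 1L)))
  bounds <- bounds[bounds <= n + 1L]
  k <- max(2L, as.integer(round(window * fs / 2)))
  out <- y
  for (i in 2:(length(bounds) - 1L)) {
    a <- bounds[i]; b <- bounds[i + 1L] - 1L
    prevEnd <- a - 1L
    prevIdx <- max(bounds[i - 1L], prevEnd - k + 1L):prevEnd
    curIdx <- a:min(b, a + k - 1L)
    offset <- mean(out[prevIdx]) - mean(out[curIdx])
    out[a:b] <- out[a:b] + offset
  }
  kind <- ifelse((runs[, 2L] - runs[, 1L] + 1L) / fs <= 3 * window,
                 "spike", "shift")
  cover <- sum(flag) / n
  list(corrected = out,
       mask = list(flag = flag,
                   segments = data.frame(start = runs[, 1L],
                                         end = runs[, 2L], kind = kind),
                   coverageFraction = cover))
}

#' Grid-search helper for artifact-correction parameters
#'
#' Scores each parameter combination by the reduction of the corrected
#' signal's upper-tail moving SD (95th percentile) relative to the input,
#' and returns the best-scoring combination. This automates the otherwise
#' manual per-signal parameter choice.
#'
#' @param x numeric signal
#' @param fs sampling rate, Hz
#' @param windows candidate windows, seconds
#' @param thresholds candidate thresholds
#' @param spars candidate spline smoothing values
#' @return list with \code{window}, \code{threshold}, \code{splineSmoothing}
#'   and the score table
#' @export
maraAutoTune <- function(x, fs, windows = c(0.5, 1, 2),
                         thresholds = c(2, 3, 4), spars = c(0.2, 0.3, 0.5)) {
  grid <- expand.grid(window = windows, threshold = thresholds,
                      spar = spars)
  base <- quantile(movingSD(x, max(3, round(min(windows) * fs))), 0.95)
  grid$score <- vapply(seq_len(nrow(grid)), function(i) {
    res <- tryCatch(
      maraCorrect(x, fs, grid$window[i], grid$threshold[i], grid$spar[i]),
      error = function(e) NULL)
    if (is.null(res)) return(Inf)
    quantile(movingSD(res$corrected,
                      max(3, round(grid$window[i] * fs))), 0.95) / base
  }, numeric(1))
  best <- grid[which.min(grid$score), ]
  list(window = best$window, threshold = best$threshold,
       splineSmoothing = best$spar, grid = grid)
}

# direct-form IIR filter with zero initial conditions (compiled)
applyIIR <- function(b, a, x) iirFilterCpp(b, a, x)

# zero-phase Butterworth low-pass (forward-backward pass) with
# endpoint-matched detrending to suppress edge transients
iirLowpass <- function(x, fs, cutoff, order = 6L) {
  n <- length(x)
  trend <- x[1L] + (x[n] - x[1L]) * (seq_len(n) - 1L) / (n - 1L)
  bf <- signal::butter(order, min(cutoff / (fs / 2), 0.99), type = "low")
  xd <- x - trend
  y <- applyIIR(bf$b, bf$a, xd)
  y <- rev(applyIIR(bf$b, bf$a, rev(y)))
  y + trend
}

#' Resample a signal with anti-aliasing
#'
#' For downsampling, a zero-phase Butterworth low-pass with cutoff below
#' half the target rate precedes interpolation onto the new grid; rate
#' reductions beyond 5x are done in cascaded stages to keep the filter
#' well-conditioned. Upsampling uses linear interpolation only. The output
#' grid is \code{t = 0, 1/fsOut, ...} up to the input duration, so the
#' output length is \code{floor((n - 1) * fsOut / fsIn) + 1}. Missing (NA)
#' input samples are bridged before filtering and re-flagged NA on the
#' output grid.
#'
#' @param x numeric signal (NA marks missing)
#' @param fsIn input sampling rate, Hz
#' @param fsOut output sampling rate, Hz
#' @param cutoffFraction anti-alias cutoff as a fraction of the output
#'   Nyquist rate (default 0.9)
#' @return numeric vector on the \code{fsOut} grid
#' @export
resampleSignal <- function(x, fsIn, fsOut, cutoffFraction = 0.9) {
  stopIfNot(fsIn > 0 && fsOut > 0, "sampling rates must be positive")
  n <- length(x)
  if (fsIn == fsOut) return(x)
  nas <- is.na(x)
  tIn <- (seq_len(n) - 1L) / fsIn
  if (any(nas)) {
    tOut <- seq(0, tIn[n], by = 1 / fsOut)
    if (all(nas)) return(rep(NA_real_, length(tOut)))
    x <- approx(tIn[!nas], x[!nas], xout = tIn, rule = 2)$y
  }
  if (fsOut < fsIn) {
    # extreme reductions are cascaded to keep the filter well-conditioned
    if (fsIn / fsOut > 40) {
      mid <- fsOut * 8
      x <- resampleSignal(x, fsIn, mid, cutoffFraction)
      y <- resampleSignal(x, mid, fsOut, cutoffFraction)
    } else {
      x <- iirLowpass(x, fsIn, cutoffFraction * fsOut / 2)
      q <- fsIn / fsOut
      if (abs(q - round(q)) < 1e-9) {
        y <- x[seq(1L, n, by = as.integer(round(q)))]
      } else {
        tOut <- seq(0, tIn[n], by = 1 / fsOut)
        y <- approx(tIn, x, xout = tOut)$y
      }
    }
  } else {
    tOut <- seq(0, tIn[n], by = 1 / fsOut)
    y <- approx(tIn, x, xout = tOut)$y
  }
  if (any(nas)) {
    tOut <- seq(0, tIn[n], by = 1 / fsOut)
    nearestNA <- approx(tIn, as.numeric(nas), xout = tOut)$y
    y <- y[seq_along(tOut)]
    y[nearestNA > 0.5] <- NA_real_
  }
  y
}

#' Centered moving average with shrinking edge windows
#'
#' The window is the nearest odd integer to \code{span * fs} samples (2.4 s
#' at 2 Hz gives 4.8, rounded to 5 for symmetry). Edges use shrinking
#' centered windows, so the output has the input's length. NA samples are
#' excluded from window means and stay NA in the output.
#'
#' @param x numeric signal
#' @param fs sampling rate, Hz
#' @param span window span, seconds (default 2.4)
#' @return smoothed signal, same length
#' @export
movingAverage <- function(x, fs, span = 2.4) {
  w <- round(span * fs)
  stopIfNot(w >= 1, "span * fs must be at least 1 sample")
  if (w %% 2 == 0) w <- w + if (abs(span * fs - (w - 1)) < abs(span * fs - (w + 1))) -1L else 1L
  w <- max(1L, w)
  half <- (w - 1L) %/% 2L
  n <- length(x)
  nas <- is.na(x)
  x0 <- ifelse(nas, 0, x)
  cs <- cumsum(c(0, x0))
  cnt <- cumsum(c(0, !nas))
  i <- seq_len(n)
  lo <- pmax(i - half, 1L)
  hi <- pmin(i + half, n)
  m <- cnt[hi + 1L] - cnt[lo]
  y <- (cs[hi + 1L] - cs[lo]) / m
  y[m == 0] <- NA_real_
  y[nas] <- NA_real_
  y
}

#' Robust local quadratic regression smoothing
#'
#' Locally weighted (tricube) quadratic least-squares fit over a
#' \code{bin}-sample neighborhood, iteratively reweighted with bisquare
#' robust weights, i.e. the classical robust LOESS smoother with a fixed
#' sample bin. A noiseless quadratic is reproduced exactly; isolated
#' outliers are strongly attenuated.
#'
#' @param x numeric signal (NA marks missing; excluded from fits and kept
#'   NA)
#' @param bin neighborhood size in samples (default 20)
#' @param degree local polynomial degree (default 2)
#' @return smoothed signal, same length
#' @export
rloessSmooth <- function(x, bin = 20, degree = 2) {
  n <- length(x)
  ok <- !is.na(x)
  m <- sum(ok)
  stopIfNot(bin >= degree + 2, "bin must be at least degree + 2")
  if (m < bin) stop("signal shorter than the smoothing bin", call. = FALSE)
  if (diff(range(x, na.rm = TRUE)) == 0) return(x)  # constant: nothing to fit
  t <- seq_len(n)
  ctrl <- stats::loess.control(
    surface = if (m <= 600) "direct" else "interpolate")
  # explicit bisquare reweighting so that degenerate residual spreads
  # (e.g. an isolated outlier on an otherwise exact fit) are handled
  rw <- rep(1, m)
  tm <- t[ok]; xm <- x[ok]
  fit <- NULL
  for (it in 1:4) {
    # locally constant stretches make individual fits ill-conditioned;
    # loess falls back to a pseudoinverse there, which is fine for a
    # smoother, so its conditioning warnings are muted
    fit <- suppressWarnings(
      stats::loess(xm ~ tm, span = bin / m, degree = degree,
                   weights = rw, family = "gaussian", control = ctrl))
    r <- stats::residuals(fit)
    s <- 6 * median(abs(r))
    if (s == 0) s <- 6 * mean(abs(r))
    if (s == 0) break
    u <- pmin(abs(r) / s, 1)
    rw <- (1 - u^2)^2
    if (all(rw == 0)) { rw <- rep(1, m); break }
  }
  y <- rep(NA_real_, n)
  y[ok] <- stats::fitted(fit)
  y
}

#' Detect breath peaks in a capnogram
#'
#' Prominence-based local-maximum detector with a refractory period:
#' candidate local maxima must rise at least \code{minProminence} above the
#' higher of the two flanking valleys (relative to the signal's robust
#' amplitude), and accepted peaks are at least \code{refractory} seconds
#' apart (greedy by height).
#'
#' @param x numeric signal
#' @param fs sampling rate, Hz
#' @param minProminence minimal prominence as a fraction of the robust
#'   (5th-95th percentile) signal amplitude (default 0.1)
#' @param refractory minimal peak separation, seconds (default 1.5, i.e. a
#'   40 breaths/min ceiling)
#' @return integer vector of peak sample indices, increasing
#' @export
findBreathPeaks <- function(x, fs, minProminence = 0.3, refractory = 1.5) {
  n <- length(x)
  if (n < 3L) return(integer())
  dx <- diff(x)
  cand <- which(dx[-length(dx)] > 0 & dx[-1L] <= 0) + 1L
  if (!length(cand)) return(integer())
  rng <- quantile(x, c(0.05, 0.95), na.rm = TRUE)
  amp <- diff(rng)
  if (amp <= 0) return(integer())
  minProm <- minProminence * amp
  # height prefilter keeps candidates that could possibly be prominent
  cand <- cand[x[cand] >= rng[1L] + minProm]
  if (!length(cand)) return(integer())
  # greedy refractory acceptance by height
  refr <- refractory * fs
  ord <- cand[order(x[cand], decreasing = TRUE)]
  accepted <- integer()
  for (p in ord)
    if (!length(accepted) || all(abs(accepted - p) >= refr))
      accepted <- c(accepted, p)
  accepted <- sort(accepted)
  # prominence check on the accepted peaks only
  prom <- vapply(accepted, function(p) {
    h <- x[p]
    left <- x[seq_len(p - 1L)]
    hlL <- which(left > h)
    lo1 <- if (length(hlL) && max(hlL) < p - 1L)
      min(x[(max(hlL) + 1L):(p - 1L)])
    else if (length(hlL)) h else min(left)
    right <- x[(p + 1L):n]
    hlR <- which(right > h)
    lo2 <- if (length(hlR) && min(hlR) > 1L)
      min(x[(p + 1L):(p + min(hlR) - 1L)])
    else if (length(hlR)) h else min(right)
    h - max(lo1, lo2)
  }, numeric(1))
  accepted[prom >= minProm]
}

#' End-tidal CO2 from a capnogram
#'
#' Computes the upper envelope through the per-breath maxima (end-tidal
#' plateaus), interpolates it onto the 2-Hz analysis grid and applies
#' [rloessSmooth()]. The envelope is taken on the native-rate capnogram;
#' low-pass resampling of the waveform itself would bias the plateaus
#' through the anti-alias filter.
#'
#' @param x capnogram samples
#' @param fs capnogram sampling rate, Hz
#' @param fsOut output rate, Hz (default 2)
#' @param smooth apply the robust smoother (default TRUE)
#' @return PETCO2 series on the \code{fsOut} grid, mmHg
#' @export
extractPetco2 <- function(x, fs, fsOut = 2, smooth = TRUE) {
  peaks <- findBreathPeaks(x, fs)
  if (length(peaks) < 2L)
    stop("no detectable breaths in capnogram", call. = FALSE)
  tPeak <- (peaks - 1L) / fs
  tOut <- seq(0, (length(x) - 1L) / fs, by = 1 / fsOut)
  env <- approx(tPeak, x[peaks], xout = tOut, rule = 2)$y
  if (smooth && length(env) >= 20L) env <- rloessSmooth(env, bin = 20)
  env
}

#' Respiratory rate from a capnogram
#'
#' Detects the maximum of every breath ([findBreathPeaks()]), converts the
#' time differences between successive peaks to instantaneous rates
#' (60 / dT, breaths/min) assigned at the inter-peak midpoints, and
#' resamples onto the 2-Hz grid by a monotone (shape-preserving) piecewise
#' cubic Hermite interpolating polynomial, so the interpolant never
#' overshoots the data range. Outside the observed midpoints the nearest
#' rate is held constant.
#'
#' @param x capnogram samples
#' @param fs capnogram sampling rate, Hz
#' @param fsOut output rate, Hz (default 2)
#' @return RR series on the \code{fsOut} grid, breaths/min
#' @export
extractRR <- function(x, fs, fsOut = 2) {
  peaks <- findBreathPeaks(x, fs)
  if (length(peaks) < 3L)
    stop("fewer than 3 breaths detected", call. = FALSE)
  tPeak <- (peaks - 1L) / fs
  dT <- diff(tPeak)
  rr <- 60 / dT
  mid <- tPeak[-length(tPeak)] + dT / 2
  tOut <- seq(0, (length(x) - 1L) / fs, by = 1 / fsOut)
  f <- splinefun(mid, rr, method = "monoH.FC")
  y <- f(pmin(pmax(tOut, mid[1L]), mid[length(mid)]))
  y
}

#' Elementwise derived cardiovascular indices
#'
#' Computes the pulse-respiration quotient \code{PRQ = HR / RR}, the
#' cardiac-output proxy \code{Q = (PP * HR) / (SBP + DBP)} and the
#' heart-rate-variability band-power ratio \code{LFHF = LF / HF}. All
#' inputs must share one (2-Hz) grid. Samples with zero or negative RR,
#' HF or SBP+DBP are flagged missing (NA), not silently dropped.
#'
#' @param HR heart rate, bpm
#' @param RR respiratory rate, breaths/min
#' @param PP pulse pressure, mmHg
#' @param SBP,DBP systolic and diastolic pressure, mmHg
#' @param LF,HF HRV band powers
#' @return list with numeric series \code{PRQ}, \code{Q}, \code{LFHF} and
#'   \code{nFlagged}, the count of newly flagged samples
#' @export
computeDerived <- function(HR, RR, PP, SBP, DBP, LF, HF) {
  lens <- c(length(HR), length(RR), length(PP), length(SBP), length(DBP),
            length(LF), length(HF))
  stopIfNot(length(unique(lens)) == 1L,
            "all series must be on a common grid")
  badRR <- !is.na(RR) & RR <= 0
  badHF <- !is.na(HF) & HF <= 0
  badBP <- !is.na(SBP) & !is.na(DBP) & (SBP + DBP) <= 0
  RR[badRR] <- NA; HF[badHF] <- NA
  sum_bp <- SBP + DBP
  sum_bp[badBP] <- NA
  list(PRQ = HR / RR,
       Q = (PP * HR) / sum_bp,
       LFHF = LF / HF,
       nFlagged = sum(badRR) + sum(badHF) + sum(badBP))
}

#' Mayer-wave amplitude of a signal
#'
#' Band-passes the signal to the Mayer band, takes the instantaneous
#' amplitude via the analytic-signal (Hilbert) envelope, and low-passes the
#' envelope. Output is in the channel's units.
#'
#' @param x signal on a regular grid
#' @param fs sampling rate, Hz (default 2)
#' @param band Mayer band edges, Hz (default c(0.07, 0.13))
#' @param envelopeCutoff low-pass cutoff for the envelope, Hz
#' @return amplitude series, same length as \code{x}
#' @export
computeMWA <- function(x, fs = 2, band = c(0.07, 0.13),
                       envelopeCutoff = 0.03) {
  stopIfNot(band[1L] > 0 && band[2L] < fs / 2 && band[1L] < band[2L],
            "band must lie inside (0, fs/2)")
  nas <- is.na(x)
  if (any(nas)) {
    t <- seq_along(x)
    x <- approx(t[!nas], x[!nas], xout = t, rule = 2)$y
  }
  filtfilt0 <- function(bf, v)
    rev(applyIIR(bf$b, bf$a, rev(applyIIR(bf$b, bf$a, v))))
  bf <- signal::butter(3, band / (fs / 2), type = "pass")
  xb <- filtfilt0(bf, x - mean(x))
  env <- hilbertEnvelope(xb)
  lf <- signal::butter(2, envelopeCutoff / (fs / 2), type = "low")
  out <- filtfilt0(lf, env)
  out[nas] <- NA_real_
  out
}

# fNIRS channel labels of a recording
fnirsChannels <- function(recording)
  grep("^(O2Hb|HHb|tHb|StO2)_", channelNames(recording), value = TRUE)

#' Default preprocessing parameters
#'
#' @return a named list of per-stage parameters (see [preprocessRecording()])
#' @export
preprocessDefaults <- function() {
  list(mara = list(enabled = TRUE, window = 1, threshold = 3,
                   splineSmoothing = 0.1),
       fsTarget = 2,
       maSpan = 2.4,
       rloessBin = 20,
       mwaBand = c(0.07, 0.13),
       mwaSource = "O2Hb",
       mwaLocations = c("LPFC", "RPFC"))
}

#' Preprocess a raw recording onto the 2-Hz analysis grid
#'
#' Runs the full preprocessing chain: artifact correction
#' ([maraCorrect()]), anti-aliased downsampling and moving-average
#' smoothing of the fNIRS channels; capnogram-derived PETCO2 and
#' respiratory rate; robust local-regression smoothing of the systemic
#' channels (skin conductance is only resampled); and the derived indices
#' PRQ, Q, LF/HF and the per-location Mayer-wave amplitude (computed from
#' the resampled O2Hb channel before moving-average smoothing, which would
#' attenuate the Mayer band).
#'
#' @param recording a raw [Recording-class]
#' @param params parameter list as from [preprocessDefaults()]
#' @param channels optional subset of channel labels to process (derived
#'   channels are added when their inputs are present)
#' @param verbose print one status line per stage
#' @return a [Recording-class] on the common 2-Hz grid; artifact masks are
#'   stored in \code{annotations(x)$maraMasks}
#' @export
preprocessRecording <- function(recording, params = preprocessDefaults(),
                                channels = NULL, verbose = FALSE) {
  fsT <- params$fsTarget
  inChannels <- channelNames(recording)
  if (is.null(channels)) channels <- inChannels
  out <- list()
  masks <- list()
  logLine <- function(...) if (verbose) message(sprintf(...))
  ## fNIRS branch
  for (nm in intersect(fnirsChannels(recording), channels)) {
    ch <- recording@channels[[nm]]
    x <- ch$samples
    if (isTRUE(params$mara$enabled)) {
      mc <- maraCorrect(x, ch$fs, params$mara$window,
                        params$mara$threshold,
                        params$mara$splineSmoothing)
      x <- mc$corrected
      masks[[nm]] <- mc$mask
      logLine("mara %s: coverage %.2f%%", nm,
              100 * mc$mask$coverageFraction)
    }
    x <- resampleSignal(x, ch$fs, fsT)
    xr <- x                       # pre-smoothing copy for the Mayer band
    x <- movingAverage(x, fsT, params$maSpan)
    out[[nm]] <- list(samples = x, fs = fsT, units = ch$units)
    attr(out[[nm]], "resampledOnly") <- xr
  }
  ## Mayer-wave amplitude from the resampled O2Hb channels
  for (loc in params$mwaLocations) {
    src <- paste0(params$mwaSource, "_", loc)
    if (!is.null(out[[src]])) {
      xr <- attr(out[[src]], "resampledOnly")
      out[[paste0("MWA_", loc)]] <-
        list(samples = computeMWA(xr, fsT, params$mwaBand),
             fs = fsT, units = out[[src]]$units)
    }
  }
  for (nm in names(out)) attr(out[[nm]], "resampledOnly") <- NULL
  ## capnogram branch
  if ("capno" %in% intersect(inChannels, channels)) {
    ch <- recording@channels[["capno"]]
    out[["PETCO2"]] <- list(samples = extractPetco2(ch$samples, ch$fs, fsT),
                            fs = fsT, units = "mmHg")
    out[["RR"]] <- list(samples = extractRR(ch$samples, ch$fs, fsT),
                        fs = fsT, units = "breaths/min")
    logLine("capnogram: %d PETCO2 samples", length(out[["PETCO2"]]$samples))
  }
  ## systemic branch: resample, then robust smoothing (except SCL)
  systemicIn <- intersect(c("HR", "MAP", "SBP", "DBP", "PP", "PTT",
                            "HF", "LF", "SCL"), intersect(inChannels, channels))
  for (nm in systemicIn) {
    ch <- recording@channels[[nm]]
    x <- resampleSignal(ch$samples, ch$fs, fsT)
    if (nm != "SCL" && sum(!is.na(x)) >= params$rloessBin)
      x <- rloessSmooth(x, params$rloessBin)
    out[[nm]] <- list(samples = x, fs = fsT, units = ch$units)
  }
  ## derived indices
  need <- c("HR", "RR", "PP", "SBP", "DBP", "LF", "HF")
  if (all(need %in% names(out))) {
    len <- min(vapply(out[need], function(c1) length(c1$samples), integer(1)))
    g <- lapply(out[need], function(c1) c1$samples[seq_len(len)])
    d <- computeDerived(g$HR, g$RR, g$PP, g$SBP, g$DBP, g$LF, g$HF)
    out[["PRQ"]] <- list(samples = d$PRQ, fs = fsT, units = "")
    out[["Q"]] <- list(samples = d$Q, fs = fsT, units = "mmHg*bpm/mmHg")
    out[["LFHF"]] <- list(samples = d$LFHF, fs = fsT, units = "")
    logLine("derived: %d flagged samples", d$nFlagged)
  }
  ## common length
  len <- min(vapply(out, function(c1) length(c1$samples), integer(1)))
  for (nm in names(out)) out[[nm]]$samples <- out[[nm]]$samples[seq_len(len)]
  ann <- recording@annotations
  ann$maraMasks <- masks
  ann$tHbExact <- NULL
  new("Recording", channels = out, timeline = recording@timeline,
      annotations = ann)
}
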