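#' @include AllClasses.R stats-tests.R
NULL

# Seven 3-s analysis intervals in seconds from segment start (closed).
intervalStarts <- c(1, 6, 11, 16, 21, 26, 31)
intervalEnds <- intervalStarts + 3
# the stimulus (on at 5 s, off at 25 s) is covered by intervals 2..5
stimulusIntervals <- 2:5

#' Cut a preprocessed recording into stimulus-locked trial segments
#'
#' One segment per light-on block, spanning [onset - 5 s, onset + 30 s) on
#' the 2-Hz grid (70 samples per signal).
#'
#' @param recording a preprocessed [Recording-class] (all channels on one
#'   grid)
#' @param timelineObj timeline to use (default: the recording's)
#' @param signals channel labels to include (default: all)
#' @return list of [TrialBlock-class], one per block
#' @export
segmentTrials <- function(recording, timelineObj = NULL, signals = NULL) {
  if (is.null(timelineObj)) timelineObj <- timeline(recording)
  stopIfNot(!is.null(timelineObj), "no timeline available")
  if (is.null(signals)) signals <- channelNames(recording)
  fs <- channelRate(recording, signals[1L])
  for (nm in signals)
    stopIfNot(channelRate(recording, nm) == fs,
              "all signals must share one sampling rate")
  nSamp <- as.integer(round(35 * fs))
  len <- min(vapply(signals,
                    function(nm) length(channelSamples(recording, nm)),
                    integer(1)))
  mat <- do.call(rbind, lapply(signals, function(nm)
    channelSamples(recording, nm)[seq_len(len)]))
  rownames(mat) <- signals
  onsets <- blockOnsets(timelineObj)
  lapply(seq_along(onsets), function(k) {
    i0 <- as.integer(round((onsets[k] - 5) * fs)) + 1L
    i1 <- i0 + nSamp - 1L
    if (i0 < 1L || i1 > len)
      stop(sprintf("block %d window [%g, %g) exceeds recording bounds",
                   k, onsets[k] - 5, onsets[k] + 30), call. = FALSE)
    new("TrialBlock", segment = mat[, i0:i1, drop = FALSE],
        onsetTime = onsets[k], fs = fs)
  })
}

# sample indices (columns) whose times fall in closed interval [lo, hi]
intervalColumns <- function(fs, lo, hi) {
  t <- (seq_len(as.integer(round(35 * fs))) - 1L) / fs
  which(t >= lo - 1e-9 & t <= hi + 1e-9)
}

#' Normalize a trial to its baseline and remove a linear trend
#'
#' Per signal, the median of the 1-4 s interval (the pre-stimulus baseline)
#' is subtracted, then the line through the first- and last-interval
#' anchor points (interval medians at their centers, 2.5 s and 32.5 s) is
#' removed, so that any affine function of time maps to the zero block and
#' the evoked response between the anchors is not attenuated. The
#' alternative \code{mode = "ls"} subtracts the full-segment least-squares
#' line instead. Signals whose baseline interval is entirely missing are
#' flagged unusable (all-NA) for this trial.
#'
#' @param block a [TrialBlock-class]
#' @param mode "anchor" (default) or "ls"
#' @return the normalized [TrialBlock-class]
#' @export
normalizeDetrend <- function(block, mode = c("anchor", "ls")) {
  mode <- match.arg(mode)
  fs <- block@fs
  seg <- block@segment
  t <- (seq_len(ncol(seg)) - 1L) / fs
  c1 <- intervalColumns(fs, intervalStarts[1L], intervalEnds[1L])
  c7 <- intervalColumns(fs, intervalStarts[7L], intervalEnds[7L])
  ref <- numeric(nrow(seg))
  names(ref) <- rownames(seg)
  out <- seg
  for (i in seq_len(nrow(seg))) {
    x <- seg[i, ]
    m1 <- medianNA(x[c1])
    if (is.na(m1)) {          # unusable: baseline interval fully missing
      out[i, ] <- NA_real_
      ref[i] <- NA_real_
      next
    }
    ref[i] <- m1
    if (mode == "anchor") {
      m7 <- medianNA(x[c7])
      slope <- if (is.na(m7)) 0 else (m7 - m1) / (mean(t[c7]) - mean(t[c1]))
      y <- x - m1 - slope * (t - mean(t[c1]))
      # re-center so the baseline-interval median is exactly zero
      out[i, ] <- y - medianNA(y[c1])
    } else {
      ok <- !is.na(x)
      co <- stats::coef(stats::lm.fit(cbind(1, t[ok]), x[ok]))
      y <- x - co[1L] - co[2L] * t
      out[i, ] <- y - medianNA(y[c1])
    }
  }
  new("TrialBlock", segment = out, onsetTime = block@onsetTime, fs = fs,
      baselineRef = ref, normalized = TRUE)
}

#' Interval medians of a trial segment
#'
#' Median of the samples whose times fall in each of the seven closed 3-s
#' intervals, per signal. Missing samples are excluded; an interval with no
#' usable samples yields NA.
#'
#' @param block a (normalized) [TrialBlock-class]
#' @return the block with its \code{intervalMedians} slot filled
#'   (signals x 7)
#' @export
intervalMedians <- function(block) {
  seg <- block@segment
  med <- matrix(NA_real_, nrow(seg), 7L,
                dimnames = list(rownames(seg), NULL))
  for (j in 1:7) {
    cols <- intervalColumns(block@fs, intervalStarts[j], intervalEnds[j])
    med[, j] <- rowMediansCpp(seg[, cols, drop = FALSE])
  }
  initialize(block, intervalMedians = med)
}

#' Subject-level significance gate
#'
#' For each signal and each of the four stimulus intervals (6-24 s), the
#' across-trial interval medians are tested against a zero median by the
#' exact Wilcoxon signed-rank test; Benjamini-Hochberg FDR correction is
#' applied across the chosen family. A signal is significant (h = 1) when
#' any of its stimulus intervals survives, and its gate weight equals h, so
#' nonsignificant subject-level block averages are weighted by zero in the
#' group model. The block average is the across-trial median of the seven
#' interval medians.
#'
#' @param blocks list of normalized [TrialBlock-class] (>= 5 trials)
#' @param alpha FDR level (default 0.05)
#' @param family FDR family: \code{"signals_x_intervals"} (default, one
#'   family spanning all signals and stimulus intervals) or
#'   \code{"per_signal"}
#' @param covariates list with color, age, gender for the group model
#' @param subjectId subject identifier
#' @return a [SubjectResult-class]
#' @export
subjectLevelGate <- function(blocks, alpha = 0.05,
                             family = c("signals_x_intervals", "per_signal"),
                             covariates = list(color = NA_character_,
                                               age = NA_real_,
                                               gender = NA_character_),
                             subjectId = "S01") {
  family <- match.arg(family)
  stopIfNot(length(blocks) >= 5L, "at least 5 trials are required")
  blocks <- lapply(blocks, function(b) {
    stopIfNot(b@normalized, "blocks must be normalized first")
    if (!ncol(b@intervalMedians)) intervalMedians(b) else b
  })
  sigs <- rownames(blocks[[1L]]@segment)
  nT <- length(blocks)
  # trials x 7 per signal
  med <- array(NA_real_, c(length(sigs), nT, 7L),
               dimnames = list(sigs, NULL, NULL))
  for (k in seq_len(nT)) med[, k, ] <- blocks[[k]]@intervalMedians
  pv <- matrix(NA_real_, length(sigs), 4L,
               dimnames = list(sigs, paste0("int", stimulusIntervals)))
  for (s in seq_along(sigs)) {
    for (j in seq_along(stimulusIntervals)) {
      v <- med[s, , stimulusIntervals[j]]
      v <- v[!is.na(v)]
      pv[s, j] <- if (length(v)) wilcoxonSignedRank(v) else NA_real_
    }
  }
  rej <- matrix(FALSE, length(sigs), 4L)
  if (family == "signals_x_intervals") {
    rej[] <- fdrBH(as.vector(pv), alpha)
  } else {
    for (s in seq_along(sigs)) rej[s, ] <- fdrBH(pv[s, ], alpha)
  }
  h <- apply(rej, 1L, any)
  names(h) <- sigs
  ba <- apply(med, c(1L, 3L), medianNA)
  new("SubjectResult", blockAverage = ba, pvals = pv, h = h,
      weight = stats::setNames(as.numeric(h), sigs),
      covariates = covariates, subjectId = subjectId)
}

# scalar group-level response per subject result x signal: the median of
# the four stimulus-interval block-average medians
stimulusResponse <- function(result, signal) {
  medianNA(result@blockAverage[signal, stimulusIntervals])
}

# assemble the observation table for the group model
groupObservations <- function(results, signals,
                              zeroWeight = c("zero", "exclude")) {
  zeroWeight <- match.arg(zeroWeight)
  rows <- list()
  for (res in results) {
    for (sg in intersect(signals, rownames(res@blockAverage))) {
      y <- stimulusResponse(res, sg)
      w <- res@weight[[sg]]
      if (is.na(y)) next
      rows[[length(rows) + 1L]] <-
        data.frame(subject = res@subjectId, signal = sg, y = y, w = w,
                   color = res@covariates$color, age = res@covariates$age,
                   gender = res@covariates$gender,
                   stringsAsFactors = FALSE)
    }
  }
  obs <- do.call(rbind, rows)
  if (is.null(obs)) return(NULL)
  if (zeroWeight == "zero") obs$y <- obs$y * obs$w
  else obs <- obs[obs$w > 0, , drop = FALSE]
  obs
}

buildDesign <- function(obs, terms, referenceColor) {
  X <- matrix(1, nrow(obs), 1L, dimnames = list(NULL, "(Intercept)"))
  if ("color" %in% terms) {
    cols <- setdiff(c("red", "green", "blue"), referenceColor)
    cols <- cols[cols %in% obs$color]
    if (length(unique(obs$color)) < 2L)
      stop("degenerate design for term 'color': a single color is present",
           call. = FALSE)
    for (cc in cols) {
      X <- cbind(X, as.numeric(obs$color == cc))
      colnames(X)[ncol(X)] <- paste0("color", cc)
    }
  }
  if ("age" %in% terms) {
    stopIfNot(all(is.finite(obs$age)), "age covariate missing")
    X <- cbind(X, age = obs$age)
  }
  if ("gender" %in% terms) {
    if (length(unique(obs$gender)) < 2L)
      stop("degenerate design for term 'gender': a single level is present",
           call. = FALSE)
    X <- cbind(X, genderMale = as.numeric(obs$gender == "male"))
  }
  X
}

#' Group-level quantile regression with subject bootstrap
#'
#' Median (or general tau) regression of the gated subject-level stimulus
#' responses on an intercept plus optional color contrasts (reference level
#' "red", so the blue coefficient is the direct blue-vs-red contrast), age
#' and gender. Left/right channels of a region are pooled as separate
#' observations of the same subject. Subject-level responses that did not
#' pass the significance gate enter weighted by zero (default) or are
#' excluded (\code{zeroWeight = "exclude"}). Confidence intervals are
#' percentile bootstrap over subjects resampled with replacement (the
#' subject is the sampling unit; all their pooled observations move
#' together). A term is significant when its CI excludes 0. With fewer
#' than two gated subjects the model is declared indeterminate.
#'
#' @param results list of [SubjectResult-class]
#' @param signals channel labels to pool (e.g.
#'   \code{c("O2Hb_LVC", "O2Hb_RVC")})
#' @param terms model terms besides the intercept: any of "color", "age",
#'   "gender" (default none: intercept-only stimulus-effect model)
#' @param tau quantile (default 0.5)
#' @param nBoot bootstrap draws (default 2000)
#' @param seed integer seed for the bootstrap
#' @param level confidence level (default 0.95)
#' @param referenceColor reference level for color contrasts (default
#'   "red")
#' @param zeroWeight "zero" (default) or "exclude"
#' @param bootSmooth use the smoothed bootstrap (kernel bandwidth
#'   \code{sd(residuals)/sqrt(nSubjects)} added to resampled responses);
#'   corrects percentile-interval undercoverage for quantiles at small n
#'   (default TRUE)
#' @return a [GroupModel-class]
#' @export
groupQuantileRegression <- function(results, signals, terms = character(),
                                    tau = 0.5, nBoot = 2000L, seed = 1L,
                                    level = 0.95, referenceColor = "red",
                                    zeroWeight = c("zero", "exclude"),
                                    bootSmooth = TRUE) {
  zeroWeight <- match.arg(zeroWeight)
  obs <- groupObservations(results, signals, zeroWeight)
  gated <- if (is.null(obs)) character() else unique(obs$subject[obs$w > 0])
  if (length(gated) < 2L) {
    return(new("GroupModel", coefficients = numeric(),
               ci = matrix(numeric(), 2, 0), nBoot = 0, tau = tau,
               terms = character(), significant = logical(),
               indeterminate = TRUE, nGated = length(gated)))
  }
  X <- buildDesign(obs, terms, referenceColor)
  est <- fitQuantile(X, obs$y, tau)
  subjects <- unique(obs$subject)
  bySubj <- split(seq_len(nrow(obs)), obs$subject)[subjects]
  interceptOnly <- ncol(X) == 1L
  sizes <- lengths(bySubj)
  nS <- length(subjects)
  # smoothed bootstrap: jitter resampled responses by a kernel bandwidth
  # proportional to the residual scale, correcting the well-known
  # undercoverage of percentile intervals for quantiles at small n
  resid <- obs$y - drop(X %*% est)
  h <- if (bootSmooth) sd(resid) / sqrt(nS) else 0
  if (!is.finite(h)) h <- 0
  boot <- withSeed(childSeed(seed, 404L), {
    draws <- matrix(sample.int(nS, nS * nBoot, replace = TRUE),
                    nrow = nBoot)
    if (interceptOnly && tau == 0.5 && length(unique(sizes)) == 1L) {
      # equal cluster sizes: all bootstrap medians in one pass
      ymat <- matrix(obs$y[unlist(bySubj, use.names = FALSE)],
                     nrow = sizes[1L])            # obs x subject
      big <- matrix(ymat[, t(draws)], ncol = nBoot)
      if (h > 0) big <- big + h * rnorm(length(big))
      matrix(rowMediansCpp(t(big)), ncol = 1L)
    } else {
      t(apply(draws, 1L, function(d) {
        idx <- unlist(bySubj[d], use.names = FALSE)
        yb <- obs$y[idx]
        if (h > 0) yb <- yb + h * rnorm(length(yb))
        if (interceptOnly) return(fitQuantile(X[idx, , drop = FALSE],
                                              yb, tau))
        Xb <- X[idx, , drop = FALSE]
        # guard against bootstrap designs that lose a column's variation
        rng <- apply(Xb[, -1L, drop = FALSE], 2L, function(col)
          max(col) - min(col))
        if (any(rng == 0)) return(rep(NA_real_, ncol(Xb)))
        fitQuantile(Xb, yb, tau, start = est, tol = 1e-8)
      }))
    }
  })
  if (ncol(X) == 1L) boot <- matrix(boot, ncol = 1L)
  a <- (1 - level) / 2
  ci <- apply(boot, 2L, quantile, probs = c(a, 1 - a), na.rm = TRUE)
  colnames(ci) <- colnames(X)
  # percentile intervals are widened (rarely needed) to bracket the
  # full-sample estimate, the documented CI contract
  ci[1L, ] <- pmin(ci[1L, ], est)
  ci[2L, ] <- pmax(ci[2L, ], est)
  signif <- ci[1L, ] > 0 | ci[2L, ] < 0
  colnames(boot) <- colnames(X)
  new("GroupModel", coefficients = est, ci = ci, nBoot = nBoot, tau = tau,
      terms = colnames(X), significant = signif, indeterminate = FALSE,
      nGated = length(gated), bootstrap = boot)
}

#' Canonical analysis signal labels
#'
#' The ~30 signals entering the block-average and connectivity analyses:
#' the 16 fNIRS channels (4 parameters x 4 locations), the two prefrontal
#' Mayer-wave amplitudes, and 12 systemic signals. Systolic and diastolic
#' pressure feed the derived indices but are not analysis signals
#' themselves.
#'
#' @return character vector of channel labels
#' @export
canonicalAnalysisSignals <- function() {
  c(as.vector(outer(c("O2Hb", "HHb", "tHb", "StO2"),
                    c("LPFC", "RPFC", "LVC", "RVC"), paste, sep = "_")),
    "MWA_LPFC", "MWA_RPFC",
    "HR", "RR", "PRQ", "PETCO2", "MAP", "PP", "Q", "PTT", "SCL",
    "HF", "LF", "LFHF")
}

#' Pooled left/right channel labels of a region
#'
#' @param region "VC" or "PFC"
#' @param param fNIRS parameter (default "O2Hb")
#' @return character vector of two channel labels
#' @export
regionSignals <- function(region = c("VC", "PFC"), param = "O2Hb") {
  region <- match.arg(region)
  paste0(param, "_", c("L", "R"), region)
}
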