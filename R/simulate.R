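#' @include AllClasses.R utils.R
NULL

#' Generate a stimulation protocol timeline
#'
#' Builds the session timeline: a dark baseline, \code{nBlocks} light-on
#' blocks of \code{onDuration} seconds separated by randomized light-off
#' periods, and a dark recovery phase. Off durations are drawn from a
#' discrete uniform distribution on the integer seconds of
#' \code{offRange} (the empirical law behind the published mean and range is
#' unknown; discrete uniform over the stated range is used and documented).
#' The last block is followed directly by recovery, so there are
#' \code{nBlocks - 1} off periods.
#'
#' @param seed integer seed; identical seeds give identical timelines
#' @param nBlocks number of light-on blocks (default 15)
#' @param onDuration light-on duration in seconds (default 20)
#' @param offRange numeric length-2, inclusive range of off durations in
#'   seconds (default c(17, 27))
#' @param baseline baseline duration in seconds (default 480, i.e. 8 min)
#' @param recovery recovery duration in seconds (default 900, i.e. 15 min)
#' @param color stimulus color: "red", "green" or "blue"
#' @return a [StimulusTimeline-class]
#' @examples
#' tl <- generateProtocol(seed = 1)
#' nBlocks(tl)          # 15
#' blockOnsets(tl)[1]   # 480
#' @export
generateProtocol <- function(seed, nBlocks = 15L, onDuration = 20,
                             offRange = c(17, 27), baseline = 480,
                             recovery = 900,
                             color = c("red", "green", "blue")) {
  color <- match.arg(color)
  stopIfNot(nBlocks >= 1L, "nBlocks must be >= 1")
  stopIfNot(length(offRange) == 2L && offRange[1L] <= offRange[2L],
            "invalid off range: min must not exceed max")
  offs <- withSeed(seed, {
    vals <- seq(floor(offRange[1L]), floor(offRange[2L]))
    if (nBlocks > 1L) vals[sample.int(length(vals), nBlocks - 1L,
                                      replace = TRUE)] else numeric()
  })
  onsets <- baseline + c(0, cumsum(onDuration + offs))
  wl <- c(red = 682, green = 515, blue = 465)[[color]]
  new("StimulusTimeline",
      baselineDuration = baseline, recoveryDuration = recovery,
      blockOnsets = onsets, onDuration = onDuration, offDurations = offs,
      color = color, wavelength = wl, illuminance = 20)
}

#' Canonical double-gamma hemodynamic impulse response
#'
#' Difference of two gamma densities with response peak near 6 s and
#' undershoot near 16 s, the standard kernel for modeling stimulus-evoked
#' cortical hemodynamic responses.
#'
#' @param t time in seconds (vector)
#' @param peakTime time-to-peak of the positive lobe, seconds
#' @param undershootTime time-to-peak of the undershoot, seconds
#' @param undershootRatio undershoot amplitude relative to the peak lobe
#' @return kernel values at \code{t} (unnormalized)
#' @export
hrfDoubleGamma <- function(t, peakTime = 6, undershootTime = 16,
                           undershootRatio = 1 / 6) {
  dgamma(t, shape = peakTime + 1, rate = 1) -
    undershootRatio * dgamma(t, shape = undershootTime + 1, rate = 1)
}

# Stimulus-evoked response template: HRF convolved with the on-block boxcar,
# scaled so a 20-s block reaches a plateau of 1. Returns a length-n vector on
# the fs grid.
evokedTemplate <- function(timelineObj, fs, n,
                           peakTime = 6, undershootTime = 16,
                           undershootRatio = 1 / 6) {
  tker <- seq(0, 32, by = 1 / fs)
  ker <- hrfDoubleGamma(tker, peakTime, undershootTime, undershootRatio) / fs
  # response to a single on-block: running sum of the kernel over a sliding
  # onDuration window (the boxcar convolution), via cumulative sums
  wOn <- as.integer(round(timelineObj@onDuration * fs))
  pad <- c(ker, numeric(wOn - 1L))
  csp <- cumsum(pad)
  blockResp <- csp - c(numeric(wOn), csp)[seq_along(pad)]
  # normalization: the amplitude parameter is defined as the block-average
  # response a 20-s reference block produces in the stimulus-interval
  # medians (6-24 s of the 35-s analysis segment, after baseline and
  # anchor-line detrending), so configured amplitudes are directly
  # comparable with pipeline block averages
  wRef <- as.integer(round(20 * fs))
  padR <- c(ker, numeric(max(wRef - 1L, 0L)))
  csR <- cumsum(padR)
  refResp <- csR - c(numeric(wRef), csR)[seq_along(padR)]
  nSeg <- as.integer(round(35 * fs))
  seg <- numeric(nSeg)
  src <- seq_len(min(length(refResp), nSeg - 5L * fs))
  seg[5L * fs + src] <- refResp[src]
  tseg <- (seq_len(nSeg) - 1L) / fs
  medIn <- function(v, lo) median(v[tseg >= lo - 1e-9 & tseg <= lo + 3 + 1e-9])
  m1 <- medIn(seg, 1); m7 <- medIn(seg, 31)
  segd <- seg - m1 - (m7 - m1) / 30 * (tseg - 2.5)
  scale <- median(vapply(c(6, 11, 16, 21), function(lo) medIn(segd, lo),
                         numeric(1)))
  y <- numeric(n + length(blockResp))
  for (on in blockOnsets(timelineObj)) {
    i0 <- as.integer(round(on * fs)) + 1L
    idx <- i0:(i0 + length(blockResp) - 1L)
    y[idx] <- y[idx] + blockResp
  }
  y[seq_len(n)] / scale
}

fnirsBaselines <- c(O2Hb = 30, HHb = 15, StO2 = 65)
fnirsUnits <- c(O2Hb = "umol/L", HHb = "umol/L", tHb = "umol/L", StO2 = "%")

#' Simulate fNIRS channels for one session
#'
#' Generates cerebral hemodynamic channels on a regular grid: per location,
#' each parameter is a baseline constant plus a stimulus-evoked component
#' (double-gamma impulse response convolved with the light-on boxcar, with
#' the subject's amplitude), a ~0.1-Hz Mayer-wave sinusoid and 1/f (pink)
#' noise. Total hemoglobin is constructed as \code{tHb = O2Hb + HHb}
#' exactly; StO2 has its own (smaller) evoked amplitude. True evoked
#' amplitudes are recorded in the annotations.
#'
#' @param timeline a [StimulusTimeline-class]
#' @param profile a [SubjectProfile-class]; amplitudes and noise scales are
#'   looked up by channel label (e.g. \code{"O2Hb_LVC"}), with 0 / default
#'   fallbacks
#' @param fs sampling rate in Hz (default 50)
#' @param seed integer seed
#' @param params which parameters to generate; requesting "tHb" implies
#'   generating O2Hb and HHb too, and tHb is their exact sum
#' @param locations channel locations (left/right prefrontal and visual
#'   cortex)
#' @param mayerFreq Mayer-wave frequency, Hz
#' @param mayerAmplitude Mayer-wave amplitude in channel units (applied to
#'   the hemoglobin channels; scaled by 0.5 for StO2)
#' @return a [Recording-class] with ground-truth annotations
#' @export
simulateFnirs <- function(timeline, profile, fs = 50, seed = 1L,
                          params = c("O2Hb", "HHb", "tHb", "StO2"),
                          locations = c("LPFC", "RPFC", "LVC", "RVC"),
                          mayerFreq = 0.1, mayerAmplitude = 0.1) {
  stopIfNot(fs >= 2, "fs must be >= 2 Hz")
  params <- match.arg(params, c("O2Hb", "HHb", "tHb", "StO2"),
                      several.ok = TRUE)
  wantTHb <- "tHb" %in% params
  wantO <- "O2Hb" %in% params || wantTHb
  wantH <- "HHb" %in% params || wantTHb
  n <- as.integer(round(totalDuration(timeline) * fs))
  tt <- (seq_len(n) - 1L) / fs
  evoked <- evokedTemplate(timeline, fs, n)
  channels <- list()
  trueAmp <- numeric()
  genParams <- c(if (wantO) "O2Hb", if (wantH) "HHb",
                 if ("StO2" %in% params) "StO2")
  defNoise <- c(O2Hb = 0.10, HHb = 0.05, StO2 = 0.10)
  withSeed(childSeed(seed, 101L), {
    phases <- runif(length(locations), 0, 2 * pi)
    noiseMat <- pinkNoiseK(n, length(locations) * length(genParams))
    col <- 0L
    for (li in seq_along(locations)) {
      loc <- locations[li]
      mayer <- mayerAmplitude * sin(2 * pi * mayerFreq * tt + phases[li])
      for (param in genParams) {
        col <- col + 1L
        lab <- paste0(param, "_", loc)
        amp <- if (lab %in% names(profile@responseAmplitudes))
          profile@responseAmplitudes[[lab]] else 0
        ns <- if (lab %in% names(profile@noiseScales))
          profile@noiseScales[[lab]] else defNoise[[param]]
        msc <- if (param == "StO2") 0.5 else 1
        channels[[lab]] <- list(
          samples = fnirsBaselines[[param]] + amp * evoked + msc * mayer +
            ns * noiseMat[, col],
          fs = fs, units = fnirsUnits[[param]])
        trueAmp[[lab]] <- amp
      }
      if (wantTHb) {
        channels[[paste0("tHb_", loc)]] <-
          list(samples = channels[[paste0("O2Hb_", loc)]]$samples +
                 channels[[paste0("HHb_", loc)]]$samples,
               fs = fs, units = fnirsUnits[["tHb"]])
        trueAmp[[paste0("tHb_", loc)]] <-
          trueAmp[[paste0("O2Hb_", loc)]] + trueAmp[[paste0("HHb_", loc)]]
      }
    }
  })
  new("Recording", channels = channels, timeline = timeline,
      annotations = list(trueAmplitudes = trueAmp,
                         mayer = list(freq = mayerFreq,
                                      amplitude = mayerAmplitude),
                         tHbExact = TRUE))
}

#' Simulate systemic physiological channels for one session
#'
#' Generates the capnogram and the beat-derived systemic streams the
#' analysis consumes. The capnogram is a per-breath waveform (smooth rise,
#' end-tidal plateau at the instantaneous PETCO2 level, fall back to 0)
#' driven by the instantaneous respiratory rate; pulse pressure is enforced
#' as \code{PP = SBP - DBP}; pulse transit time is inversely coupled to
#' mean arterial pressure; HF/LF heart-rate-variability band powers and the
#' tonic skin conductance level are generated directly as slowly drifting
#' positive series with optional stimulus-evoked steps. The true
#' respiratory-rate and PETCO2 traces are stored in the annotations on the
#' 2-Hz analysis grid.
#'
#' Stimulus-evoked steps are looked up in the profile amplitudes by channel
#' name ("RR" in breaths/min, "HR" in bpm, "MAP", "SBP", "DBP" in mmHg,
#' "PETCO2" in mmHg, "HF"/"LF" multiplicative log-steps, "SCL" in uS) and
#' applied through the same double-gamma response template as the cerebral
#' channels (slow autonomic responses share its timescale).
#'
#' @param timeline a [StimulusTimeline-class]
#' @param profile a [SubjectProfile-class]
#' @param seed integer seed
#' @param fsCapno capnogram sampling rate, Hz (default 25)
#' @param fsBeat sampling rate of the beat-derived/NIBP streams, Hz
#'   (default 1; the device rate is undocumented, this is a stated guess)
#' @param fsScl skin-conductance sampling rate, Hz (default 2)
#' @param breathingFreq baseline breathing frequency, Hz (default 0.25,
#'   i.e. 15 breaths/min); must be below \code{fsCapno / 2}
#' @param petco2Level baseline end-tidal CO2 plateau, mmHg (default 38)
#' @param hrBase,sbpBase,dbpBase,pttBase baselines: heart rate (bpm),
#'   systolic/diastolic pressure (mmHg), pulse transit time (ms)
#' @param noise overall noise level multiplier (0 disables all stochastic
#'   components)
#' @param rrRamp linear respiratory-rate drift across the session,
#'   breaths/min (default 0)
#' @param petco2Ramp linear end-tidal CO2 drift across the session, mmHg
#'   (default 0)
#' @return a [Recording-class] with ground-truth annotations
#' @export
simulateSystemic <- function(timeline, profile, seed = 1L, fsCapno = 25,
                             fsBeat = 1, fsScl = 2, breathingFreq = 0.25,
                             petco2Level = 38, hrBase = 70, sbpBase = 120,
                             dbpBase = 80, pttBase = 250, noise = 1,
                             rrRamp = 0, petco2Ramp = 0) {
  stopIfNot(breathingFreq < fsCapno / 2,
            "breathing frequency must be below half the capnogram rate")
  dur <- totalDuration(timeline)
  amp <- function(lab, default = 0)
    if (lab %in% names(profile@responseAmplitudes))
      profile@responseAmplitudes[[lab]] else default
  channels <- list()
  ann <- list()
  withSeed(childSeed(seed, 202L), {
    ## --- capnogram + ground-truth RR / PETCO2 -------------------------
    nC <- as.integer(round(dur * fsCapno))
    evC <- evokedTemplate(timeline, fsCapno, nC)
    frac <- (seq_len(nC) - 1L) / max(nC - 1L, 1L)
    rr <- breathingFreq * 60 + rrRamp * frac + amp("RR") * evC +
      noise * slowDrift(nC, fsCapno, 0.3, cutoff = 0.005)
    rr <- pmax(rr, 4)
    pet <- petco2Level + petco2Ramp * frac + amp("PETCO2") * evC +
      noise * slowDrift(nC, fsCapno, 0.3, cutoff = 0.005)
    phase <- cumsum(rr / 60 / fsCapno)
    u <- phase %% 1
    wave <- capnoShape(u)
    capno <- wave * pet + noise * 0.05 * rnorm(nC)
    channels[["capno"]] <- list(samples = capno, fs = fsCapno,
                                units = "mmHg")
    grid2 <- seq(0, (nC - 1L) / fsCapno, by = 0.5)
    ann$trueRR <- list(samples = approx((seq_len(nC) - 1) / fsCapno, rr,
                                        xout = grid2)$y, fs = 2,
                       units = "breaths/min")
    ann$truePETCO2 <- list(samples = approx((seq_len(nC) - 1) / fsCapno, pet,
                                            xout = grid2)$y, fs = 2,
                           units = "mmHg")
    ## --- beat-derived streams -----------------------------------------
    nB <- as.integer(round(dur * fsBeat))
    evB <- evokedTemplate(timeline, fsBeat, nB)
    hr <- hrBase + amp("HR") * evB + noise * slowDrift(nB, fsBeat, 1.5) +
      noise * 0.5 * rnorm(nB)
    dbp <- dbpBase + amp("DBP") * evB + noise * slowDrift(nB, fsBeat, 2) +
      noise * 0.5 * rnorm(nB)
    sbp <- sbpBase + amp("SBP") * evB +
      (dbp - dbpBase) + noise * slowDrift(nB, fsBeat, 2) +
      noise * 0.5 * rnorm(nB)
    sbp <- pmax(sbp, dbp + 10)
    pp <- sbp - dbp
    map <- dbp + pp / 3 + amp("MAP") * evB
    ptt <- pttBase - 1.0 * (map - (dbpBase + (sbpBase - dbpBase) / 3)) +
      noise * 0.5 * rnorm(nB)
    hf <- exp(log(300) + amp("HF") * evB +
                noise * slowDrift(nB, fsBeat, 0.15))
    lf <- exp(log(600) + amp("LF") * evB +
                noise * slowDrift(nB, fsBeat, 0.15))
    beat <- list(HR = list(hr, "bpm"), MAP = list(map, "mmHg"),
                 SBP = list(sbp, "mmHg"), DBP = list(dbp, "mmHg"),
                 PP = list(pp, "mmHg"), PTT = list(ptt, "ms"),
                 HF = list(hf, "ms^2"), LF = list(lf, "ms^2"))
    for (nm in names(beat))
      channels[[nm]] <- list(samples = beat[[nm]][[1L]], fs = fsBeat,
                             units = beat[[nm]][[2L]])
    ## --- skin conductance ----------------------------------------------
    nS <- as.integer(round(dur * fsScl))
    evS <- evokedTemplate(timeline, fsScl, nS)
    scl <- 5 + amp("SCL") * evS + noise * slowDrift(nS, fsScl, 0.3) +
      noise * 0.02 * rnorm(nS)
    channels[["SCL"]] <- list(samples = scl, fs = fsScl, units = "uS")
  })
  new("Recording", channels = channels, timeline = timeline,
      annotations = ann)
}

# Per-breath capnogram shape as a function of cycle position u in [0, 1):
# smooth rise over [0, 0.12), alveolar plateau rising from 0.96 to 1.0
# (end-tidal maximum at the end of exhalation, as in real capnograms)
# over [0.12, 0.58), smooth fall over [0.58, 0.70), zero (inspiration)
# elsewhere.
capnoShape <- function(u) {
  y <- numeric(length(u))
  ris <- u < 0.12
  y[ris] <- 0.96 * 0.5 * (1 - cos(pi * u[ris] / 0.12))
  pla <- u >= 0.12 & u < 0.58
  y[pla] <- 0.96 + 0.04 * (u[pla] - 0.12) / 0.46
  fal <- u >= 0.58 & u < 0.70
  y[fal] <- 0.5 * (1 + cos(pi * (u[fal] - 0.58) / 0.12))
  y
}

#' Inject movement artifacts into a recording
#'
#' Adds spikes (1-3 samples) and sudden baseline shifts (step changes
#' persisting until the next step) at Poisson-distributed times, the two
#' dominant movement-artifact types in head-mounted optical recordings.
#' The exact artifact sample mask and the clean signal are stored in the
#' annotations so that correction algorithms can be scored against the
#' truth.
#'
#' @param recording a [Recording-class]
#' @param spikeRate expected spikes per minute
#' @param shiftRate expected baseline shifts per minute
#' @param spikeScale spike amplitude in multiples of the channel SD
#' @param shiftScale shift amplitude in multiples of the channel SD
#' @param seed integer seed
#' @param channels channel labels to corrupt (default: all fNIRS channels,
#'   i.e. labels matching O2Hb/HHb/tHb/StO2)
#' @return the corrupted [Recording-class]; annotations gain
#'   \code{artifactMask} (per-channel logical vectors) and
#'   \code{cleanChannels}
#' @export
injectArtifacts <- function(recording, spikeRate = 0, shiftRate = 0,
                            spikeScale = 20, shiftScale = 10, seed = 1L,
                            channels = NULL) {
  stopIfNot(spikeRate >= 0 && shiftRate >= 0, "rates must be >= 0")
  if (is.null(channels))
    channels <- grep("^(O2Hb|HHb|tHb|StO2)_", channelNames(recording),
                     value = TRUE)
  masks <- list()
  clean <- list()
  ch <- recording@channels
  withSeed(childSeed(seed, 303L), {
    for (nm in channels) {
      x <- ch[[nm]]$samples
      fs <- ch[[nm]]$fs
      n <- length(x)
      minutes <- n / fs / 60
      s <- sd(x)
      mask <- logical(n)
      add <- numeric(n)
      nspike <- stats::rpois(1, spikeRate * minutes)
      if (nspike > 0) {
        starts <- sort(sample.int(n, nspike))
        for (st in starts) {
          len <- sample(1:3, 1)
          idx <- st:min(st + len - 1L, n)
          a <- sample(c(-1, 1), 1) * spikeScale * s * runif(1, 0.8, 1.2)
          shape <- exp(-(seq_along(idx) - 1))
          add[idx] <- add[idx] + a * shape
          mask[idx] <- TRUE
        }
      }
      nshift <- stats::rpois(1, shiftRate * minutes)
      if (nshift > 0) {
        starts <- sort(sample.int(n - 1L, nshift))
        for (st in starts) {
          a <- sample(c(-1, 1), 1) * shiftScale * s * runif(1, 0.8, 1.2)
          add[(st + 1L):n] <- add[(st + 1L):n] + a
          mask[st:(st + 1L)] <- TRUE
        }
      }
      if (nspike + nshift > 0) {
        clean[[nm]] <- x
        masks[[nm]] <- mask
        ch[[nm]]$samples <- x + add
      }
    }
  })
  # keep tHb = O2Hb + HHb consistent after corruption: recompute tHb from
  # the corrupted components where all three exist
  for (loc in unique(sub("^tHb_", "", grep("^tHb_", names(ch), value = TRUE)))) {
    o <- ch[[paste0("O2Hb_", loc)]]; h <- ch[[paste0("HHb_", loc)]]
    if (!is.null(o) && !is.null(h) && !is.null(ch[[paste0("tHb_", loc)]])) {
      nm <- paste0("tHb_", loc)
      if (is.null(clean[[nm]]) &&
          (!is.null(clean[[paste0("O2Hb_", loc)]]) ||
           !is.null(clean[[paste0("HHb_", loc)]])))
        clean[[nm]] <- ch[[nm]]$samples
      ch[[nm]]$samples <- o$samples + h$samples
      m <- masks[[paste0("O2Hb_", loc)]]
      if (is.null(m)) m <- logical(length(o$samples))
      m2 <- masks[[paste0("HHb_", loc)]]
      if (!is.null(m2)) m <- m | m2
      if (any(m)) masks[[nm]] <- m
    }
  }
  ann <- recording@annotations
  ann$artifactMask <- masks
  ann$cleanChannels <- clean
  new("Recording", channels = ch, timeline = recording@timeline,
      annotations = ann)
}

#' Build a subject profile
#'
#' @param subjectId identifier
#' @param age age in years
#' @param gender "male" or "female"
#' @param responseAmplitudes named numeric vector of evoked amplitudes
#' @param noiseScales named numeric vector of noise SDs
#' @return a [SubjectProfile-class]
#' @export
subjectProfile <- function(subjectId, age = 33, gender = "male",
                           responseAmplitudes = numeric(),
                           noiseScales = numeric()) {
  new("SubjectProfile", subjectId = as.character(subjectId), age = age,
      gender = gender, responseAmplitudes = responseAmplitudes,
      noiseScales = noiseScales)
}

# Scenario amplitude table: per color, named evoked amplitudes.
# "headline": visual cortex responds to every color; prefrontal cortex
# responds to blue only (positive O2Hb/tHb/StO2, negative HHb).
scenarioAmplitudes <- function(scenario, color,
                               locations = c("LPFC", "RPFC", "LVC", "RVC")) {
  base <- c(O2Hb = 0.4, HHb = -0.15, StO2 = 0.2)
  amps <- numeric()
  if (scenario == "null") return(amps)
  for (loc in locations) {
    isVC <- grepl("VC$", loc)
    active <- if (isVC) TRUE else identical(color, "blue")
    for (p in names(base))
      amps[[paste0(p, "_", loc)]] <- if (active) base[[p]] else 0
  }
  # modest systemic responses (qualitative shape only)
  amps <- c(amps, RR = 1, HR = if (color == "blue") 1.5 else 0,
            MAP = if (color == "blue") 0 else -1.5)
  amps
}

#' Generate a synthetic crossover cohort
#'
#' Simulates a randomized crossover cohort: each subject is measured once
#' per color on a separate session (its own randomized off periods). The
#' default scenario ("headline") reproduces the qualitative structure the
#' analysis is designed to detect: visual-cortex responses for every color
#' and prefrontal responses for blue only. The "null" scenario has no
#' evoked responses anywhere.
#'
#' @param nSubjects number of subjects (default 14)
#' @param seed integer seed
#' @param scenario "headline" or "null"
#' @param colors colors measured per subject (crossover design)
#' @param fs fNIRS sampling rate, Hz
#' @param fnirsParams fNIRS parameters to simulate
#' @param locations fNIRS locations
#' @param includeSystemic also simulate the systemic channels
#' @param ampVariability multiplicative intersubject amplitude SD
#' @param timelineArgs list of extra arguments for [generateProtocol()]
#' @param artifactArgs optional list of arguments for [injectArtifacts()]
#'   applied to every recording (e.g. \code{list(spikeRate = 0.5)})
#' @return list with \code{profiles} (list of [SubjectProfile-class]) and
#'   \code{recordings} (nested list: subject, then color)
#' @export
generateCohort <- function(nSubjects = 14L, seed = 1L,
                           scenario = c("headline", "null"),
                           colors = c("red", "green", "blue"), fs = 50,
                           fnirsParams = c("O2Hb", "HHb", "tHb", "StO2"),
                           locations = c("LPFC", "RPFC", "LVC", "RVC"),
                           includeSystemic = FALSE, ampVariability = 0.15,
                           timelineArgs = list(), artifactArgs = NULL) {
  scenario <- match.arg(scenario)
  stopIfNot(nSubjects >= 1L, "nSubjects must be >= 1")
  demo <- withSeed(childSeed(seed, 7L), {
    ages <- round(pmin(pmax(rnorm(nSubjects, 33.4, 10.5), 20), 60))
    nMale <- round(nSubjects * 9 / 14)
    genders <- sample(rep(c("male", "female"),
                          c(nMale, nSubjects - nMale)))
    factors <- pmax(rnorm(nSubjects, 1, ampVariability), 0.3)
    list(ages = ages, genders = genders, factors = factors)
  })
  profiles <- vector("list", nSubjects)
  recordings <- vector("list", nSubjects)
  for (i in seq_len(nSubjects)) {
    recs <- list()
    ampsAll <- numeric()
    for (ci in seq_along(colors)) {
      color <- colors[ci]
      sSeed <- childSeed(seed, i * 17L + ci)
      tl <- do.call(generateProtocol,
                    c(list(seed = sSeed, color = color), timelineArgs))
      amps <- scenarioAmplitudes(scenario, color, locations) *
        demo$factors[i]
      ampsAll <- c(ampsAll, amps[setdiff(names(amps), names(ampsAll))])
      prof <- subjectProfile(sprintf("S%02d", i), demo$ages[i],
                             demo$genders[i], responseAmplitudes = amps)
      rec <- simulateFnirs(tl, prof, fs = fs, seed = sSeed,
                           params = fnirsParams, locations = locations)
      if (includeSystemic) {
        sys <- simulateSystemic(tl, prof, seed = sSeed)
        rec@channels <- c(rec@channels, sys@channels)
        rec@annotations <- c(rec@annotations, sys@annotations)
      }
      if (!is.null(artifactArgs))
        rec <- do.call(injectArtifacts,
                       c(list(recording = rec, seed = sSeed), artifactArgs))
      recs[[color]] <- rec
    }
    profiles[[i]] <- subjectProfile(sprintf("S%02d", i), demo$ages[i],
                                    demo$genders[i],
                                    responseAmplitudes = ampsAll)
    recordings[[i]] <- recs
  }
  list(profiles = profiles, recordings = recordings)
}
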