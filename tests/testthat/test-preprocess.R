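test_that("artifact correction leaves clean signals untouched", {
  set.seed(1)
  t <- (0:2999) / 10
  x <- sin(2 * pi * 0.05 * t) + 0.2 * rnorm(3000)
  res <- maraCorrect(x, fs = 10)
  expect_identical(res$corrected, x)
  expect_equal(nrow(res$mask$segments), 0)
  expect_equal(res$mask$coverageFraction, 0)
})

test_that("artifact correction removes steps and spikes against the clean oracle", {
  set.seed(2)
  t <- (0:2999) / 10
  clean <- sin(2 * pi * 0.05 * t) + 0.1 * rnorm(3000)
  s <- sd(clean)
  # single step of +10 SD
  stepped <- clean + c(numeric(1500), rep(10 * s, 1500))
  res <- maraCorrect(stepped, fs = 10)
  expect_gt(nrow(res$mask$segments), 0)
  resid <- alignResidual(res$corrected, clean, res$mask$flag)
  expect_lt(sd(resid[!res$mask$flag]), 0.05 * s)
  expect_lt(max(abs(resid[!res$mask$flag])), 0.5 * s)
  # 1-sample spike of 20 SD: amplitude reduced by >= 90%
  spiked <- clean
  spiked[800] <- spiked[800] + 20 * s
  res2 <- maraCorrect(spiked, fs = 10)
  resid2 <- alignResidual(res2$corrected, clean, res2$mask$flag)
  expect_lt(abs(resid2[800]), 2 * s)   # 20 SD -> <= 2 SD
  # all-flagged signal errors
  expect_error(maraCorrect(rep(c(0, 50), 50), fs = 10, window = 1,
                           threshold = 1e-6),
               "no clean reference")
})

test_that("artifact correction is idempotent on its own output", {
  set.seed(3)
  t <- (0:1999) / 10
  for (s in 1:5) {
    clean <- sin(2 * pi * 0.05 * t) + 0.2 * rnorm(2000)
    x <- clean
    x[500] <- x[500] + 15 * sd(clean)
    x[1200:2000] <- x[1200:2000] + 8 * sd(clean)
    r1 <- maraCorrect(x, fs = 10)
    expect_gt(r1$mask$coverageFraction, 0)
    r2 <- maraCorrect(r1$corrected, fs = 10)
    expect_equal(r2$mask$coverageFraction, 0)
    expect_identical(r2$corrected, r1$corrected)
  }
})

test_that("the automatic parameter search returns a usable combination", {
  set.seed(8)
  x <- 0.2 * rnorm(1500)
  x[700] <- x[700] + 20 * sd(x)
  tune <- maraAutoTune(x, fs = 10, windows = c(0.5, 1),
                       thresholds = c(3, 4), spars = c(0.3))
  expect_true(tune$window %in% c(0.5, 1))
  expect_lte(min(tune$grid$score, na.rm = TRUE), 1)
})

test_that("resampling preserves the passband and rejects the stopband", {
  expect_equal(resampleSignal(rep(2.5, 501), 50, 2), rep(2.5, 21))
  t <- (0:49999) / 50
  lo <- sin(2 * pi * 0.1 * t)
  y <- resampleSignal(lo, 50, 2)
  expect_equal(max(abs(y[100:1900])), 1, tolerance = 0.01)
  hi <- sin(2 * pi * 10 * t)
  yh <- resampleSignal(hi, 50, 2)
  expect_lt(sqrt(mean(yh^2)) / sqrt(mean(hi^2)), 0.05)
  expect_error(resampleSignal(lo, -1, 2), "positive")
  # two-stage agrees with direct on band-limited input
  d1 <- resampleSignal(lo, 50, 2)
  d2 <- resampleSignal(resampleSignal(lo, 50, 10), 10, 2)
  expect_lt(max(abs(d1[50:1950] - d2[50:1950])), 0.02)
})

test_that("moving average has the documented window and edge behavior", {
  expect_equal(movingAverage(rep(3, 50), 2), rep(3, 50))
  ramp <- seq(0, 10, length.out = 101)
  ma <- movingAverage(ramp, 2)
  expect_equal(ma[3:99], ramp[3:99])    # symmetric window on a line
  set.seed(4)
  w <- rnorm(20000)
  v <- var(movingAverage(w, 2)[100:19900])
  expect_equal(v, 1 / 5, tolerance = 0.05)  # 2.4 s at 2 Hz -> 5 samples
  # NA samples stay NA and are excluded from neighboring windows
  x <- c(1, 2, NA, 4, 5, 6, 7)
  ma2 <- movingAverage(x, 2)
  expect_true(is.na(ma2[3]))
  expect_equal(ma2[4], mean(c(2, 4, 5, 6)))
})

test_that("robust local regression reproduces quadratics and resists outliers", {
  t <- seq(-3, 3, length.out = 200)
  q <- 2 + 0.5 * t - 1.2 * t^2
  expect_equal(rloessSmooth(q), q, tolerance = 1e-6)
  expect_equal(rloessSmooth(rep(4, 60)), rep(4, 60), tolerance = 1e-9)
  x <- rep(1, 100)
  x[50] <- 101
  sm <- rloessSmooth(x)
  expect_lt(max(abs(sm - 1)), 5)       # < 5% of the outlier height
  expect_error(rloessSmooth(rnorm(10), bin = 20), "shorter")
})

test_that("end-tidal CO2 tracks constant and ramping plateaus", {
  tl <- tinyProtocol()
  prof <- subjectProfile("S01", 30, "male")
  rec <- simulateSystemic(tl, prof, seed = 5, noise = 0, petco2Level = 38)
  pet <- extractPetco2(channelSamples(rec, "capno"), 25)
  core <- pet[20:(length(pet) - 20)]
  expect_lt(max(abs(core - 38)), 0.5)
  # ramping plateaus 35 -> 40
  rec2 <- simulateSystemic(tl, prof, seed = 6, noise = 0,
                           petco2Level = 35, petco2Ramp = 5)
  pet2 <- extractPetco2(channelSamples(rec2, "capno"), 25)
  truth <- annotations(rec2)$truePETCO2$samples
  n <- min(length(pet2), length(truth))
  core <- 20:(n - 20)
  expect_lt(max(abs(pet2[core] - truth[core])), 0.5)
  expect_error(extractPetco2(numeric(500), 25), "no detectable breaths")
})

test_that("respiratory rate recovers constant and ramping breathing", {
  tl <- tinyProtocol()
  prof <- subjectProfile("S01", 30, "male")
  rec <- simulateSystemic(tl, prof, seed = 7, noise = 0,
                          breathingFreq = 0.25)
  rr <- extractRR(channelSamples(rec, "capno"), 25)
  expect_lt(max(abs(rr[20:(length(rr) - 20)] - 15)), 0.2)
  # ramp 12 -> 18 breaths/min
  rec2 <- simulateSystemic(tl, prof, seed = 8, noise = 0,
                           breathingFreq = 0.2, rrRamp = 6)
  rr2 <- extractRR(channelSamples(rec2, "capno"), 25)
  truth <- annotations(rec2)$trueRR$samples
  n <- min(length(rr2), length(truth))
  core <- 30:(n - 30)
  expect_lt(max(abs(rr2[core] - truth[core])), 0.5)
  # monotone interpolant never leaves the data range
  peaks <- findBreathPeaks(channelSamples(rec2, "capno"), 25)
  rates <- 60 / diff((peaks - 1) / 25)
  expect_lte(max(rr2), max(rates) + 1e-9)
  expect_gte(min(rr2), min(rates) - 1e-9)
  expect_error(extractRR(sin(2 * pi * 0.25 * (0:100) / 25), 25),
               "fewer than 3")
})

test_that("derived indices follow their defining formulas and flag bad samples", {
  d <- computeDerived(HR = 72, RR = 18, PP = 40, SBP = 120, DBP = 80,
                      LF = 0.04, HF = 0.02)
  expect_equal(d$PRQ, 4)
  expect_equal(d$Q, (40 * 72) / 200)
  expect_equal(d$LFHF, 2)
  d2 <- computeDerived(HR = c(70, 70), RR = c(0, 14), PP = c(40, 40),
                       SBP = c(120, 120), DBP = c(80, 80),
                       LF = c(1, 1), HF = c(1, -1))
  expect_true(is.na(d2$PRQ[1]))
  expect_true(is.na(d2$LFHF[2]))
  expect_equal(d2$nFlagged, 2)
  expect_error(computeDerived(1:3, 1:2, 1:3, 1:3, 1:3, 1:3, 1:3),
               "common grid")
})

test_that("Mayer-wave amplitude tracks in-band oscillations only", {
  t <- (0:4799) / 2                      # 40 min at 2 Hz
  x <- 0.8 * sin(2 * pi * 0.1 * t)
  mwa <- computeMWA(x, 2)
  core <- 300:4500
  expect_equal(median(mwa[core]), 0.8, tolerance = 0.05)
  out <- computeMWA(0.8 * sin(2 * pi * 0.3 * t), 2)
  expect_lt(median(out[core]), 0.05 * 0.8)
  # slow amplitude modulation is tracked
  modu <- 0.5 + 0.3 * sin(2 * pi * t / 1200)
  xm <- modu * sin(2 * pi * 0.1 * t)
  mm <- computeMWA(xm, 2)
  expect_lt(max(abs(mm[core] - modu[core])) / 0.8, 0.1)
  expect_error(computeMWA(x, 2, band = c(0.5, 1.2)), "band")
})

test_that("preprocessing a full recording yields the 2-Hz analysis channels", {
  tl <- tinyProtocol()
  prof <- subjectProfile("S01", 30, "male",
                         responseAmplitudes = c(O2Hb_LVC = 0.4))
  rec <- simulateFnirs(tl, prof, fs = 50, seed = 11)
  sys <- simulateSystemic(tl, prof, seed = 11)
  rec@channels <- c(rec@channels, sys@channels)
  rec@annotations <- c(rec@annotations, sys@annotations)
  pp <- preprocessRecording(rec)
  expect_true(all(c("O2Hb_LVC", "tHb_RPFC", "MWA_LPFC", "MWA_RPFC", "RR",
                    "PETCO2", "PRQ", "Q", "LFHF", "SCL") %in%
                    channelNames(pp)))
  for (nm in channelNames(pp))
    expect_equal(channelRate(pp, nm), 2)
  lens <- vapply(channelNames(pp), function(nm)
    length(channelSamples(pp, nm)), integer(1))
  expect_equal(length(unique(lens)), 1L)
})
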