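---
title: "Methods: simulation and analysis of SPA-fNIRS color-stimulation experiments"
author: "spafnirs package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulation and analysis of SPA-fNIRS color-stimulation experiments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spafnirs)
```

## Scope and model

Systemic-physiology-augmented fNIRS (SPA-fNIRS) records cerebral
hemodynamics and oxygenation ([O2Hb], [HHb], [tHb], StO2 at left/right
prefrontal and visual cortex) simultaneously with systemic signals
(capnogram-derived PETCO2 and respiratory rate, heart rate, blood
pressures, pulse transit time, heart-rate-variability band powers, skin
conductance). This package implements, end to end, an analysis for
intermittent visual color stimulation experiments with such recordings:

1. a ground-truth-annotated **simulator** of the full multimodal session,
2. the **preprocessing chain** (movement-artifact reduction, anti-aliased
   downsampling to a common 2-Hz grid, smoothing, capnogram envelope and
   breath-peak analysis, derived indices),
3. **stimulus-locked block averaging** with a subject-level signed-rank
   significance gate and group-level quantile regression,
4. significance-masked **Spearman connectivity networks** with weighted
   graph metrics and between-color comparisons.

Because no public recording of this kind is available, every stage is
validated against the simulator's ground truth and against independent
brute-force oracles (exact test enumeration, closed-form convolutions,
Floyd-Warshall path search, exact L1 fits).

## The simulated experiment

A session is 8 min of dark baseline, 15 light-on blocks of 20 s separated
by randomized dark off periods, and 15 min of dark recovery. Off
durations are drawn from a discrete uniform distribution on 17-27 s
(mean and range of the published protocol are known, its exact law is
not; the uniform choice is configurable). The last block is followed
directly by recovery. Each of the 14 simulated subjects is measured once
per color (red, green, blue) with its own randomized timeline, mirroring
a crossover design; ages are drawn near 33 +/- 10 years and the sex ratio
is 9:5.

The fNIRS signal model per channel is

    baseline + amplitude * evoked(t) + Mayer wave + 1/f noise,

where `evoked(t)` is the canonical double-gamma impulse response (peak
6 s, undershoot 16 s, ratio 1/6) convolved with the light-on boxcar. The
amplitude parameter is calibrated so that one isolated 20-s block yields
a stimulus-interval block-average median equal to the amplitude; this
makes configured amplitudes directly comparable with pipeline estimates.
Defaults for the "headline" scenario are +0.4 umol/L [O2Hb],
-0.15 umol/L [HHb], +0.2 % StO2 in the visual cortex for every color and
in the prefrontal cortex for blue only, with intersubject amplitude
variability of 15 % (multiplicative, s.d.), Mayer-wave amplitude
0.1 umol/L at 0.1 Hz, and pink-noise s.d. 0.1 (O2Hb, StO2) and 0.05
(HHb). `tHb` is constructed as `O2Hb + HHb` exactly. Movement artifacts
(spikes of 1-3 samples and persisting baseline shifts, Poisson-placed)
can be injected with a per-channel sample mask and the retained clean
signal as oracle.

The capnogram is a per-breath waveform (cosine rise, end-tidal plateau at
the instantaneous PETCO2, cosine fall) driven by phase-integrating the
instantaneous respiratory rate at 25 Hz (the device rate is not
documented; 25 Hz is a stated choice). Beat-derived channels are
generated at 1 Hz (again a documented guess; skin conductance at the
documented 2 Hz), with `PP = SBP - DBP` enforced, `MAP = DBP + PP/3`,
pulse transit time inversely coupled to MAP, and HF/LF band powers as
log-normal slow drifts. HF/LF are generated directly as band-power
series: re-deriving HRV spectra from an ECG is out of scope.

What the simulator does *not* emulate: scalp/superficial contamination
(the modeled instrument's multidistance geometry minimizes it),
photon-transport physics, realistic beat-to-beat waveforms,
skin-conductance responses, or habituation across blocks. Passing tests
therefore demonstrate that the analysis recovers what it assumes, not
that those assumptions hold on any given real recording.

## Preprocessing

**Movement-artifact reduction.** Samples whose moving standard deviation
(1-s centered window) exceeds 3x the signal's median moving SD are
flagged; detections are expanded by half a window, merged across short
gaps, modeled by a near-interpolating smoothing spline
(`splineSmoothing = 0.1` removes 10 % of the segment's degrees of
freedom), and the model is subtracted; segments are then re-concatenated
by constant offset matching over half-window neighborhoods at each seam.
Detection and correction iterate (at most 4 passes) until a pass flags
nothing, which makes the procedure idempotent on its own output. Clean
regions are altered only by per-segment constants. The published
procedure chose its parameters per signal by hand; `maraAutoTune()`
provides a small grid search scored on upper-tail moving-SD reduction.
The relative threshold presumes a measurement-noise floor; on an exactly
noise-free signal the stimulus response itself becomes the most variable
feature and would be flagged, so noise-free oracle tests disable this
stage.

**Rate conversion.** All analysis happens on a 2-Hz grid. Downsampling
applies a zero-phase (forward-backward) order-6 Butterworth low-pass at
0.9x the target Nyquist before grid interpolation; integer-ratio
reductions subsample directly after filtering. A 0.1-Hz component is
preserved to <1 % and a 10-Hz component suppressed below 5 % RMS. fNIRS
channels then receive a centered moving average of 2.4 s; at 2 Hz that is
4.8 samples, rounded to the nearest odd window (5) for symmetry, with
shrinking windows at the edges.

**Capnogram.** Breath maxima are detected by a prominence-based peak
detector (prominence at least 30 % of the robust signal amplitude,
refractory period 1.5 s, i.e. a 40 breaths/min ceiling). PETCO2 is the
upper envelope through the per-breath maxima interpolated to the 2-Hz
grid and smoothed by robust local regression; the envelope is taken on
the native-rate capnogram because low-pass resampling of the waveform
itself would bias the plateaus downward. The respiratory rate is 60
divided by successive peak intervals, assigned at inter-peak midpoints
and interpolated with a monotone (shape-preserving) piecewise cubic
Hermite polynomial, so interpolated rates never leave the observed
range; outside the first/last midpoint the nearest rate is held.

**Robust smoothing.** Systemic channels (except skin conductance) are
smoothed by robust local regression: locally weighted quadratic fits
over a 20-sample bin with explicit bisquare reweighting (4 iterations).
The explicit reweighting loop reproduces noiseless quadratics exactly
and handles the degenerate case of an isolated outlier on an otherwise
exact fit, where the usual residual-MAD scale collapses to zero. The
20-sample bin is interpreted on the 2-Hz grid (10 s) for all systemic
signals.

**Derived indices.** `PRQ = HR/RR`, `Q = (PP*HR)/(SBP+DBP)`,
`LFHF = LF/HF`, computed elementwise on the common grid; samples with
nonpositive denominators are flagged missing, never silently dropped.
The Mayer-wave amplitude (MWA) of the prefrontal O2Hb channels is the
analytic-signal envelope of the 0.07-0.13-Hz band-passed signal,
low-passed at 0.03 Hz. No published definition of MWA exists for this
analysis; band edges, the envelope method and the source channel (O2Hb,
where Mayer waves are most visible) are package choices, and MWA is
computed from the resampled signal *before* the moving average, which
would attenuate the Mayer band by ~10 %.

## Block-average statistics

Each trial segment spans 35 s from 5 s before light-on, at 2 Hz (70
samples). Medians are taken over the seven closed 3-s intervals starting
at 1, 6, 11, 16, 21, 26 and 31 s; the stimulus is covered by the four
intervals between 6 and 24 s. Normalization subtracts the first-interval
median and removes the line through the first- and last-interval anchor
points (then re-centers so the first-interval median is exactly zero).
The anchor-line convention was chosen over full-segment least squares
because a least-squares line fitted through the evoked response itself
attenuates it; the least-squares variant remains available
(`mode = "ls"`). Any affine function of time maps to the zero block
exactly.

The subject-level gate tests, per signal and stimulus interval, the
across-trial interval medians against zero with an exact Wilcoxon
signed-rank test (midrank ties, exact enumeration up to n = 25 via a
generating-function convolution, normal approximation beyond; fewer than
5 non-zero values give p = 1). Benjamini-Hochberg FDR correction is
applied across one family spanning all signals and the four stimulus
intervals (a per-signal family is available); a signal is significant
when any stimulus interval survives, and its gate weight (0/1) multiplies
its block average in the group model. The weight-by-zero convention is
taken literally: non-significant subject-level responses enter the group
model as zeros rather than being excluded. Exclusion (available via
`zeroWeight = "exclude"`) selects exactly those null subjects whose
noise happened to look extreme, biasing the surviving sample away from
zero and inflating group-level false positives far above the nominal
level; zeroing keeps the group median anchored and calibrated.

Group-level inference is median (tau = 0.5) regression of the pooled
left+right per-subject stimulus responses (median of the four
stimulus-interval block averages) on an intercept, optional color
contrasts (reference red, so the blue coefficient is blue-vs-red
directly; blue-vs-green is the derived difference of the two contrast
coefficients, with its CI from the same bootstrap draws), age and
gender. The solver is iteratively reweighted least squares on the check
loss with an epsilon-smoothed weight floor, followed by a vertex-descent
polish over exact p-point fits; it reproduces noiseless fits exactly and
matches an exact L1 enumeration oracle on small problems. Confidence
intervals are percentile intervals from a subject-resampling (cluster)
bootstrap, 2000 draws by default (the published analysis used 100,000;
the default here is a desk-scale choice and is configurable). Resampled
responses are jittered by a kernel bandwidth of
`sd(residuals)/sqrt(nSubjects)` (smoothed bootstrap): the plain
percentile interval of a median at 14 subjects is visibly anti-
conservative (about 91-92 % coverage at nominal 95 %) because the
bootstrap median lives on a few order statistics, and smoothing is the
standard correction. With fewer than two gated subjects the model is
declared indeterminate rather than fitted.

## Connectivity networks

Per trial, Spearman correlations are computed between all pairs of the
normalized 70-sample segment time courses (about 30 signals when the
full channel set is simulated: 16 fNIRS channels, 2 MWA, 12 systemic).
Two-sided p-values use the t approximation on the rank correlation;
Benjamini-Hochberg correction is applied across all pairs, and
non-significant entries are deleted (masked). Whether the published
per-trial correlation used the segment time courses or the seven interval
medians is not stated; time courses are the default here (the medians
variant can be fed in by constructing blocks from them). Matrices are
averaged entrywise over the matrices in which the entry is unmasked
(`nEff` records the count); treating deleted entries as zero is available
as an option. Correlations map to edge weights by absolute value by
default, because the weighted metrics require nonnegative weights;
positive-only is the alternative.

The four metrics follow the standard weighted definitions: density
`D = 2K/(N(N-1))`; weighted transitivity `Tw` as the ratio of the
geometric-mean triangle intensity sum (weights pre-scaled by the maximum
weight) over the connected-triple count; weighted global efficiency `Ew`
as the mean inverse shortest-path length with edge lengths `1/w`
(disconnected pairs contribute 0); and weighted assortativity `rw` as the
Pearson correlation of endpoint strengths over both edge orientations,
with strengths including the connecting edge. `rw` is undefined (NA) for
graphs with fewer than two edges or constant endpoint strengths. Shortest
paths use Dijkstra via igraph; the test oracle re-derives all four
metrics by direct formula evaluation and Floyd-Warshall. Per-subject
metrics (one value per subject and color, from the subject's
trial-averaged matrix) are compared between colors with the exact
Wilcoxon rank-sum test.

## Numerical and scale choices

* Exact test enumeration switches to the normal approximation above
  n = 25 (signed rank) / pooled n = 30 (rank sum); both handle midrank
  ties exactly below that via subset-sum dynamic programming on doubled
  ranks.
* Time is `(i-1)/fs` from recording start; resampling to rate `r` yields
  `floor((n-1) r / fs) + 1` samples.
* Missing samples propagate as NA through elementwise operations and are
  excluded from medians; a trial whose baseline interval is entirely
  missing is flagged unusable for that signal.
* `tHb = O2Hb + HHb` holds exactly at generation and to filter tolerance
  through the linear preprocessing stages; the artifact-correction stage
  is the one nonlinear step and can perturb the identity when it fires
  asymmetrically across the three channels.
* Default problem sizes used by the validation suite: 100 simulation
  seeds for the headline-pattern, artifact-correction and respiratory
  recovery checks; 1000 null subjects for gate calibration; 200
  replicates for CI coverage; 2000 bootstrap draws in the headline runs
  and 1000 in calibration runs. These are the package's desk-scale
  defaults; all are configurable upward.
* The headline validation scenario simulates the O2Hb channel set only
  and skips the MWA channels; both are purely a matter of which channels
  the check needs, not of the method.

## A worked example

```{r example, eval = FALSE}
cfg <- defaultRunConfig(seed = 1L)
cfg$cohort$fnirsParams <- "O2Hb"
cfg$preprocess$mwaLocations <- character(0)
out <- runPipeline(cfg)
out$regionColor
out$contrasts
```

`regionColor` flags, per region and color, whether the group stimulus
response is significant (bootstrap CI excluding zero); `contrasts` holds
the full color/age/gender model per region including the derived
blue-vs-green contrast. Under the headline scenario the expected pattern
is visual-cortex significance for all three colors and prefrontal
significance for blue only, with both blue contrasts significant.

## Known limitations

* The simulator's noise is stationary 1/f plus sinusoidal Mayer waves;
  real recordings contain nonstationary physiology and task-correlated
  systemic confounds that can mimic cortical responses — the very reason
  the systemic channels are recorded alongside.
* The artifact detector's relative threshold assumes artifacts are rare
  and the noise floor stationary; pathological signals (artifact
  coverage approaching the clean fraction) degrade the median reference.
* The group model treats color as a fixed effect in a single model
  (color, age, gender together); crossover carry-over effects are
  assumed absent, as in the modeled design.
* Network metrics are computed on significance-masked weighted graphs;
  their values depend on the masking level alpha and the weight
  transform, which should be reported alongside any comparison.
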