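---
title: "Methods: trial-based calcium imaging and intrinsic-signal plasticity analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: trial-based calcium imaging and intrinsic-signal plasticity analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(caplast)
```

## The problem

Sensory-evoked plasticity experiments record the same neurons repeatedly in
trials: each trial has a pre-stimulus baseline, one stimulus, and a response
period. The scientific question is whether the stimulus-evoked calcium
response of a population changes after a plasticity-induction protocol, and
whether the cortical territory activated by a single whisker (measured by
intrinsic optical imaging) expands or shrinks. caplast implements that
analysis chain as a tested library: raw per-ROI fluorescence in,
plasticity tables and activation areas out, with a ground-truthed synthetic
generator standing in for the microscope.

## The forward model behind the generator

`simulateCalciumSession()` is the package's definition of what the analysis
assumes about the data. Per ROI and trial, non-negative impulses `s[t]`
drive an AR(1) latent transient

$$c_t = \gamma\, c_{t-1} + s_t, \qquad
  F_t = F_{\mathrm{base}}\,(1 + c_t) + \varepsilon_t,\quad
  \varepsilon_t \sim \mathcal N(0, \sigma_F^2).$$

Spontaneous impulse counts are Poisson per frame at rate
`spontRate / frameRate` (frame-resolution thinning, matching the
frame-resolution detector); with probability `evokedProb` one evoked impulse
is placed at the stimulus-onset frame plus a latency jittered uniformly on
±`latencyJitterMs` and rounded to the nearest frame — one stimulus, at most
one evoked event per trial. Evoked amplitudes on post-induction trials are
multiplied by `plasticityFactor`, which is the ground truth the plasticity
stage must recover.

Defaults describe the target acquisition: 20 s trials (620 frames) at
30.98 Hz with the stimulus after a 5 s baseline, GCaMP6f-like decay
$\gamma = e^{-1/(0.4 \cdot 30.98)} \approx 0.922$ (400 ms indicator time
constant), sparse spontaneous activity (0.1 events/s), evoked probability
0.6, amplitude 0.5 ± 0.1 ΔF/F, baseline 100 a.u. with noise SD 2 (ΔF/F
noise ≈ 0.02, session SNR well above 5). Rates and amplitude scales are
realistic free choices of this package, not measured constants. One master
seed feeds independent substreams for spontaneous events, evoked flags,
jitter, amplitudes and noise, so changing the noise level never moves an
event — several tests rely on exactly this property.

What the generator does *not* emulate: pixel-level movies (no neuropil, no
segmentation errors), indicator nonlinearity and saturation, bleaching,
slow drift, and correlated network events. Passing recovery tests therefore
demonstrate the correctness of the algorithms under the model's
assumptions, not robustness to every pathology of real recordings.

## ΔF/F recipes

Two preprocessing recipes coexist because cerebellar and barrel-cortex
(S1) recordings are treated differently:

* `dffCerebellar()`: per trial, F0 is the 20th percentile of the raw trial
  trace; ΔF/F is smoothed with a centred 5-frame moving average and then
  re-referenced by subtracting the mean of the 5 frames before stimulus
  onset (which therefore averages to zero — an invariant the tests assert).
* `dffS1()`: the concatenated session trace is smoothed with a 51-point
  first-order Savitzky–Golay filter; F0 is the 1st percentile of the
  smoothed trace; ΔF/F = (smoothed − F0)/F0. F0 is taken per session, not
  per trial (the session-wide trace is the natural reading; per-trial
  baselines are the cerebellar convention). Because background subtraction
  precedes F0, a negative F0 inverts the signal; such ROIs are rejected
  rather than analysed.

All percentiles use one frozen convention: linear interpolation between
order statistics anchored at probabilities $(k-0.5)/n$ (`percentileMid()`,
`stats::quantile` type 5 — the convention of the numerical environment
these recipes come from). A sort-based oracle in the test suite pins it.

Baseline noise is `noiseSigma()`: the sample SD of every 5 s sliding window
(155 frames at 30.98 Hz, stride one frame — the most inclusive reading of
"each 5 s period"), compiled over the session, 1st percentile. SNR is the
95th percentile of all ΔF/F samples divided by σ. Savitzky–Golay edges use
shrink-fits (a line fitted over the truncated window): constants and ramps
are exact fixed points everywhere, which the simpler off-centre evaluation
of a full-window fit would not give.

Frame/time conversion is always `round(duration × frameRate)`: 5 s at
30.98 Hz is 155 frames; 12 frames is 387 ms; 1 s at 30 Hz is 30 frames.

## Event inference

`oasisAR1()` solves sparse non-negative AR(1) deconvolution by
pool-adjacent-violators merging (OASIS-style): pools carry the running
weighted least-squares height of a decaying segment, and adjacent pools
merge while the implied impulse between them falls below the minimum event
amplitude `sMin`. Sparsity comes only from `sMin = 3σ` — no L1 penalty —
because the amplitude threshold is the detection rule this pipeline
defines. The threshold is interpreted as a minimum inferred impulse size,
not a ΔF/F crossing: it modifies the deconvolution itself. A transient
carrying several threshold-crossing impulses on consecutive frames is
legitimate (event count grows with transient amplitude); the binary raster
used downstream caps each trial-frame at one event.

Two numerical choices deserve a note:

* **Terminal-frame censoring.** An impulse inferred on the last frame of a
  trial has no subsequent frame, so the decaying-transient evidence that
  distinguishes an event from a terminal noise spike cannot exist. Such
  detections are unfalsifiable and are never binarised (the amplitude is
  still reported). Without this rule, pure-noise sessions occasionally
  produce a single last-frame "event" that fabricates an evoked window.
* **Exactness.** On noiseless impulse trains the solver is exact; the test
  suite compares it against a dense non-negative least-squares oracle
  (`deconvMatrixOracle()`, the explicit lower-triangular AR(1) design
  matrix solved by `pracma::lsqnonneg`) on random instances: residual norms
  agree to 1e−6 and event supports are identical.

`estimateGamma()` provides the decay coefficient either from an indicator
time constant (`exp(-1/(tau * frameRate))`) or from the lag-2/lag-1
autocovariance ratio, clipped to (0.5, 0.999) with a warning — white noise
pins the estimate to the lower bound, which is a diagnosis, not a value.

## Evoked windows, responsive trials, persistent cells

`computePEvent()` turns the binary raster into the per-frame proportion of
trials with an event, `evokedWindow()` thresholds it at mean + 3 SD
(moments over *all* frames of the trial-time axis, pre-stimulus included —
no exclusion is defined) and selects, among maximal supra-threshold runs,
the longest starting at or after stimulus onset, earliest on ties.
Anchoring at the stimulus onset is the package's resolution of what to do
with a spurious pre-stimulus run: it cannot define an evoked window. The
absence of any qualifying run raises a classed error
(`caplast_no_evoked_window`) rather than returning a degenerate window.
Durations are frame counts converted to ms and rounded — 12 frames at
30.98 Hz is the canonical 387 ms window.

A trial is responsive iff it contains a binary event inside the half-open
window; a neuron is responsive iff any trial is; `persistentCells()` is the
set intersection across two conditions and gates every paired analysis.

Spontaneous events (`detectSpontaneousEvents()`) use the
derivative/prominence rules on smoothed cerebellar ΔF/F: candidate frames
where the first *and* second finite differences reach 0.04 (the
conjunctive reading is the stricter one; thresholds are per frame, since
no time unit is attached to them — both are exposed as parameters), peaks
with topographic prominence at least 0.1 ΔF/F within 200 ms of a candidate
(two-sided, configurable), onsets found by scanning backward until the
first difference drops below 0.05, and a 1 s window extracted per event
(zero-padded and flagged at trial edges).

## Plasticity quantification

`responseAUC()` is the mean ΔF/F over the response window times the window
duration in seconds — the AUC is by construction proportional to the mean,
and the tests assert the identity to 1e−12. Window frames are the 0-based
frames `f` with `startMs <= (f − onset)/rate·1000 < endMs` (half-open).
Named windows: default 0–700 ms, late 650–850 ms, and 0–1750 ms for
prolonged chemogenetically-enhanced responses; the late window uses the
same trial-averaging as the default one. `responseAmplitude()` is the
window maximum. AUC is reported in ΔF/F·s, recorded in output metadata.

`quantifyPlasticity()` trial-averages each neuron's responsive trials per
epoch (pre: up to 50 min before induction; post: up to 60 min after) and
keeps only persistent cells; `timeBinnedAUC()` assigns post-induction
trials to half-open 10-min bins by stimulus time (a trial at exactly
10 min belongs to the second bin), averages within cells then across
cells, and reports empty bins as missing rather than zero.
`normalizeByMouse()` divides each animal's condition response by its
baseline response (unweighted means over that animal's persistent cells)
and runs a one-sample t-test against 1; zero baselines exclude the animal,
zero-variance ratio sets are flagged as degenerate instead of tested.

## Movement and intrinsic signals

`motionBinary()` thresholds a caller-supplied frame-difference energy
series (frame 0 is non-moving by definition); `classifyTrials()` labels a
trial rest iff no movement falls in the inclusive ±400 ms guard around
stimulus onset — "at least 400 ms" reads as a closed bound — and flags
trials whose guard leaves the trial as unclassifiable. Video and imaging
are assumed sample-synchronous at 30.98 Hz.

For intrinsic stacks, `preprocessStack()` applies a Gaussian blur
(σ = 1 px default, configurable; the kernel is renormalised at image
edges so constants are fixed points) and 4× block-mean downsampling
(block means, not striding — deterministic and smoother). `drrTrial()`
averages a 1 s (30-frame) baseline R0, three 200 ms post-stimulus bins at
400–1000 ms, and sums the three (bin − R0)/R0 images. `activationMap()`
averages ≥30 trials, zeroes out-of-mask pixels, z-scores over in-mask
pixels only (including zeroed outside pixels would dilute the moments with
values that are artifacts of masking), thresholds z < −1.5 (activated
cortex darkens), median-filters the binary image with a 5×5
truncated-at-border majority vote, and normalises the activated pixel
count by the mask area. The median filter is applied to the binary image
and the count taken afterwards (filter-then-count); on a discrete disc it
necessarily erodes high-curvature boundary pixels, so exact pixel-count
checks live at the pre-filter binary, with the filtered count pinned to a
brute-force median oracle.

## Statistics

`selectAndRun()` implements the normality-gated decision table: Lilliefors
(via `nortest::lillie.test`) on each sample at α = 0.05; paired designs use
the paired t-test when both samples pass, Wilcoxon signed-rank otherwise;
unpaired designs add an F-ratio variance gate at α = 0.05 (the equal-
variance criterion is not otherwise specified; the F test is the simplest
frozen choice) to pick Student vs Welch, falling to the rank-sum test for
non-normal data; categorical tables use chi-squared without continuity
correction; factorial designs use fixed-effects two-way ANOVA with
interaction on balanced designs (interaction included; unbalanced designs
are out of scope). Samples with n < 5 cannot be tested by Lilliefors and
fall back to the non-parametric branch with a warning. Significance labels
are `*`, `**`, `***` at 0.05/0.01/0.001. Simulation in the test suite
holds the full procedure's type-I error on Gaussian nulls within
[0.03, 0.07] at nominal 0.05 over 2000 replicates.

## Problem sizes used by tests and the acceptance script

The suite exercises the pipeline at deliberately compact scales chosen to
keep the statistical checks sharp: recovery and null sessions of 20–60
trials × 310–620 frames at the default noise (session SNR ≈ 15), plasticity
recovery over 40 neurons in 4 simulated mice, null calibration over 500
six-mouse cohorts of 5 ROIs × 20 trials, intrinsic maps of 40–50 px images
over 30 trials, and 2000-replicate statistical calibrations. These sizes
are the package's own reproducibility choices; every number reported by
`scripts/acceptance.R` is recomputed from scratch at run time under the
seed passed on the command line.

## Known limitations

* The deconvolution is AR(1) only; AR(2) rise dynamics, joint noise
  estimation and spike-rate smoothing are out of scope.
* Motion correction is rigid, integer-pixel, whole-frame correlation; no
  subpixel or non-rigid registration.
* The S1 recipe's 51-frame smoothing spreads a transient's rise over many
  frames: frame-accurate event timing should be assessed on lightly
  smoothed ΔF/F, which is how the recovery tests measure it.
* Statistical wrappers cover the decision table only — no multiple-
  comparison correction and no mixed models.
* File formats are plain text (CSV + JSON sidecars) and TIFF; the CSV
  serialisation round-trips doubles exactly at 17 significant digits.
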