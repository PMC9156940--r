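---
title: "Methods: from sleep photometry to next-day maze behavior"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from sleep photometry to next-day maze behavior}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The scientific question

`nremlink` implements the analysis chain for experiments asking whether
spontaneous population activity of midbrain (VTA) neurons during sleep is
related to how exploratory an animal is the *next* day. The chain has five
measurement layers, each usable on its own:

1. **Sleep scoring** — classify EEG/EMG into Wake/NREM/REM in 5 s epochs.
2. **Photometry** — normalize fluorescence to ΔF/F, detect calcium
   transients, and summarize activity per vigilance state.
3. **Maze behavior** — port-zone visits, visit speed, escape metrics and
   novelty preference from 10 Hz tracking tables.
4. **Behavioral clustering** — a temporally regularized variational
   autoencoder + self-organizing map (SOM) that turns 10 s trajectory
   windows into 36 discrete behavioral clusters and per-trial occupancy
   vectors.
5. **Linking statistics** — join each day's sleep summary to the *next*
   day's behavior and compute per-cluster Pearson correlations (Bonferroni
   over 36), a quartile Mann–Whitney comparison of port-visit speeds, and
   coupling-recovery regressions.

Because the original recordings cannot be regenerated, every stage is
validated against a first-class synthetic-data generator with planted ground
truth.

# The synthetic world

`sim_config()` fixes the generative model; `sim_config_desk()` is the same
world scaled for desk runs (30 min rests instead of 4 h, 50 Hz photometry
instead of 400 Hz, REM latency scaled with the rest so REM exists in the
shorter recording).

**Hypnograms** are semi-Markov chains over Wake/NREM/REM with
truncated-exponential dwell times (Wake mean 4 min, NREM 8 min, REM 1.5 min
capped at 2 min — individual REM episodes are rarely longer than that) and
the grammar Wake→NREM, NREM→{Wake, REM}, REM→{Wake, NREM}. REM is forbidden
before the latency parameter (default 1 h of rest), reproducing the
NREM-first structure of early rest. Bout lengths are quantized to whole
epochs so bout durations sum exactly to the requested duration.

**EEG/EMG** are built per epoch from unit-variance band-limited noise:
delta-weighted (1–4 Hz) and high amplitude in NREM, theta-weighted
(4–10 Hz) with EMG atonia in REM, low-amplitude broadband with high EMG in
Wake. These are statistical stand-ins for scoring, not biophysical EEG.

**Photometry** is a baseline (100 a.u.) plus a polynomial bleaching drift,
white noise (SD 0.3 a.u.), and transients at state-dependent Poisson rates
(defaults Wake 4, NREM 2, REM 10 events/min — placeholders; published reports of
this preparation give no quantitative per-state rates) with a GCaMP6s-like kernel
`A(exp(-t/2) − exp(-t/0.2))` (peak-normalized). One deliberate deviation
from a pure Poisson process: onsets within `transient_min_sep = 3` s of the
previous kept onset are thinned (a hard-core refractory rule). With a ~2 s
kernel width, closer onsets are physically unresolvable as separate events —
they produce a single fluorescence peak — so counting them as distinct
ground truth would make the generator contradict its own recoverability
contract (≥ 90 % sensitivity for well-isolated events at 5× noise).

**Maze trials** alternate locomotion between random waypoints, pauses, and
port approaches. Each visit is drawn *slow* (investigative bobbing at the
port, nose pointed at it; mean window speed ≈ 5 cm/s) or *fast*
(pass-and-go sweep, ≈ 25 cm/s) with `P(slow) = logistic(drive)`. The motif
speed governs only the −0.5 s…+2.5 s visit window (travel before and after
runs at ordinary ~15 cm/s locomotion): the planted coupling must act on the
slow-visit probability only, not on overall locomotion speed, mirroring the
finding that generic speed clusters were uncorrelated with sleep activity.
Visited ports concentrate geometrically around the correct port
(`port_bias = 0.5`), a realism stand-in for spatial memory. Every trial ends
with the nose entering the correct escape pod; that escape entry carries no
motif label (its visit window mixes the approach with sitting in the pod).

**The planted link**: in `synth_multiday_experiment()`, the drive of day
`d`'s trials equals `coupling ×` the ground-truth standardized NREM
transient amplitude of day `d − 1`'s rest (day-1 trials get drive 0).
Standardization is the same within-mouse z-score plus across-day linear
detrend that `standardize_across_animals()` applies to measured data.

What a green test does *not* establish: the generator has none of the
nonstationarity, motion artifacts, electrode drift, or behavioral
idiosyncrasy of real recordings; it validates the *pipeline's* correctness
and power at the stated effect sizes, not performance on any real dataset.

# Numerical and procedural choices

**Sleep scoring.** The customary workflow is commercial software plus
manual verification; we substitute an explicit rule with auto-calibrated
thresholds: Wake if EMG RMS exceeds the midpoint of a deterministic
2-cluster split of log EMG RMS; else NREM if delta power > 0.45 of
broadband (0.5–25 Hz) power; else REM if theta/delta > 1.5 with EMG below
the 25th percentile of NREM-candidate EMG. Unclassifiable epochs inherit the
previous label (first epoch → Wake) and single-epoch islands merge into the
preceding bout. Spectra are Hann-windowed periodograms per 5 s epoch
(0.2 Hz resolution).

**Photometry.** ΔF/F = (F_r − F_m)/F_m with a median baseline (whole
recording, or 10 s pre-stimulus). Long recordings are detrended by
subtracting a fitted polynomial (degree 2 by default: it captures
monotone photobleaching without eating transients) and adding back the median. The quiet period (250 s used
to calibrate detection) is found automatically as the minimum-rolling-SD
window fully inside NREM; the manual option (an explicit interval) remains.
Detection keeps strict local maxima with topographic prominence > 3× the
quiet SD and half-prominence width ≥ 1.5 s; extents are prominence base
intervals clipped to ±10 s and truncated at inter-peak minima. Half-width is
measured at half-*prominence* (robust to baseline offset) rather than
half-maximum. Before detection the pipeline low-passes ΔF/F with a 0.25 s
boxcar: indicator kinetics are far slower than the sampling rate, and
unsmoothed sample noise truncates the half-width walk (we measured ~0.9 s
apparent widths for true ~2 s events), which would make the 1.5 s artifact
filter reject genuine transients. `detect_transients()` itself stays pure —
it analyzes exactly the trace it is given, which keeps it comparable to the
brute-force oracle in the test suite. The 405 nm isosbestic correction is
deliberately absent: the channel's purpose is standard but no single
correction procedure is, so none is silently imposed.

**Windows and clustering.** Trials are featurized at 10 Hz into 7
dimensions (maze-centered body-center x/y, nose and tail relative to
center, body area), z-standardized with pooled training statistics, and cut
into overlapping 10 s windows (100 steps × 7 features, stride 1 s). The
cluster model is a dense VAE (700 → 128 → 4-dim Gaussian latent, mirrored
decoder) whose latent is clustered by a 6 × 6 SOM, trained by minibatch
Adam on a composite loss: reconstruction + KL (scaled per input element, so
the default weight 1 behaves like a mild β), a SOM commitment term with an
annealed Gaussian grid neighborhood (σ 2 → 0.5), a latent smoothness
penalty between consecutive windows, and a one-step *linear* latent
forecast (weights 1/1/1/0.1/0.1). A linear predictor replaces the reference
architecture's LSTM: at desk scale the forecasting term only regularizes
latent dynamics, and a linear map does that deterministically with far
fewer parameters. The train/validation split (85/15) is at *trial*
granularity so overlapping windows never leak across the split; early
stopping tracks validation reconstruction error. Inference uses the
posterior mean, so labeling is deterministic. Backpropagation is
hand-written matrix algebra, verified against finite differences in the
test suite; training on ~5–7 k windows for 30 epochs takes ~30 s on one
CPU. Labels are 1…36 in the R API.

**Linking statistics.** Rows are (mouse, day, trial), pooled across mice
after per-mouse standardization of activity. Per-cluster Pearson tests are
two-sided with Bonferroni over 36; the quartile comparison ranks mouse-days
by activity, pools visit speeds in the lower and upper quartiles, and uses
a two-sided Mann–Whitney U (exact for small tie-free samples).
`recover_coupling()` regresses the per mouse-day logit slow-visit fraction
(empirical logit at the 0/1 boundaries) on true standardized NREM activity,
with a percentile bootstrap CI over mouse-days.

# Design choices where practice varies

* Dwell distributions, transient rates/amplitudes and EEG band weights are
  uncalibrated placeholders exposed in `sim_config()`; no quantitative
  values are available to pin them to.
* "Standardized between animals" is implemented within-animal (z-score per
  mouse); per-day (not per-trial) values feed the activity axis.
* "6 degree deviation" is read as a half-angle (12° wedge), configurable.
* The pod "door line" is a radial crossing of the outer zone radius within
  the port wedge; the pod center sits on the arena edge so part of its 3 cm
  approach perimeter is reachable without crossing the door line.
* "Turned the nose away" is a > 90° deviation of the 3-frame nose heading
  from the nose-to-pod bearing for ≥ 2 consecutive frames inside the
  perimeter.
* Visit-speed windows that overrun the trial are dropped (flagged
  `unassigned`), not truncated.

# Known limitations

* The reconstruction floor of the 4-dim latent on this generator is ~0.5
  (standardized MSE); the model compresses position coarsely, so behavioral
  motifs spread over several position-specific clusters. Consequently a
  planted slow/fast coupling shows up as *several* significantly correlated
  clusters with the right signs (slow-enriched positive, fast-enriched
  negative, REM-based null on average) rather than the exactly-two-cluster
  count reported from real recordings — that count is data-specific
  (see the acceptance suite, where this is asserted and documented as a red
  criterion rather than relaxed).
* Trials within a day share one activity value; the trial-level correlation
  rows are therefore not independent, exactly as in the field's standard trial-level convention.
  Null simulations in the test suite quantify the resulting false-positive
  behavior instead of pretending the rows are independent.
* The generator's EEG is statistically, not biophysically, state-typical;
  scoring accuracy on it (>90–99 %) is an upper bound on real-data
  performance.
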