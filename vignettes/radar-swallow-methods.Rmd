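---
title: "Methods: radar-based respiration and swallowing-pause detection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: radar-based respiration and swallowing-pause detection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The measurement model

A pulse-coherent radar transmits phase-controlled pulses every 0.01 s and
records, per 1 mm range bin between 0.2 and 0.7 m, the amplitude and
wrapped phase of the reflection.  For a reflector at distance $R$ the
received phase obeys

$$\Delta\phi = \frac{4\pi\,\Delta R\, f}{c},$$

so distance changes far below the 1 mm range resolution are visible as
phase changes: at $f = 60$ GHz, 1 mm is about $144^\circ$; the sensor's
documented $6.1^\circ$ phase repeatability corresponds to about 42 µm.
Sensitivity is proportional to $f$, which is why a millimeter-wave carrier
resolves the sub-centimetre chest motion of breathing where time-of-flight
ranging cannot.

`estimate_displacement()` composes four steps, each exported on its own:

1. `select_range_bin()` — the chest is taken to be the *mode* over frames
   of the per-frame argmax-amplitude bin.  The mode (rather than a
   per-frame argmax) suppresses isolated amplitude outliers; posture is
   assumed fixed over the processed interval.  Ties resolve to the lowest
   bin, both within a frame and between tied modes, so the rule is total
   and deterministic.  Bin indices are 1-based, as everywhere in R.
2. `extract_phase()` — the wrapped phase series at that bin, values in
   $[0, 2\pi)$.
3. `unwrap_phase()` — a consecutive difference whose magnitude *strictly
   exceeds* $\pi$ is declared a wrap crossing and corrected by $2\pi$; a
   difference of exactly $\pi$ is left untouched.  The output is congruent
   to the input modulo $2\pi$ elementwise and its increments never exceed
   $\pi$ in magnitude.
4. `phase_to_displacement()` — the linear conversion above, applied to
   increments and anchored at zero for the first frame: the relation is
   differential, so the absolute standoff is discarded.

No filtering is applied to the estimated trace: at this phase-noise level
the raw trace is clean enough for feature extraction, and filtering would
smear the very plateaus the classifier must find.

**Sign convention.** Traces are *expiration-positive*: the chest recedes
from a front-mounted radar while exhaling, so an increase in radar-to-chest
distance is reported as positive displacement.  All downstream slope logic
(`respiratory_pattern()`) assumes this convention.

**Validity limit.** Unwrapping is correct only while the true per-frame
motion stays below a quarter wavelength, $c/(4f) \approx 1.24$ mm per
10 ms frame at 60.5 GHz.  Faster motion aliases by half a wavelength; the
test suite pins both sides of the boundary (1.2 mm recovers, 1.3 mm
wraps).  Breathing at physiological amplitudes and rates stays one to two
orders of magnitude below the limit.

**Conversion frequency.** The sweep bandwidth is 57–64 GHz with centre
60.5 GHz; the conversion uses 60.5 GHz by default and
`radar_config(center_frequency =)` exposes the choice, since published
sensitivity figures are sometimes quoted at a round 60 GHz.

## Windowing, labels, features

Windows are 4 s (400 frames) slid every 1 s (100 frames); a window's label
is the activity at its midpoint — defined as the sample at index $W/2$,
i.e. 2 s into a 4 s window — *except* that a swallow interval contained
whole inside the window (both endpoints inside) forces the label `swal`.
The containment override exists because deglutition apnea is short
(0.3–1.5 s): the midpoint alone would miss most windows that clearly show
the pause.  Windows whose midpoint no annotated interval covers are
excluded from datasets (count reported); if two swallow intervals fall in
one window (possible only for 6 s windows) it is still one `swal` window.
The commanded breath-hold intervals are shifted by the 0.5 s instruction
delay — the lag between the on-screen command and the subject's response —
with the end shifted equally so duration is preserved.

The classifier input is a 40-vector, four families of ten.  The families
are dictated by what separates the three classes; the concrete ten per
family are this package's design (documented here because only the family
ideas and the count of ten are externally fixed):

* **Movement range** (`range_01..10`): symmetric inter-quantile spans
  $q_{50+5k} - q_{50-5k}$, $k = 1..10$, so $k=5$ is the interquartile range
  and $k=10$ is max − min.  Breath-holds collapse every span toward zero;
  trimmed spans resist noise spikes.  Units: mm.
* **Autocorrelation** (`ac_01..10`): mean-removed, variance-normalised
  autocorrelation at lags $0.4, 0.8, \ldots, 4.0$ s — a grid spanning the
  physiological cycle range.  A lag at or past the window length returns 0
  (zero-padding convention); a zero-variance window returns all zeros.
* **FFT** (`fft_01..10`): magnitudes of the ten lowest positive-frequency
  bins of the mean-subtracted window (0.25–2.5 Hz at the default window),
  i.e. exactly the respiratory band; the mean subtraction removes DC.
  Magnitudes (not powers) were chosen so the family scales linearly with
  amplitude, matching the range family.
* **Histogram** (`hist_01..10`): fractions of samples in ten equal-width
  bins between the window's min and max.  Fractions (not counts) make the
  feature window-length independent, which the window-size sweep needs.
  The top bin is right-closed so the maximum is counted; a flat window puts
  all mass in bin 1 by convention, preserving the hold-versus-breathing
  contrast (a uniform spread would erase it).  Breathing windows show the
  characteristic two-peak (arcsine-like) shape from the dwell at the
  turning points.

Range and FFT families scale with the signal amplitude; autocorrelation
and histogram are amplitude-invariant — a property the tests enforce.

`general_features()` provides the broad-catalogue comparison arm (~60
standard time-series statistics with dataset-level constant/duplicate
removal via `drop_constant_features()`).  No pre-installed R library
offers an exhaustive extractor of the tsfresh kind, so the catalogue is
authored here; its exact length is recorded, not contractual, and
reproducing any particular published feature count is a non-goal.

## Classification and evaluation

Class imbalance (respiring dominates roughly 8:1 over swallowing) is met
with balanced weights $w_c = N/(k\,n_c)$ at training time and
macro-averaged F1 — the unweighted mean of per-class F1 — at evaluation
time, so the rare swallow class counts as much as breathing.  Precision,
recall and F1 are 0 by convention when undefined (a class never
predicted).

Models: a random forest (`ranger`; trees, depth, features-per-split) and
SVMs with linear or RBF kernels (`e1071`; cost, kernel width).  The
default search grids are $C \in \{0.1, 1, 10, 100\}$, kernel width
$\gamma \in \{0.1, 1, 10\} \times 1/(p \cdot \mathrm{var}(X))$, trees
$\{100, 300\}$, depth $\{\infty, 5, 10\}$, features-per-split
$\{\sqrt p, \log_2 p\}$ — the hyperparameters named for these model
families, with grids chosen as conventional coarse ladders.

Cross-validation is **grouped by subject** (leave-one-subject-out by
default, grouped $k$-fold behind a flag): windows of one subject are
heavily autocorrelated, and subject leakage would inflate every score.
Held-out predictions from all folds are pooled into a single confusion
matrix per grid point and macro-F1 computed from it; per-fold averaging
would be unstable whenever a held-out subject lacks a class.  Tree
ensembles are seeded and single-threaded, and prediction tie-breaking is
seeded too, so identical runs give identical scores.  The RBF-kernel +
general-features combination is allowed but not a default (cost grows
quickly with the catalogue).

## What the simulator emulates — and what it does not

`generate_motion()` produces displacement as a raised-cosine cycle:
expiration rises from $-A/2$ to $+A/2$ over the expiratory fraction of the
cycle, inspiration falls back, with zero derivative at both turning points.
This matches the sine-like shape of real chest traces while producing the
short end-expiration/end-inspiration dwells that give breathing windows
their two-peak histogram.  The cycle is *quasi*-periodic: instantaneous
period and amplitude are modulated by smooth AR(1) processes (correlation
time of one cycle) with coefficient of variation 0.10 each — typical
breath-to-breath variability of resting adults.  The modulation clock only
runs while breathing, so plateaus stay exactly flat before noise.

Subject parameters are drawn once per synthetic subject: period uniform in
[2.5, 5] s and amplitude in [2, 8] mm (the reported physiological ranges),
inspiratory fraction in [0.35, 0.45] (expiration is longer than
inspiration at rest), swallow-pause duration in [0.3, 1.5] s, standoff in
[0.30, 0.60] m.  Defaults elsewhere: motion jitter 0.05 mm, radar phase
noise 6.1°, amplitude falloff across range bins Gaussian with a 3-bin
standard deviation (any peaked profile works with mode-of-argmax
selection), and an optional random-walk posture drift, off by default.

Holds freeze the cycle clock after the 0.5 s instruction delay.  Swallows
wait until the realised cycle phase reaches `swallow_cycle_phase` (default
0.35 of the cycle, i.e. mid-to-late expiration) and then freeze for the
pause duration.  Where in the cycle swallows occur is genuinely open —
instruction timing does not pin it — so it is a parameter; the default
sits inside the expiration limb because the dominant observed pattern in
healthy adults is exhalation–swallow–exhalation, which requires the pause
to interrupt expiration rather than end it.

The trial template (`default_schedule()`) is breathe 12 s, hold 5 s,
breathe 10 s, one swallow, breathe 10 s: with ten trials per subject this
yields the characteristic strong class imbalance (roughly 27 respiring to
5 hold to 3–4 swallow windows per trial).

What passing tests on this simulator do **not** show: robustness to body
movement and posture change (the drift component is off by default and
never resembles real gross motion), multipath or clothing effects
(deliberately out of scope), sensor-specific band-sensor artifacts, or
real inter-subject variability beyond the parameter ranges above.  Clean
simulation is *easier* than real data: correlations with the reference
channel come out near 0.99 where real recordings average ~0.7, and
classification scores well above really achievable ones.  The synthetic
results validate the machinery, not the field performance.

## Validation computations

The band-sensor reference channel is modelled as gain × displacement +
white noise and cleaned with a zero-phase order-4 Butterworth low-pass at
5 Hz.  `signal::butter` supplies the coefficients; the forward–backward
pass is implemented with odd-reflection padding and steady-state initial
conditions (the standard `lfilter_zi` construction), because naive
forward–backward filtering from zero initial state shows edge transients
that violate the unit-DC-gain contract the tests enforce.

Waveform agreement is scored as zero-lag Pearson correlation of
mean-removed 5 s respire-only segments (up to three per trial); whether a
published correlation of this kind is zero-lag or peak-lag is usually
ambiguous, so a max-over-±lags variant sits behind the `max_lag` flag to
absorb fixed sensor delay.  Constant segments are indeterminate (`NA` with
a warning).

`respiratory_pattern()` automates the visual pre/post-swallow call: the
least-squares slope over 0.8 s before onset and after offset, classified
expiration / inspiration / indeterminate against a threshold defaulting to
10 % of the trace's median absolute slope — the threshold must scale with
breathing amplitude or quiet breathers would always be indeterminate.
The 0.8 s span is configurable; it needs to be well under half a cycle so
the slope does not straddle a turning point.

## Numerical choices and degenerate inputs

* Quantiles use R's default type-7 interpolation.
* Phases are validated into $[0, 2\pi)$ at container construction; the
  renderer re-wraps after adding phase noise.
* A trace shorter than one window yields an empty window set with a
  warning; a constant window yields all-zero range/autocorrelation/FFT
  features and the degenerate histogram.
* An exactly-$\pi$ phase difference is *not* corrected (strict
  inequality), pinning the boundary case.
* Random-forest fits and predictions are seeded with one worker thread;
  all simulator randomness flows from integer seeds derived from the
  master seed with small prime multipliers, kept under $2^{31}$.

## Problem sizes

The test suite exercises the full pipeline at 19 subjects × 10 trials
(≈ 7,000 windows) for the cohort classification and window-size
experiments, with a single forest configuration (300 trees, unlimited
depth, $\sqrt p$ features per split) under leave-one-subject-out
validation; grid-search behaviour is tested separately on small separable
data.  Round-trip and unwrapping properties run over 50 random profiles
and 1,000 random ramps respectively.  These sizes were chosen to give
stable scores (hundreds of windows per class) at ordinary desktop
runtimes.

## Known limitations

* Single reflector: no multi-target tracking or range migration; the
  range-bin mode assumes fixed posture per processed interval.
* The window-size experiment on clean simulation shows only a small
  difference between 2 s and 4 s windows: with little noise, a contained
  pause fills a larger fraction of a short window, which offsets the lost
  periodicity evidence.  On real, noisier data short windows degrade more
  sharply; the simulator's cleanliness caps how much of that effect can
  be reproduced.
* Swallow detection hinges on the pause plateau; swallows without a clear
  apnea (or masked by body movement) are not represented in the generator
  and would not be detected.
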