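# respirad

Unconstrained respiratory measurement and swallowing-pause detection with
millimeter-wave radar.

## The problem

Breathing stops briefly while the airway closes during the pharyngeal phase
of swallowing (*deglutition apnea*).  The respiratory phase immediately
around that pause matters clinically: an inspiration right before or after
it raises the risk of aspiration, a major cause of pneumonia in older
adults.  Detecting the pauses without body-worn sensors would allow routine
monitoring during meals.

A pulse-coherent millimeter-wave radar pointed at the chest can do this.
The chest moves less than 10 mm with respiration, but a radial distance
change ΔR of the reflecting surface appears as a phase change of the
received pulse,

    Δφ = 4π · ΔR · f / c,

so at a 60 GHz carrier a 1 mm movement is ≈ 144° of phase, and the sensor's
6.1° phase noise floor corresponds to ≈ 42 µm of distance — easily fine
enough to resolve breathing.

`respirad` implements the whole processing chain, for researchers in
non-contact vital-sign sensing:

1. **Displacement estimation** — select the target range bin as the mode of
   per-frame argmax amplitudes, extract its wrapped phase, unwrap
   (correcting jumps that exceed π), and convert phase increments to
   millimetres (`estimate_displacement()`).
2. **Windowing and labels** — 4 s windows (400 frames) slid every 1 s,
   labelled respiring / breath-hold / swallow by the activity at the window
   midpoint, with a contained swallow interval overriding the midpoint rule
   (`build_dataset()`).
3. **Designed features** — a 40-value vector per window: 10 symmetric
   inter-quantile movement ranges (the IQR generalised), 10 autocorrelation
   lags (0.4–4.0 s), the 10 lowest positive FFT magnitudes, and a 10-bin
   waveform histogram (`designed_features()`); plus a broad general
   time-series feature catalogue (`general_features()`).
4. **Class-weighted classification** — random-forest and SVM models with
   balanced class weights `N/(k·n_c)`, tuned and scored by macro-averaged
   F1 under leave-one-subject-out cross-validation (`tune_and_train()`,
   `evaluate()`, `macro_f1()`).
5. **Validation tools** — zero-phase order-4 Butterworth (5 Hz) for a
   band-sensor reference channel, zero-lag waveform correlation, and
   automated pre/post-swallow respiratory-pattern calls
   (`lowpass_reference()`, `cross_correlation()`, `respiratory_pattern()`).

Because recordings of human subjects are not openly available, the package
ships a first-class synthetic generator (`subject_profile()`,
`generate_motion()`, `render_sweeps()`, `simulate_cohort()`): quasi-periodic
raised-cosine breathing (period 2.5–5 s, amplitude 2–8 mm, ~10 % breath-to-
breath jitter), commanded breath-holds with a 0.5 s instruction delay, short
swallow plateaus (0.3–1.5 s) inserted in the expiration limb, rendered into
radar sweeps (0.2–0.7 m at 1 mm resolution, 0.01 s frames) with 6.1° phase
noise.

## Worked example

```r
library(respirad)

p <- subject_profile(seed = 42)
p
#> <subject_profile> T = 4.79 s, A = 7.62 mm, insp 0.38, pause 1.30 s, standoff 0.49 m

# one commanded trial through the full radar pipeline
sim <- simulate_trial(p, measure = "radar", seed = 42)
cor(sim$trace$values, sim$truth$values)   # radar estimate vs true motion
#> 0.9999
estimate_respiratory_cycle(sim$trace)     # autocorrelation peak, seconds
#> 4.77

# a small cohort, end to end
rec <- simulate_cohort(6, 4, seed = 42, measure = "radar")
ds  <- build_dataset(rec)
ds
#> <window_dataset> 875 windows of 4 s from 6 subjects (resp:679, hold:120, swal:76)
ft  <- designed_feature_table(ds)
fit <- tune_and_train(ft[, -(1:3)], ft$label, ft$subject,
                      train_config("tree-ensemble",
                                   grid = data.frame(trees = 300, depth = 0,
                                                     mtry_rule = "sqrt")))
fit$cv_report
#> Confusion matrix (Ans. rows, Pred. columns):
#>       pred
#> true   hold resp swal
#>   hold  119    1    0
#>   resp    2  665   12
#>   swal    4   34   38
#>      precision recall    f1 support
#> hold     0.952  0.992 0.971     120
#> resp     0.950  0.979 0.964     679
#> swal     0.760  0.500 0.603      76
#> macro-averaged F1: 0.846
```

The numbers mean: the radar-derived trace is essentially the true chest
motion (r ≈ 1 when per-frame motion stays under a quarter wavelength);
breath-holds are nearly perfectly separable from breathing by movement
range alone; swallow windows are the hard class — their brief plateau looks
like ordinary breathing whenever labelling context and window placement
disagree — exactly the difficulty ordering seen on real recordings.  With
the full-size cohort (19 subjects × 10 trials) the leave-one-subject-out
macro-F1 exceeds 0.9 (see the acceptance suite).

A thin CLI over the same functions is installed at `inst/cli/respirad`
(`simulate`, `estimate`, `featurize`, `train`, `validate` subcommands).

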