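---
title: "Assessing freezing of gait from wearable gyroscopes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing freezing of gait from wearable gyroscopes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fogatsf)
```

## The measurement problem

Freezing of gait (FOG) is a brief, episodic arrest of forward progression of
the feet despite the intention to walk. It is common in Parkinson's disease,
hard to elicit on demand in a clinic, and under-reported by questionnaires,
which measure the patient's *perception* of freezing and suffer recall bias.
Body-worn inertial sensors offer an alternative: record angular velocity at
both feet and the hip continuously, detect freezing automatically, and
summarize each person's burden as the **percent of active time spent
freezing** (%ATSF),

$$\%\mathrm{ATSF} = 100 \times
  \frac{\text{time spent freezing}}{\text{active (non-sedentary) time}}.$$

`fogatsf` implements that pipeline end to end: sensor stream I/O and
resampling, sedentary-time exclusion, a two-stage probabilistic FOG
detector, event post-processing, sample-wise agreement scoring against
expert interval annotations, and nonparametric cohort statistics. Because no
patient recordings ship with the package, it also includes a synthetic
cohort generator with exact ground truth and an imperfect-rater emulation,
so every stage is exercised by reproducible simulation.

## Pipeline stages and their parameters

### Common analysis rate

All analysis runs at 100 samples/s. Recordings at a higher rate (e.g.
128 Hz hardware) are downsampled with `resample_sinc()`: convolution with a
Hann-tapered sinc kernel cut off at the target Nyquist frequency, kernel
half-width 64 source samples, reflection padding at the edges, and per-sample
renormalization of the kernel weights so a constant signal is reproduced
exactly. Output timestamps are anchored at the recording's `t0_s` with
`floor((n - 1) \cdot r) + 1` samples for rate ratio `r`; these conventions
are arbitrary where the filter family alone does not fix them, and are
chosen for determinism. Sub-10 Hz content — everything the detector uses —
passes with amplitude error below 1%. Upsampling is refused rather than
invented.

### Sedentary exclusion

A hip-worn gyroscope distinguishes genuinely active time from sitting.
`compute_activity_mask()` smooths the *total hip angular speed* (the sum of
absolute angular velocity over the three axes) with a centered 20 s moving
average and calls a sample active when the smoothed value is strictly above
1 deg/s. Samples at exactly the threshold are sedentary, matching the
definition of sedentary time as *less than* 1 deg/s. The moving-average
window shrinks at the session edges rather than padding with invented data.
A per-axis variant (any axis above threshold after smoothing) is available
behind `per_axis = TRUE` but is off by default, because the summed total is
the stated definition. The 20 s window means a sitting bout shorter than
~10 s cannot be excluded — an accepted resolution limit. Crucially, a person
sitting and bouncing a leg keeps a quiet hip: foot motion alone never makes
time "active".

### Two-stage FOG detection

The per-foot detector is a fully specified stand-in that preserves the
two-stage structure of probabilistic FOG detection: derive per-sample
*event* flags, then fuse them with a probability filter.

1. **Zero-velocity flags** (`zero_velocity_flags()`): RMS of the gyroscope
   magnitude over a centered 0.25 s window strictly below 10 deg/s. This
   fires in normal stance phases as well as in motionless (akinetic)
   freezing — deliberately weak evidence on its own.
2. **Trembling flags** (`trembling_flags()`): over a centered 2 s window,
   periodogram band power in the freeze band (3–8 Hz) versus the locomotor
   band (0.5–3 Hz), summed over the three gyro axes, each axis implicitly
   window-mean-detrended. A sample is flagged when freeze power exceeds
   twice the locomotor power *and* the total exceeds 10 (deg/s)². Band
   power is computed on the signed axis components, not on the vector norm:
   the norm of a symmetric oscillation is rectified, which would move a
   genuine 5 Hz tremor to 10 Hz and out of band. The power floor keeps
   near-silent signals (noise, akinetic feet) from producing spurious
   ratios. Samples within half a window of an edge inherit the nearest
   full-window decision.
3. **Forward probability filter** (`pfog_forward_filter()`): a two-state
   hidden process (noFOG/FOG) with symmetric self-transition probability
   0.99 per sample observes the flag pair as one of four categories. The
   default emission table

   | state | (0,0) | (zv) | (tremble) | (both) |
   |-------|------:|-----:|----------:|-------:|
   | noFOG | 0.60  | 0.25 | 0.10      | 0.05   |
   | FOG   | 0.10  | 0.20 | 0.20      | 0.50   |

   makes simultaneous zero-velocity + trembling strongly FOG-like, trembling
   alone moderately FOG-like (ratio 2:1), and zero-velocity alone slightly
   *anti*-FOG (0.20 vs 0.25), because ordinary stance produces it
   constantly. The filter is causal (forward only, no smoothing), starts
   from prior P(FOG) = 0.01, and is renormalized at every step. One
   consequence is intentional and worth stating plainly: with these
   emissions a purely akinetic freeze — zero-velocity evidence only — never
   accumulates enough likelihood to cross the threshold, so the detector is
   essentially trembling-driven and systematically under-reports total
   burden. That asymmetry mirrors how sensor-based %ATSF is reported lower
   than video-based %ATSF by human raters who count both phenotypes.

A sample is called FOG when **either foot's** probability is strictly above
0.7. Runs of calls become half-open events, and events separated by strictly
less than 2 s are merged transitively (`merge_events()`); a gap of exactly
2 s is kept. Merging operates on the full timeline *before* sedentary
restriction, because exclusion is an analysis-time filter; %ATSF then counts
only active samples of the merged events.

### Scoring

`confusion()` counts sample-wise agreement between sensor calls and rater
intervals over active samples only; `accuracy_pct()` is
$100 (tp + tn)/(tp + tn + fp + fn)$. Sensitivity and specificity are
reported alongside although accuracy is the headline figure — they cost
nothing and expose detector bias. For the in-person visit only task time is
analyzed: samples outside task intervals are dropped before scoring, and
per-task metrics are computed on each task's own samples. Undefined metrics
(a task with no active samples, an empty event list) are reported as
missing values, never as zeros, so cohort means are not biased.

### Cohort statistics

`shapiro_wilk_p()` records the normality gate; %ATSF distributions are
heavily right-skewed (many subjects near zero), so rank-based correlation is
the appropriate choice throughout. `spearman_rho()` is the Pearson
correlation of average-ranked values (ties get their mean rank), with
pairwise-complete deletion; `correlation_matrix()` assembles the
visit-level and IADL-level matrices with unit diagonal and `NA` for
undefined cells. No p-values are attached to the headline matrices.

## What the synthetic cohort emulates

`simulate_cohort()` generates `n = 19` subjects by default, severities
spaced over [0, 1] with the two lowest at exactly 0 — so the cohort always
contains people who never freeze, and zero-burden rows must flow through the
pipeline as valid data, not errors.

Per subject and session the generator produces piecewise-stationary signals
at 100 Hz:

* **Walking/IADL/home segments**: alternating half-sine foot swing pulses
  (cadence 1.8 steps/s, peak 200 deg/s, IADL slightly attenuated) with a
  hip oscillating in a 5–20 deg/s band.
* **Sitting**: hip at rest; occasional single-foot 2 Hz, 20 deg/s
  leg-bounce bursts that must *not* defeat the sedentary filter.
* **FOG episodes**: Poisson arrivals at `1.5 × severity` per active minute
  within movement segments; log-normal durations with mean 5 s (sdlog 0.5);
  70% trembling phenotype (5 Hz, 25 deg/s foot oscillation on both feet),
  30% akinetic (feet near-motionless); the hip stays active during both, so
  freezing time counts as active time. Arrivals beginning inside an earlier
  episode are dropped so truth intervals never overlap; the raw arrival
  count is retained for the Poisson-rate check.
* **Noise**: additive Gaussian noise, σ = 0.3 deg/s per channel — a typical
  MEMS gyroscope noise floor. This value matters: the sum of three absolute
  noise channels has mean ≈ 2.4σ, so a noise floor near 1 deg/s would make
  quiet sitting register as "active" at the 1 deg/s threshold and the
  sedentary filter could never work.
* **Rater emulation** (`emulate_rater()`): ground-truth boundaries jittered
  with σ = 0.2 s, episodes shorter than 0.5 s dropped — an expert who is
  accurate but not sample-exact.
* **Questionnaire analog**: `round(28 (0.3 · severity + 0.7 · u))` with
  uniform noise `u`, deliberately noise-dominated so the cohort analysis
  can demonstrate the dissociation between self-report and observed
  freezing.

The default visit plan is three clinic walking/turning tasks (120 s each),
three movement IADL tasks (180 s each) and a 600 s sitting task; the home
plan is three "days" of ~30 min alternating movement and sitting. These
desk-scale durations — roughly 25 min of visit and 90 min of home wear per
subject — keep a full 19-subject simulation plus detection in the
low-minutes range while leaving hundreds of episodes across the cohort.

What the generator does **not** emulate: biomechanically realistic gait
(no stride variability, turning dynamics, or festination), gradual
transitions between activities, sensor drift or dropout, accelerometer
content, and any correlation between phenotype and severity. Passing tests
therefore demonstrate that the pipeline's logic and statistics are correct
under the stated signal model — not that the detector would achieve the
same figures on real patient data.

## Numerical and design choices

* All randomness flows from one integer seed; per-subject and per-stream
  seeds are derived by fixed offsets, so any single artifact (a session, a
  rater track) can be regenerated in isolation.
* Half-open `[start, end)` intervals everywhere, rasterized with a 1e-9
  sample-unit tolerance so second-valued boundaries are not split by
  floating-point drift; rasterizing detector events and rater annotations
  uses the same code path.
* Rater (video) intervals are **not** merged with the 2 s rule — merging
  models a property of the sensor pipeline, not of expert review.
* The forward filter's 3-step hand recursion, and an exhaustive
  path-enumeration oracle over all 1024 length-5 observation strings, pin
  the recursion to 1e-12.
* Band power uses the analysis window's own Fourier frequencies
  (resolution ≈ 0.5 Hz at 2 s); the locomotor band is `[0.5, 3)` Hz and the
  freeze band `[3, 8]` Hz so no bin is counted twice.
* `merge_events()` is idempotent and order-insensitive; property tests
  assert the fixpoint against brute-force repeated pairwise merging.
* Visit scoring restricts to task intervals; inter-task transition time is
  excluded, and the sitting task contributes only its (few) active samples.
* Home %ATSF pools all home recordings after sedentary exclusion rather
  than averaging per-day values.

## Known limitations

* The detector is a documented stand-in: it reproduces the two-stage
  events-then-probability architecture and the 0.7/2 s/1 deg/s/20 s
  analysis constants, not any particular published implementation's
  numerics. Orientation/navigation processing is omitted entirely.
* Akinetic freezing is invisible to the default emission table (see above).
  On synthetic cohorts this caps the rank correlation between detected and
  total injected burden — with a 70/30 phenotype mix the per-subject
  binomial share adds rank noise on top of an otherwise near-perfect
  (ρ ≈ 1) recovery of trembling burden.
* Sample-wise accuracy is dominated by true negatives at realistic burdens;
  it is reported because it is the field's headline metric, but
  sensitivity/specificity and %ATSF carry the diagnostic content.
* The activity mask is computed per contiguous recording; multi-bout home
  data are treated as one stream per file.
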