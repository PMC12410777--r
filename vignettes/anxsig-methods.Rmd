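---
title: "Methods: multimodal biosignal analysis of anticipatory anxiety"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multimodal biosignal analysis of anticipatory anxiety}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(anxsig)
```

## The analysis problem

`anxsig` implements a group analysis for multimodal psychophysiological
recordings collected while participants anticipate a social stressor. A
cohort of participants (17 by default) is recorded for 300 s across seven
signal streams at heterogeneous native rates — 27-channel EEG, 2-channel
ECG, 4-channel EOG, skin conductance (GSR), and respiration at 500 Hz;
two-eye pupil size at 200 Hz; head-roll angular velocity at 110 Hz — and
fills in a seven-item state-anxiety questionnaire (GAD-7 administered as
visual-analogue scales) immediately before and after the anticipation
period. The analysis asks which physiological measures differ between
participants whose self-reported anxiety rose most (the *anxious* group)
and the rest (*non-anxious*), where group membership is a median split on
the mean-item questionnaire change.

Because raw recordings of this kind are rarely shareable, the package
ships a synthetic-cohort generator whose output has exactly the
statistical structure the analysis consumes. Every downstream stage is
validated by parameter recovery against the generator's stored ground
truth.

## Pipeline

### Preprocessing (per modality, at native rate)

All filters are zero-phase: a Butterworth design (4th order unless noted)
realized as cascaded second-order sections and applied forward-backward.
Transfer-function realizations of these designs are numerically unusable at
the very low normalized cutoffs involved (a 0.05 Hz corner at a 500 Hz
rate), which is why the package factors every filter into biquads. Before
filtering, the signal mean is removed and the ends are extended by
reflection over several settling constants of the slowest pole
(`4 / f_low` seconds); the mean is restored for mean-preserving kinds.
This makes the DC contract exact: a constant trace passes a low-pass
unchanged and maps to zero under a high-pass.

| Stream      | Operation                                                          |
|-------------|--------------------------------------------------------------------|
| cardiac     | bipolar ECG derivation, band-pass 2–30 Hz                          |
| tonic GSR   | low-pass 0.05 Hz                                                   |
| phasic GSR  | high-pass 0.05 Hz                                                  |
| pupil       | low-pass 50 Hz                                                     |
| respiration | band-pass 0.1–0.5 Hz                                               |
| head roll   | low-pass, 45 Hz effective on the 110 Hz gyroscope stream           |
| EEG         | mastoid re-reference (27→25 ch), band-pass 0.5–50 Hz, 50 Hz notch (2nd-order, Q = 30), EOG regression, common average reference |

The tonic/phasic electrodermal split uses the *same* corner (0.05 Hz) for
the low- and high-pass, so the two components are complementary: their sum
correlates with the input at r > 0.99 away from the band edge. The phasic
branch is a true high-pass rather than the arithmetic complement, matching
the stated processing. The head-roll low-pass is nominally 50 Hz; on a
110 Hz stream that corner sits too close to the 55 Hz Nyquist for a stable
4th-order design, so the effective cutoff is 45 Hz. EOG regression fits
ordinary least squares of each EEG channel on the vertical and horizontal
bipolar EOG derivations (plus intercept) over the full recording — one
model per channel, not per epoch — and subtracts the fitted EOG
contribution, leaving residual correlations with both regressors at zero
by construction.

Filtering happens **before** resampling. The alternative order is
ill-posed: the 50 Hz cutoffs coincide with the Nyquist frequency of the
100 Hz common rate.

### Resampling and epoching

All processed streams are brought to a common 100 Hz rate by Fourier
resampling: the signal is mirror-extended (so both ends are continuous),
transformed, truncated at the new Nyquist, and inverted at the new length.
This is zero-phase, implicitly anti-aliasing, preserves DC bit-for-bit and
in-band amplitudes exactly, and conserves the variance of band-limited
noise — the property the head-roll variance feature depends on. A polyphase
FIR resampler would serve equally well in principle; the Fourier route was
chosen because it is transparent about exactly which spectral content
survives.

Streams are then cut into 30 s windows advanced in 5 s steps. Epoch k
covers the half-open interval `[5(k-1), 5(k-1) + 30)` s, so a 300 s
recording yields `floor((300-30)/5) + 1 = 55` epochs and adjacent epochs
never share a boundary sample.

### Per-epoch features

* **Heart rate**: the epoch is z-normalized; peaks of the negated first
  difference above half its in-epoch maximum, with a 250 ms refractory
  period, are beats; the rate is `60 * n_intervals / sum(intervals)`
  (interval-based, robust to partial beats at the edges). Epochs whose
  detections do not look like a beat train — under 2 beats, rate outside
  30–240 bpm, inter-beat interval coefficient of variation above 0.3, or
  peak-amplitude coefficient of variation above 0.11 — are flagged missing.
  The two irregularity cutoffs were calibrated on synthetic data: across
  50–110 bpm the QRS-train values stay below 0.08/0.09 while detections on
  pure noise stay above 0.31/0.14, so the guards sit in a wide margin
  between the populations.
* **Heart rate variability**: SD of the inter-beat intervals divided by
  their root mean square (sample SD, n−1). This is a dimensionless,
  scale-invariant ratio — not SDNN or RMSSD — and is exactly 0 for a
  perfectly regular rhythm.
* **Tonic / phasic GSR, pupil**: the epoch mean. Pupil traces are
  additionally zeroed at the first epoch per participant (absolute pupil
  diameter depends on viewing geometry), and both eyes are reported
  separately.
* **Respiratory rate**: same detector as heart rate but on the
  z-normalized signal itself with a 2 s refractory period (capping
  detectable rates at 30 breaths/min).
* **Head-roll variance**: the sample variance of the epoch.
* **Spectra**: Welch PSD with 1 s periodic-Hann segments, 50% overlap,
  per-segment constant detrend, one-sided density scaling — 1 Hz bins at
  0–50 Hz. Band powers are bin means over half-open bands: delta 1–4,
  theta 4–8, alpha 8–13, beta 13–30, gamma 30–50 Hz; the 50 Hz Nyquist bin
  belongs to no band.

### Group statistics

* **Grouping**: change score = mean(post items) − mean(pre items);
  participants strictly above the sample median are anxious, strictly
  below non-anxious; for odd n the median participant joins the anxious
  group (deterministic, and yields the 9/8 split at n = 17). Tied scores
  at the median are rejected rather than silently broken.
* **Tests**: Wilcoxon rank-sum, reporting the rank sum of the anxious
  group. For untied pooled samples up to 25 the two-sided p-value is exact
  (twice the smaller tail of the null distribution, capped at 1; the test
  suite cross-checks it against exhaustive enumeration over all
  relabelings). Otherwise a normal approximation with tie and continuity
  corrections is used.
* **Effect size**: Cohen's d with the pooled (n−1) SD.
* **Descriptives**: mean, median, SD, and an *empirical* 2.5/97.5
  percentile interval of the per-participant whole-task means. Percentiles
  are used because no parametric interval is implied by the analysis.
* **Multiplicity**: per-epoch time-course tests are reported uncorrected
  (exploratory, by design); PSD grids — per 1 Hz bin for head roll, per
  (channel, band) cell for EEG — are corrected with the Benjamini–Hochberg
  step-up procedure across the whole grid. Masks threshold at 0.05.

## The synthetic cohort

The generator emulates only what the analysis consumes:

* **ECG**: beats at inter-beat intervals `60/hr` s with Gaussian jitter
  (default SD 50 ms within participants), each a ~20 ms Gaussian deflection
  split antisymmetrically across the two electrodes over broadband noise.
* **EDA**: tonic level plus optional linear drift, plus sparse
  skin-conductance responses (Poisson events, default 2/min, instantaneous
  rise, 3 s exponential decay), plus measurement noise.
* **Respiration**: a unit sinusoid at the target rate plus noise.
* **Pupil**: baseline diameter with slow (<0.5 Hz) correlated drift per eye.
* **Head roll**: stationary Gaussian noise band-limited to 0.5–45 Hz —
  inside the preprocessing low-pass, so the filter conserves its variance —
  normalized to the target variance exactly.
* **EEG**: per channel, a sum of band-limited noise processes with
  specified one-sided PSD levels per band, plus a mixed-in share of the
  vertical/horizontal EOG ground truth (stronger on frontal channels),
  plus 50 Hz line pickup whose amplitude varies 0.7–1.3× per channel —
  electrode-dependent pickup is what makes the notch filter necessary,
  since a perfectly common-mode line artifact would vanish at
  re-referencing.
* **Questionnaire**: seven continuous items in [0, 3] summing to requested
  totals; cohort change scores are drawn from disjoint per-group ranges
  (anxious 1.0–2.5, non-anxious −0.5–0.8 mean-item change), so they are
  all distinct and the median split recovers the generating groups.

Group-level defaults follow the study conditions: heart rate 79.445 vs
66.75 bpm, respiratory rate 17.879 vs 15.37 brpm, tonic level 8.099 vs
4.84 μS, roll variance 8.261 vs 2.104 (deg/s)², with between-subject SDs
from the same descriptive table, and theta/beta/gamma EEG power elevated
1.8× in the anxious group. Everything is deterministic given the cohort
seed.

What the generator does **not** emulate: cardiac morphology beyond a
QRS-like pulse, real ocular kinematics or blinks, EEG microstates or
1/f structure, device clock drift, movement artifacts. Passing tests
therefore demonstrate that the pipeline's operations are correct and
well-calibrated on signals with the assumed statistical structure — not
that the pipeline is robust to every artifact of real recordings.

## Numerical choices and degenerate inputs

* Head-roll "variance" is treated as (deg/s)²; the dimensionless HRV ratio
  is reported as a ratio. Printed unit labels elsewhere for these two
  quantities are inconsistent with their definitions, and the definitions
  win.
* Epoch counts use `floor((duration − window)/step) + 1` with a 1 ns guard
  against floating-point underestimation.
* Missing epochs (failed beat detection) propagate as NA; a participant
  with no valid epoch for a measure is excluded from that measure's test
  with a message; an epoch with fewer than two valid values in either
  group gets an NA p-value in the time course.
* Zero pooled SD makes Cohen's d undefined (NA with a warning); constant
  EOG regressors pass the EEG through unchanged with a warning; duration
  shorter than one window, cutoffs at/above Nyquist, missing streams, and
  malformed or gappy timestamp files are all rejected with named
  diagnostics.
* Test problem sizes: module tests run cohorts of 4–6 participants at
  30–120 s; the calibration suites use 1000 null cohorts (per-epoch type-I
  error) and 500 null PSD grids (FDR control) at the feature level, where
  the tested property lives; full-length (300 s) single-modality
  recordings are used for the parameter-recovery checks.

## Known limitations

* The exact rank-sum path requires untied data; features measured on a
  continuous scale make ties improbable, but heavily quantized input would
  silently use the approximate path.
* The beat detector is tuned for clean QRS-like deflections; its
  plausibility guards will flag (not mis-measure) epochs whose cardiac
  signal deviates strongly from that morphology.
* No correction is applied across the 55 time-course tests — by design,
  mirroring the exploratory analysis the pipeline reproduces; the masks
  must be read as hypothesis-generating.
* Fourier resampling assumes the recording is long relative to any edge
  transients (the mirror extension handles discontinuities, but
  sub-second streams should not be resampled this way).
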