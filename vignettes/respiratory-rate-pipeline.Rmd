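---
title: "Estimating respiratory rate from ECG and PPG waveforms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating respiratory rate from ECG and PPG waveforms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem and the model

Respiration leaves three well-known fingerprints on cardiovascular
waveforms: **amplitude modulation** (AM) of the beat amplitude, driven by
intrathoracic pressure and stroke-volume changes; **baseline wander** (BW)
of the whole signal; and **frequency modulation** (FM) of the beat-to-beat
period through respiratory sinus arrhythmia (RSA) — the heart beats slightly
faster during inspiration. Because ECG and PPG are recorded routinely and
cheaply, a respiratory rate (RR) estimated from them is an attractive
substitute for a dedicated respiration sensor.

`rrwave` implements a feature-based surrogate-respiration pipeline:

1. **Condition** the raw channel. ECG: zero-phase Butterworth band-pass with
   a 5–40 Hz passband, which removes baseline wander and most P/T-wave
   energy while preserving QRS timing. PPG: zero-phase 8th-order Butterworth
   low-pass at 10 Hz, then multilevel wavelet smoothing, then a
   Savitzky–Golay polynomial filter.
2. **Detect beats.** ECG: a Pan–Tompkins detector (derivative → squaring →
   150 ms moving-window integration → adaptive dual thresholds with a 200 ms
   refractory period and searchback), with each fiducial refined to the
   local maximum of the filtered ECG within ±50 ms. PPG: systolic peaks by
   local-maximum search with a minimum spacing of 60/220 s and a prominence
   gate, each paired with the preceding trough.
3. **Extract per-beat features.** ECG (with Q and S located as the local
   minima within 100 ms before/after R): R-peak amplitude
   `R_i = max(x_j), j in QRS_i`; up-slope `max |x_j - x_(j-1)|` over
   `(Q_i, R_i]`; down-slope `max |x_(j+1) - x_j|` over `[R_i, S_i)`; and QRS
   area, the sum of the absolute trapezoidal areas of the Q, R and S lobes
   after referencing the QRS span to its median. PPG: the AM series
   (systolic peak minus preceding trough) and the FM series (successive
   peak-to-peak intervals).
4. **Reconstruct** a continuous surrogate respiration by natural cubic-spline
   interpolation through the beat-feature knots, evaluated at 4 Hz over the
   knot span and normalized to [0, 1].
5. **Count.** The record is tiled with contiguous, non-overlapping, half-open
   windows (default 30 s); respiratory peaks of the surrogate are detected
   (minimum spacing 60/60 s, prominence ≥ 0.1 normalized units) and each
   window's rate is `RR = n_peaks * 60 / T` breaths/min.

The evaluation suite compares derived and reference RR series with MAE,
MAPE, RMSE, Pearson correlation (with the conventional weak/moderate/strong
bands at 0.3 and 0.7), a Wilcoxon signed-rank test, and Bland–Altman limits
of agreement, aggregated within subjects (across windows), between subjects
(across windows' subject means), and overall (the average of the two stage
summaries).

## Tunable parameters

| parameter | default | unit | why |
|---|---|---|---|
| ECG passband | 5–40 | Hz | removes BW and P/T energy, keeps QRS slopes |
| band-pass order | 4 | – | enough roll-off; zero-phase application doubles it effectively |
| integration window | 150 | ms | classic Pan–Tompkins value, ~QRS width |
| refractory period | 200 | ms | physiological minimum inter-beat interval |
| R refinement window | ±50 | ms | bounds fiducial slack of the integrator |
| Q/S search window | 100 | ms | bounds the QRS at physiological widths |
| PPG low-pass | 10 Hz, order 8 | – | pulse morphology lives below 10 Hz |
| wavelet depth / zeroed levels | 11 / 2 finest | – | common PPG smoothing practice; depth falls back for short records |
| Savitzky–Golay | 250 ms, order 3 | – | smooths without flattening systolic peaks |
| pulse spacing / prominence | 60/220 s / 0.3 × median | – | 220 beats/min ceiling; gate vs dicrotic bumps |
| surrogate rate `fs_out` | 4 | Hz | Nyquist-safe for RR ≤ 60 breaths/min; peak counts are insensitive to this rate (verified in the tests) |
| respiratory peak spacing / prominence | 1 s / 0.1 | – | 60 breaths/min ceiling; rejects small spline ripple |
| window length | 30 (20/60 supported) | s | 30 s is the pipeline's design point |

All slopes are reported in signal units per sample; RR extraction is
invariant to that scaling choice.

## What the synthetic generator emulates — and what it does not

`modulation_spec()` + `generate_ecg()/generate_ppg()/generate_record()`
produce records in which every downstream quantity has a known ground
truth. Beats are sums of Gaussian bumps (five for ECG — P, Q, R, S, T at
−200, −25, 0, +25, +250 ms; two for PPG — systolic and dicrotic, scaled to
the mean heart period). Respiration is a unit sinusoid `r(t)`, optionally
with a linearly ramping rate; it drives all three modulation routes:
beat `k` is scaled by `1 + am_depth·r(t_k)`, the baseline is
`bw_amp·r(t)`, and the instantaneous heart period is
`(60/hr)·(1 − fm_depth·r(t_k))`. White Gaussian noise is added from a
single seed, so identical specifications are bit-identical. Template
centers are snapped to the sample grid (half-sample jitter is
physiologically irrelevant, and the zero-modulation amplitude series is
then exactly constant, which the tests exploit).

The generator deliberately does **not** emulate: powerline or motion
artifacts, electrode or perfusion changes, ectopic beats or arrhythmia,
apnea, or non-sinusoidal breathing. Passing tests on this corpus therefore
demonstrate the *correctness of the pipeline's mechanics* (detection,
feature extraction, reconstruction, counting, statistics) under controlled
modulation — not clinical performance on real recordings, where signal
quality, not mechanics, dominates the error.

## Numerical choices

- **Zero-phase filtering with symmetric padding.** `signal::filtfilt`
  starts from zero initial conditions, so both filters are applied to a
  symmetric-reflection extension (2 s each side) and the pads are
  discarded. Symmetric (rather than anti-symmetric) reflection keeps an
  extremum that touches a record edge at its location, which matters for a
  beat whose apex is the first sample. The PPG low-pass additionally
  filters around the channel mean so the DC level is preserved exactly.
- **Detector threshold floor.** The Pan–Tompkins adaptive threshold is
  floored at 5% of the 99th percentile of the integrated signal; a quiet
  lead-in can otherwise arm the detector on filter ripple.
- **Ties and degenerate windows.** Argmin/argmax ties break toward the
  earliest index. `q_idx == r_idx` (or `r == s`) yields a slope of 0; an
  empty Q/S search window collapses onto R. Constant signals normalize to
  all zeros with a warning rather than an error, keeping batch runs alive.
- **QRS area construction.** The baseline is the median over `[Q, S]`; the
  lobes are split at the baseline crossings nearest R on each side, with a
  midpoint fallback when a limb never crosses.
- **Spline boundaries.** Natural boundary conditions and no extrapolation:
  extrapolated cubics oscillate and would fabricate respiratory peaks.
- **Wavelet transform.** A periodized orthogonal DWT with the classic
  4-tap Daubechies filter, written in R; with periodic extension the
  analysis operator is orthogonal, so synthesis is its transpose and
  reconstruction is exact to machine precision (unit-tested). Odd lengths
  are padded by repeating the last sample and trimmed on reconstruction.
- **Wilcoxon signed-rank.** Zero differences are dropped and ties
  mid-ranked. For ≤ 15 differences the two-sided p-value is exact by full
  enumeration of the `2^m` sign assignments (valid under ties, where the
  textbook exact tables are not); beyond that, the normal approximation
  with tie correction.
- **Indices.** R-native 1-based sample indices; the time of sample `i` is
  `t0 + (i − 1)/fs`, windows are half-open `[start, end)` in seconds, so
  channels with different sampling rates align by time.

## Design choices where the design was open

- **FM intervals are systolic peak-to-peak** (not trough-to-trough),
  timestamped at the interval midpoints for the spline knots.
- **AM is peak minus preceding trough** rather than raw peak height, making
  it invariant to residual baseline.
- The ECG conditioning is a **5–40 Hz passband**; that is the only
  physically sensible combination of the two corner frequencies for
  isolating QRS energy.
- **Difference orientation** in agreement analysis is derived − reference:
  a negative bias means the surrogate method underestimates RR.
- **Non-overlapping windows with the trailing remainder discarded**; every
  peak belongs to exactly one half-open window, so per-window counts sum to
  the record total (tested as a conservation law).

## Quantization and the resolution of peak counting

A `T`-second window resolves RR in steps of `60/T` breaths/min: 2
breaths/min at the 30 s default. Two consequences are worth knowing.
First, a true rate that is not a multiple of the step (e.g. 15 breaths/min
counted in 30 s windows = 7.5 peaks) produces alternating counts and a mean
absolute error of up to one step even for a perfect estimator; the
end-to-end recovery tests bound the error at exactly this floor. Second,
rank statistics over a slowly ramping rate saturate: on a 19→22 breaths/min
ramp over 8 min, 30 s counting of the *true respiration itself* yields a
Spearman trend of only ≈ 0.70 because of tied counts, while 60 s windows
(1 breath/min resolution) yield ≈ 0.95. The ramp-tracking validation
therefore asserts the monotone trend at 60 s windows and, at 30 s, that the
surrogate reproduces the reference counting up to boundary-phase one-count
shifts with an identical record-total breath count.

## Problem sizes used in validation

The test suite and the acceptance script validate on 8-minute records at
300 Hz (the pipeline's design target for a full record), 60 s records for
detector characterization, and 20–120 s records for unit-level properties;
statistical oracles use 50–10,000 randomized cases per property. These
sizes were chosen so every property is exercised at its natural scale.

## Known limitations

- No signal-quality screening: all windows are analyzed, including ones a
  clinician would discard. This is intentional (realistic batch behavior)
  but means real-data errors are dominated by artifact segments.
- Peak counting cannot report sub-step rate changes within a window;
  spectral estimators (not implemented) trade that resolution against
  stationarity assumptions.
- The PPG branch extracts AM and FM only; a baseline-wander surrogate from
  PPG is out of scope.
- WFDB-format input is not supported; records are exchanged as CSV
  (`time_s,<channel>` with full float precision, lossless round-trip).

## A worked example

```{r, eval = FALSE}
library(rrwave)

spec <- modulation_spec(duration_s = 480, fs = 300, hr_bpm = 70,
                        rr_bpm = 15, am_depth = 0.2, fm_depth = 0.1,
                        noise_sd = 0.02, seed = 7)
rec <- generate_record(spec)

edr <- estimate_rr(rec$ecg, method = "r_amp")     # ECG branch
pdr <- estimate_rr(rec$ppg, method = "am")        # PPG branch
ref <- estimate_rr(rec$resp_ref, method = "reference")

pair <- rr_pair(ref$rr_bpm, edr$rr_bpm)
rr_mae(pair); rr_rmse(pair)
bland_altman(pair)
```
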