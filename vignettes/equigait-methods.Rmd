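---
title: "Methods: IMU-based screening of training-induced gait change in horses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: IMU-based screening of training-induced gait change in horses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(equigait)
```

## Scope and model

`equigait` screens multi-sensor IMU recordings of horse locomotion for
differences between a run recorded *before* and a run recorded *after* a
training session. The pipeline makes only weak assumptions about the
signals: strides are quasi-periodic, the sternum moves predominantly
vertically at the stride frequency, and the sensors deliver a usable
orientation estimate. It does not model the horse biomechanically; it
derives empirical indicators per stride and tests them across horses.

The unit of inference is the **horse**: each indicator is reduced to one
value per horse and condition, and conditions are compared with a paired
two-sided Wilcoxon signed-rank test across the herd (default n = 10).

## Conventions

* Quaternions are scalar-first `(w, x, y, z)`, Hamilton convention, and
  rotate sensor-frame vectors into the global frame. `q` and `-q` are
  treated as the same rotation everywhere (canonical sign: `w >= 0`).
* The global frame is right-handed with +Z up; gravity is
  `g = 9.81 m/s^2`.
* Sensor mounting: the sensor x-axis is aligned with the carrying
  segment's longitudinal axis; for the limb sensors x is therefore the
  twist axis and y the lateral (swing-signing) axis.
* Sampling rate is arbitrary on input and 128 Hz for synthetic data.

## Kinematic channels

Per sensor the pipeline derives `acc_x..z` and `gyro_x..z` (raw sensor
frame), the globally resolved movement acceleration
`a_g = R(q) a - g e_z` reported as the vertical component `acc_vert` and
the planar norm `acc_horiz`, the unsigned angles of the three sensor axes
to the vertical (`angle_xv/yv/zv`, degrees in [0, 180]), and, for the
cannon sensors, signed `swing` and `twist` angles. This is the unique
accounting that yields 11 channels for body sensors and 13 for limb
sensors (3 + 3 + 2 + 3, plus 2).

Two choices here were genuinely open:

* **Gravity removal.** The channels are movement signals, so gravity is
  removed before resolving components; a static sensor reads zero in
  `acc_vert`/`acc_horiz` at any attitude. This makes the vertical channel
  comparable across sensors with different mean attitudes.
* **Swing-twist reference.** The decomposition needs a zero attitude. A
  fixed laboratory reference would make the limb angles depend on the
  horse's heading in the arena; the per-passage chordal mean attitude is
  used instead, which makes the channels drift-free and heading-invariant.
  The twist factor is the projection of the relative rotation onto the
  twist axis; the 180-degree rotation exactly orthogonal to the twist axis
  has no defined twist and is returned as twist 0 with a QC flag.

## Stride segmentation

Stride boundaries are maxima of the low-pass filtered sternum vertical
acceleration. Parameters: Butterworth order 4, cutoff 3 Hz, and a minimum
peak spacing of 75% of the period.

* **Zero-phase filtering.** The filter is applied forward-backward so peak
  *timing* is unbiased; the magnitude response is consequently that of an
  8th-order filter, which is immaterial because only peak locations are
  consumed.
* **"The period".** The spacing rule needs a period before any peak is
  accepted. It is initialized from the dominant spectral frequency of the
  filtered signal, constrained to [0.5, 3] Hz (the plausible range of
  stride frequencies at trot and canter); a dominant frequency outside the
  band raises a "no periodicity detected" error. Candidate maxima are then
  accepted greedily in amplitude-descending order, and the estimate is
  updated as the running median of accepted inter-peak intervals
  (restricted to 0.55-1.8 times the spectral period, an outlier guard
  against transiently absurd medians while the accepted set is small).
* **Edges.** Peaks closer than half a period to either end of the record
  are flagged `edge_truncated`; strides bounded by such a peak are
  excluded from all stride sets. Because every finite record produces
  these flags, they are treated as routine exclusions: the QC verdict
  warns only on `short_period`/`low_prominence` flags or a period CV above
  15%.
* Stride windows are half-open peak-to-peak sample intervals; all sensors
  of a passage share the sternum-derived boundaries.

## Stride comparison

Strides are time-normalized to 100 points with shape-preserving cubic
(PCHIP) interpolation - monotone data stay monotone, linear data are
reproduced exactly, endpoints are preserved. Strides of a run are pooled
across the run's passages into one group per (sensor, channel); the
**reference stride** is the row minimizing the RMSD to the pointwise group
mean (ties to the lowest index). The per-horse indicator value is the mean
over that run's stride-vs-reference comparisons, so passages are weighted
by their stride counts.

Scopes:

* `intra_before`, `intra_after`: strides against their own run's
  reference, *excluding* the reference compared with itself (which would
  inject exact CC = 1 / RMSD = 0 values);
* `inter`: every after-stride against the before reference (the screening
  condition);
* `inter_rev`: the symmetric direction, stored for completeness but not
  used by the default screen.

The inter scope deliberately uses *all* strides of the probing run. The
alternative - excluding the probing run's own reference - was evaluated
and doubles the small intrinsic intra-vs-inter bias under the null
(the reference is selected *by* its group, so intra comparisons are
slightly favourable; keeping the probing run's most central stride in the
inter mean partially offsets this). The residual bias is visible as a
type-I rate slightly above nominal for CC/RMSD keys and is measured, not
hidden: the acceptance suite requires the pooled null rejection rate at
alpha = 0.05 to stay within [0.02, 0.08] over 200 seeded herds.

## Smoothness

**SPARC.** For a per-stride signal `v(t)` the magnitude spectrum is
computed by FFT, zero-padded to the next power of two at least 4x the
segment length (rectangular window), normalized by its maximum, and the
arc length of the normalized spectrum is accumulated over [0, fc] with
fc = 10 Hz:

```
SPARC = - sum_i sqrt( (df_i / fc)^2 + (V̂_{i+1} - V̂_i)^2 )
```

Numerical choices: the padding fixes the frequency resolution finely
enough that the discrete arc length is stable across stride lengths; the
last segment is interpolated to end exactly at fc, so the frequency-axis
terms sum to exactly 1 and `SPARC <= -1` holds for every signal. SPARC is
computed on the raw-time stride samples, not the 100-point normalized
strides, because the frequency axis is in Hz and smoothness lives in real
time. A constant (pure-DC) signal is a degenerate single-bin spectrum with
no magnitude variation; it is returned as exactly -1 with a `degenerate`
attribute, while an identically zero signal (normalization undefined)
raises an error. SPARC is evaluated on every kinematic channel and on the
angular velocity norm; the adaptive-cutoff SPARC variant is intentionally
not implemented (fc is fixed at 10 Hz).

**LDLJ-A.** On the gravity-free acceleration vector restricted to a
stride,

```
LDLJ-A = -ln( (t2 - t1) / apeak^2 * integral ||d a_g / dt||^2 dt )
```

with `apeak` the peak acceleration magnitude after removing the
segment-mean acceleration vector, jerk by central differences
(one-sided at the edges) and trapezoidal quadrature. This is the only
unit-consistent reading of the defining expression (the prefactor has
units s / (m^2 s^-4), the integral m^2 s^-5), and it reproduces the
closed form `-ln(omega^2 T^2 / 2)` for a pure sinusoid, which the test
suite checks to 1e-3 relative at 1 kHz. Gravity removal shares the code
path of the kinematic channels. Both metrics are amplitude-scale
invariant by construction.

## Statistical screen

For each (gait, sensor, channel, indicator) key the paired per-horse
values are: CC and RMSD - `intra_before` vs `inter`; SPARC, LDLJ-A and
stride duration - `before` vs `after`. Left/right cannon sensors are
pooled by per-horse averaging before testing (configurable).

The Wilcoxon signed-rank test drops zero differences, assigns average
ranks to tied absolute differences, and enumerates all `2^n` sign
assignments for n <= 15 (the two-sided p-value uses the symmetry of the
statistic about its null mean, which remains valid under ties); above
n = 15 a normal approximation with continuity correction and tie-corrected
variance is used. Significance is banded at 0.01 and 0.05; no
multiple-testing correction is applied by default (a Benjamini-Hochberg
column is available, off by default, since the screen is explicitly
exploratory). CC keys are retained only when the mean pre-training
intra-run CC across horses exceeds 0.80: a channel that does not repeat
well before training cannot evidence a change. Per-horse means (rather
than pooled strides) feed the retention rule, matching the pairing unit
of the test.

## The synthetic herd generator

The generator exists so that every downstream stage has ground truth. Per
sensor location it defines harmonic series (5 harmonics, amplitude decay
0.55 per harmonic) of the stride frequency for a global kinematic
acceleration and for small-angle roll/pitch/yaw oscillations about a
location-specific mean attitude; limb sensors carry a +/-35 degree swing
oscillation and hang x-down. The orientation stream is built first, and
the accelerometer stream is the inverse-rotated (global acceleration +
gravity) plus noise - so re-resolving the stored data in the global frame
recovers the generating signal to machine precision when noise is zero,
which the tests assert at 1e-9.

Study conditions (defaults): 10 horses, 2 passages per run, 8 s per
passage at 128 Hz (roughly 10 trot strides per passage - corridor
passages are short), stride frequency 1.4 Hz at trot and 1.8 Hz at canter
(typical equine values), stride-to-stride timing jitter with SD 2% of the
period, accelerometer noise SD 0.3 m/s^2 and gyro noise SD 0.05 rad/s
(deliberately generous, standing in for soft-tissue artifact as well as
sensor noise). Horses differ by seeded amplitude multipliers (lognormal,
sigma 0.15), a stride-frequency multiplier (sigma 5%) and waveform phase
offsets on harmonics >= 2; these horse parameters are shared between a
horse's two runs, while jitter and noise realizations are independent per
passage, so before and after runs are exchangeable under the null effect.
The sternum vertical acceleration uses pure cosine harmonics so its
maxima are the ground-truth stride boundaries.

The three fatigue knobs perturb after-runs only and each maps onto one
indicator family: `shape_delta` phase-shifts harmonics >= 2 (lowers inter
CC), `amp_delta` scales amplitudes (raises inter RMSD), and
`roughness_delta` adds 8-12 Hz band-limited noise with SD proportional to
the channel SD (degrades SPARC/LDLJ).

What the generator does **not** emulate: rider influence, ground reaction
dynamics, asymmetric lameness, sensor mounting slippage (the known
withers-fixation problem in field data), magnetometer disturbance of the
orientation estimate, or drift in the manufacturer's sensor fusion.
Passing tests therefore demonstrate that the pipeline recovers known
effects from clean quasi-periodic data with realistic noise and timing
variability - not that it is robust to every field artifact.

## Problem sizes and determinism

All randomness flows from integer seeds through per-horse and per-passage
substreams, so identical configuration and seed reproduce outputs
byte-identically. The test suite exercises: segmentation recovery on 50
jittered noisy passages (recall and precision 1.0, peak timing within
0.05 s of ground truth); type-I calibration of the screen on 200 seeded
null herds of 10 horses (sternum sensor, pooled rejection rate required
in [0.02, 0.08]); and power on 50 herds with `shape_delta = 0.3` (the
sternum vertical-acceleration CC key must flag with intra > inter in at
least 90% of herds). `scripts/acceptance.R` recomputes scaled versions of
the same quantities (100 null herds, 25 power herds) plus a full
nine-sensor pipeline run and writes them to JSON.

## Known limitations

* The intra-vs-inter CC/RMSD screen inherits a small anti-conservative
  bias from reference-stride selection (see above); at the study size it
  stays within the accepted calibration band but it is not exactly
  nominal.
* Uniform time-normalization aligns strides only at their boundaries; no
  curve registration or time warping is performed, so phase variability
  inside the stride loads onto CC/RMSD.
* The Wilcoxon screen treats indicators independently; with hundreds of
  keys the unadjusted screen is exploratory by design.
* Orientation estimates are taken as given; no sensor-fusion is performed
  and orientation error propagates directly into the global-frame and
  angle channels.
* The 11/13 channel accounting is the unique combination consistent with
  a single horizontal-norm channel; alternatives (two horizontal
  components, gravity retained) cannot be ruled out from first principles
  but would change the accounting.
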