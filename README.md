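# equigait

Screening body-mounted IMU recordings of horse locomotion for
training-induced changes in gait pattern and movement smoothness.

## The problem

A demanding training session is expected to alter a horse's locomotion
before overt fatigue is measurable physiologically. Nine time-synchronized
inertial measurement units (forehead, poll, withers, sternum, sacrum, and
the four cannons) each deliver 3-axis acceleration, 3-axis angular velocity
and an orientation estimate. The question this package answers: *which
kinematic indicators derived from those streams change between a run
recorded before and a run recorded after a training session?*

The analysis pipeline is:

1. **Channel derivation.** Per sensor: raw accelerations and angular
   velocities (`acc_x..z`, `gyro_x..z`), globally resolved vertical and
   horizontal movement acceleration (gravity removed,
   `a_g = R(q)a - g e_z`), the angle of each sensor axis to the vertical,
   and - for the limb sensors - swing and twist angles from a swing-twist
   decomposition of the attitude relative to the passage mean
   (`q_rel = q_swing q_twist`, twist about the limb's long axis).
   That gives 13 channels per cannon sensor and 11 per other sensor.
2. **Stride segmentation.** Local maxima of the sternum vertical
   acceleration after a zero-phase 4th-order Butterworth low-pass at 3 Hz,
   accepted greedily by amplitude subject to a spacing of at least 75% of
   the running period estimate.
3. **Stride comparison.** Each stride is time-normalized to 100 points by
   shape-preserving (PCHIP) interpolation; per run, the stride minimizing
   the RMSD to the group mean is the reference; Pearson correlation (CC)
   and RMSD are computed stride-vs-reference within a run (*intra*, the
   null condition) and across runs (*inter*, the effect condition).
4. **Smoothness.** Per stride: the spectral arc length
   `SPARC = -∫_0^fc sqrt((1/fc)^2 + (dV̂/df)^2) df` of the max-normalized
   magnitude spectrum (fc = 10 Hz), on every channel and on the angular
   velocity norm; and the log dimensionless jerk of the gravity-free
   acceleration vector,
   `LDLJ-A = -ln( (t2-t1)/a_peak^2 · ∫ ||da_g/dt||^2 dt )`.
5. **Screening.** Per (gait, sensor, channel, indicator), a two-sided
   paired Wilcoxon signed-rank test across horses (exact enumeration up to
   n = 15), alpha = 0.05; CC indicators are additionally retained only when
   the mean pre-training intra-run CC exceeds 0.80.

Because no public recordings of this kind exist, the package ships a seeded
synthetic gait generator: harmonic stride waveforms per sensor location,
physically consistent orientation/acceleration streams, stride timing
jitter, and three independent "fatigue" knobs (waveform distortion,
amplitude scaling, roughness) that map monotonically onto the CC, RMSD and
smoothness indicator families. Every stage of the pipeline is testable
against the generator's ground truth.

## Worked example

```r
library(equigait)

cfg <- pipeline_config(
  mode = "synthetic", seed = 42, gait = "canter", n_horses = 10,
  sensors = c("ST", "SA", "FC_left", "FC_right"),
  effect = fatigue_effect(shape_delta = 0.25, roughness_delta = 0.3))
res <- run_pipeline(cfg)
head(res$screen[res$screen$retained,
                c("sensor", "channel", "indicator", "p_value",
                  "mean_x", "sd_x", "mean_y", "sd_y", "direction")], 8)
```

```
 sensor    channel indicator p_value mean_x   sd_x mean_y   sd_y direction
     FC acc_vector      LDLJ 0.00195  -3.20 0.0427  -3.85 0.1010  decrease
     SA acc_vector      LDLJ 0.00195  -3.18 0.0451  -3.80 0.0841  decrease
     ST acc_vector      LDLJ 0.00195  -3.01 0.0364  -3.55 0.0541  decrease
     FC  acc_horiz     SPARC 0.00195  -2.44 0.1583  -2.20 0.1322  increase
     SA  acc_horiz     SPARC 0.00195  -2.43 0.1081  -2.20 0.0856  increase
     ST  acc_horiz     SPARC 0.00195  -2.35 0.1461  -2.10 0.1074  increase
     SA   acc_vert     SPARC 0.00195  -2.82 0.2155  -2.69 0.1105  increase
     ST   acc_vert     SPARC 0.00195  -5.15 0.2304  -4.54 0.2436  increase
```

Each row is one screened indicator: `mean_x (sd_x)` summarizes the null
condition across the 10 horses (the before run, or the intra-run
comparison for CC/RMSD), `mean_y (sd_y)` the effect condition, and
`p_value` the exact paired Wilcoxon p (2/1024 is the smallest attainable
two-sided value with 10 tie-free pairs). Here the injected roughness makes
the acceleration-vector LDLJ clearly more negative after the "session"
(direction `decrease` = less smooth), as designed.

`run_pipeline()` with `out_dir` set also writes `indicators.csv`,
`screen*.csv`, `sensor_counts.csv`, `qc.csv` and a `manifest.yaml` that
fully reproduces the run.

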