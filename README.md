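# stretchsuit

A desk-scale digital twin of a full-body motion-capture garment built from
capacitive textile stretch sensors. Garments like this measure **local skin
stretch**: each sensor is a strip of conductive/dielectric fabric whose
capacitance rises monotonically as the skin path beneath it elongates, so a
network of 38 sensors over 13 joints (39 rotational DoF) can reconstruct
full-body pose anywhere — no cameras, no magnetic base stations, no IMU
drift. The package is for people who design or study such systems: it lets
you exercise the *entire* workflow — sensor placement optimization, signal
simulation, calibration, and activity recognition — on synthetic data with
known ground truth, on a single CPU.

## What it implements

- **Procedural body**: a 13-joint skeleton (intrinsic X→Y→Z Euler angles,
  degrees) with a connected, watertight skinned triangle mesh and
  linear-blend skinning.
- **Placement by geodesic stretch**: sensors are surface paths; candidates on
  a grid of centers × tangent directions around each joint are scored by the
  maximal relative stretch of their path over single-joint sweeps,

  `score = max over sweep of |L(pose) − L(rest)| / L(rest)`,

  then selected greedily under a path-overlap rule. The default budget yields
  the 38-sensor suit.
- **Sensor forward model**: a linear gauge law around a 100 pF base,
  `C = c_base(1 + g·s⁺) + c_trace + drift + ε`, with garment pre-tension,
  slack clamping, parasitic trace offset, spatially propagating drift
  (seeded at armpits and knees), and per-channel seeded noise, sampled at
  40 Hz.
- **Labeled motion generators** (100 Hz): a daily-pose corpus; single-joint
  sweep sessions over the 11 tracked joints; a coordinated multijoint
  calisthenics-like routine with an exact summed angle-change-rate target;
  metronome-paced pick-and-place reaches (3 heights × 5 speeds); treadmill
  gait with speed / step-width / slope signatures (15 classes); squat bursts
  for cross-device synchronization.
- **Preprocessing**: linear resampling to 100 Hz, zero-phase 4th-order 10 Hz
  Butterworth for reference angles, automated squat-burst clock alignment
  (sub-frame offset and clock-scale recovery), 3:1:1 random or sequential
  splits.
- **Calibration**: a 5×100 ReLU MLP (MSE, Adam 1e-3/ε 1e-4, batch 64, 10,000
  iterations, best-on-validation) mapping standardized channels to joint
  angles in degrees, with per-DoF/per-joint MAE reports, plus a long-window
  Savitzky–Golay drift baseline (order 3, window 18,000, applied twice).
- **Pattern recognition**: DFT amplitude spectra with the stationary offset
  reported separately, and a 3-layer hidden-50 LSTM classifier (one
  look-back step, cross-entropy, batch 64, 1000 iterations) over sensor
  windows.

Everything is a tibble in, tibble out; fitted objects support `tidy()`,
`glance()` and `autoplot()`.

## Worked example

Design the suit, generate a treadmill session with five step-width classes
(3-minute labeled segments), simulate the 38 channels, and train the
classifier:

```r
library(stretchsuit)

body   <- build_capsule_body()           # 13 joints / 39 DoF, skinned mesh
design <- design_suit(body)              # 38 sensors over 13 joints
rep <- run_experiment("gait_widths", seed = 1, body = body, design = design,
                      segment_s = 180)
rep
#> <experiment_report> preset=gait_widths seed=1 sensors=38
#> # A tibble: 1 × 4
#>   accuracy n_classes classes_majority_correct n_windows
#>      <dbl>     <int>                    <int>     <int>
#> 1    1.000         5                        5     17999
```

The report says the LSTM identified the step width of essentially every
held-out test frame (99.99% of 17,999 windows; all 5 classes
majority-correct) from the instantaneous 38-channel capacitance vector alone
— step width leaves a static hip-abduction signature the sensors see in every
frame. The same harness runs the other protocols:

```r
run_experiment("single_joint", seed = 1, body = body, design = design)
#> <experiment_report> preset=single_joint seed=1 sensors=38
#> # A tibble: 1 × 3
#>   overall_mae_deg mean_rate_deg_10ms n_frames
#>             <dbl>              <dbl>    <int>
#> 1           0.609               1.20    38608
```

Here the 5×100 MLP recovers the 33 evaluated joint angles of a ~387 s
single-joint session with a mean absolute error of 0.61°, the one-degree
regime expected for slow single-joint motion. Per-DoF errors come from
`tidy(rep$evaluation)` and the polar accuracy plot from
`autoplot(rep$evaluation)`.

## Command line

A thin CLI over the same functions ships at `inst/cli/stretchsuit.R`:

```sh
Rscript inst/cli/stretchsuit.R design   --out out/
Rscript inst/cli/stretchsuit.R simulate --preset gait --seed 2 --out out/
Rscript inst/cli/stretchsuit.R classify --preset gait_widths --out out/
```

See `vignettes/methods.Rmd` for the models, their assumptions, and the
limits of what synthetic validation shows.
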