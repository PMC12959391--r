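---
title: "A digital twin of a strain-sensing motion-capture suit: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A digital twin of a strain-sensing motion-capture suit: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(stretchsuit)
```

`stretchsuit` is a desk-scale digital twin of a full-body garment carrying 38
capacitive textile stretch sensors over 13 joints (39 rotational degrees of
freedom). It covers the complete workflow of such a system — designing where
the sensors go, simulating what they read, and running the calibration and
pattern-recognition pipelines that turn readings back into joint angles and
activity classes — entirely on synthetic data, so every quantitative claim
can be exercised end to end on a laptop. This vignette describes the models,
their assumptions, the parameters that matter, and what the synthetic
experiments do and do not establish.

## The body model

The body is procedural: a 13-joint skeleton (pelvis root `PV`; lower back
`LB`, trunk `T`, upper back `UB`, neck `NK`; shoulders `LS`/`RS`, elbows
`LE`/`RE`; hips `LT`/`RT`, knees `LK`/`RK`), each joint with three rotational
DoF as intrinsic X→Y→Z Euler angles in degrees, in a right-handed, Y-up,
meter-scaled frame. Degrees are used at every public interface; radians never
appear.

The skin is a single connected triangle mesh built from generalized
cylinders: one closed tube per chain (torso+head, each arm, each leg), with
cap fans at the tube ends and each limb's proximal cap apex welded onto the
nearest torso vertex. This construction was chosen over blending capsule
unions because it guarantees, by construction, the three properties the rest
of the package needs — a connected surface (so geodesics can cross every
joint), edge-manifoldness, and watertightness — without a mesh-boolean stage.
Skinning weights fall off as a Gaussian of the distance to each joint's bone
segments (`blend_radius`, default 0.06 m), pruned below 0.1% of the
per-vertex maximum and renormalized, so rows sum to exactly one and the
identity pose reproduces the rest mesh to machine precision. `resolution`
(segments around each tube, default 10, minimum 8) controls mesh density;
doubling it roughly quadruples the face count without moving the skeleton.

The Euler convention is a declared choice: the order and intrinsic/extrinsic
convention of the three per-joint angles is not observable from the package's
own outputs (all generators and consumers agree on it), but users supplying
external pose tables must match it.

One structural consequence worth knowing: rotations of the pelvis *root* move
the entire body rigidly and therefore produce no skin stretch at all. A
stretch-sensing garment is blind to global orientation — as is the real one,
whose optical reference likewise reported 11 joints (33 DoF), not the root.
Calibration therefore targets those 33 DoF by default.

## Geodesics and the sensor path model

Geodesic distances are shortest paths on the mesh edge graph augmented with
one midpoint node per edge, plus the in-face midpoint–midpoint and
midpoint–opposite-corner links (Dijkstra via `igraph`). This over-estimates
exact polyhedral geodesics by a small, refinement-controlled factor (≤ 8% on
a flat square's diagonal at the default density; the test suite pins this
bound) and has the virtue of being *exactly* checkable against an independent
shortest-path oracle, which the tests do.

A designed sensor is a fixed material curve on the skin: the chain of graph
nodes of its rest-pose geodesic path. Posing the body moves those material
points by linear blend skinning, and the sensor's length under a pose is the
posed polyline length. The shortest path is deliberately *not* re-solved on
the posed mesh: a textile sensor sewn to the garment cannot re-route itself.
This also makes the forward simulation fast — all sensors and frames reduce
to one dense matrix product per coordinate.

## Placement optimization

Candidates are enumerated around each joint: centers on mesh vertices within
a geodesic `radius` (0.22 m) of the joint, thinned to `grid_spacing` (0.04 m),
with tangent directions every `direction_step` (15°, i.e. 12 directions
mod 180°). Endpoints sit half a sensor length (160 mm unit) away along the
surface in opposite directions, found among the nodes in a geodesic band
around ±80 mm whose initial path direction best matches the requested
bearing; the candidate's path is the two geodesic branches joined at the
center. On a discrete mesh several bearings can resolve to the same endpoint
pair, so the effective number of distinct directions per center is usually
below 12.

Each candidate is scored by its **relative stretch**: the maximum over a
single-joint sweep of `|L(pose) − L(rest)| / L(rest)`, where the sweep takes
each of the joint's three DoF through its configured range (9 poses per DoF).
Selection is greedy in descending score, ties broken by enumeration order,
rejecting any candidate whose path comes within `overlap_threshold` (10 mm,
one sensor width) of an accepted path, under per-joint budgets that default
to 38 sensors over the 13 joints. The whole procedure is deterministic.

Open choices resolved here: the stretch statistic is a max over the sweep
(not a range or integral), and overlap is handled by the automatic
path-proximity rule rather than manual inspection.

## The sensor forward model

Capacitance follows a linear gauge law around a 100 pF base:
`C = c_base (1 + g · s⁺) + c_trace + drift + ε`, with gauge `g = 0.8`,
parasitic trace offset `c_trace = 5 pF`, and white measurement noise
(`noise_sd = 0.05 pF`, per-channel seeded substreams fanned out from one
master seed). The linear law reflects a monotone, low-hysteresis sensor;
hysteresis is deliberately not modelled. Skin-path strain is clamped below at
`strain_floor = −0.05` (fabric buckles rather than compresses), and the worn
garment adds a mounting pre-tension `pre_strain = 0.15`: the gauge strain is
`max(pre_strain + max(s, floor), 0)`. Pre-tension matters — without it the
rectified gauge law silences every placement on the contracting side of a
joint, which is not how a tight-fitting suit behaves; with it, contraction
reads as a capacitance drop until the fabric goes fully slack.

Drift is additive and spatially propagating: it seeds at the armpits and
knees (where sweating begins), spreads over the skin at
`propagation_speed = 2 mm/s`, and rises after onset as a saturating
exponential to `max_drift = 8 pF` with time constant `tau = 180 s`. These
amplitudes are configuration choices — the study this emulates reports the
spatial pattern and that drift is continuous over a 16-minute session, but
not per-sensor magnitudes — bounded so that calibration remains exercisable.

Streams are sampled at 40 Hz (angle streams linearly interpolated to sensor
timestamps), with channels ordered `ch00…ch37`.

## Synthetic motion protocols

All generators run at 100 Hz, are seeded and deterministic, keep every angle
inside the configured joint ranges, and attach labeled segments:

* **Pose corpus** — per-DoF truncated normals centered mid-range
  (sd = range/4), standing in for a large daily-pose corpus; the range
  estimator (2000-bin histograms over ±180°, smallest window holding
  `coverage` of the mass, default 0.995) recovers generator ranges within a
  degree at coverage 1.
* **Single-joint sweeps** — for the 11 tracked joints in the standard order
  (LE, LS, RE, RS, UB, LB, T, LT, RT, LK, RK), each axis swept sinusoidally
  5 times per ~11.7 s segment (≈387 s total), with 2° smooth jitter on all
  other DoFs, since a wearer cannot hold the rest of the body still.
* **Multijoint routine** — a coordinated calisthenics-like routine: 8 shared
  latent oscillators (2 sinusoids each, 0.3–1 Hz, the tempo of such
  routines) sparsely mixed across all DoFs. Coordination is essential, not
  cosmetic: scripted whole-body exercise moves many joints in a few shared
  patterns, which is what makes 38 channels sufficient to invert 33 DoF.
  One global amplitude factor is solved (linearly, hence exactly) so the
  mean summed angle-change rate matches its target, default 15.9°/10 ms.
* **Pick-and-place reaches** — 3 heights × 5 metronome speeds (base 90 BPM,
  one reach half-cycle per beat — the beat convention is a declared choice),
  with the observed joint allocation: upper height loads shoulders over
  elbows, middle loads elbows predominantly, lower loads elbows slightly
  more.
* **Treadmill gait** — periodic thigh/knee/arm patterns with a 50% left/right
  phase offset and class signatures chosen on biomechanical grounds: speed
  scales cadence (×(0.5+0.5s)) *and* stride amplitude (×(0.6+0.4s)) and adds
  forward trunk lean; step width is foremost stance geometry, a static hip
  abduction offset per class (−3° to +10°) plus redistributed
  abduction-swing vs knee amplitude, with trunk roll for sway; incline
  raises hip flexion and trims knee amplitude, decline the reverse and
  slightly faster. Each class also carries a seeded **session style** (±1.5%
  amplitude, ±0.75% cadence, sub-degree offsets): wearers never reproduce a
  condition identically across recordings, and this is what keeps the three
  nominally identical baseline recordings (regular width, 1.0×, 0°) in the
  15-class shuffled problem distinct, as they were in the original data.
* **Sync squats** — 5 deep knee/hip flexion cycles (110° knee) prepended and
  appended to a session, the deliberate bursts both recording systems see.

## Preprocessing

Sensor streams are linearly resampled to the 100 Hz reference clock
(endpoint-preserving, envelope-bounded). Reference angles can be low-passed
with a 4th-order 10 Hz Butterworth applied forward–backward; zero phase was
chosen so filtering never lags the labels. Clock alignment is automated:
knee-angle squat peaks (≥60° prominence) define burst templates at both ends
of the session, each candidate knee channel is cross-correlated against them
(absolute covariance, so buckling-side channels that dip during squats work
too, with parabolic sub-sample refinement), and the best-correlated channel
yields the offset and a linear clock scale through both bursts. Injected
offsets are recovered to well under one 100 Hz frame and clock scale to ~1e-6
relative; peak-train matching on raw sensor traces was tried first and is
structurally fragile (anti-phase peaks, saturated troughs).

Splitting is 3:1:1 with the remainder to train. Random mode permutes frames —
which implies temporal leakage between train and test within a session, a
property inherited from the protocol it reproduces and worth remembering when
reading the calibration errors. Sequential mode takes contiguous blocks per
labeled segment (each class's own timeline is split 3:1:1), the discipline
used for all classification experiments; for unlabeled data the blocks are
global.

## Calibration

The regressor is a 5×100 ReLU multilayer perceptron trained with
mean-squared error and Adam (learning rate 1e-3, epsilon 1e-4), batch 64,
10,000 mini-batch gradient steps ("iterations" are steps, not epochs), with
the best-on-validation snapshot retained. Channels *and* targets are z-scored
with training-split statistics — raw pF scales would otherwise dominate the
initialization; predictions are mapped back to degrees. The networks are
implemented in package code (matrix algebra plus hand-written
backpropagation and Adam), and their gradients are verified against finite
differences in the test suite; a noise-free linear system is checked against
an exact least-squares oracle.

Evaluation reports per-DoF mean absolute error in degrees, per-joint
aggregates, and the DoF-weighted overall mean over the 33 evaluated DoF.

The slow drift baseline is an order-3 Savitzky–Golay filter applied twice
over an 18,000-frame window with nearest-value edge padding. At that window
length the filter is applied as an FFT convolution with the single central
least-squares kernel — numerically the interior behaviour of the standard
implementation, validated in tests against explicit local polynomial fits.
Whether the baseline is subtracted before training or the regressor is
trained on raw drifting signals is exposed as a choice; the drift-robustness
check trains on raw drifting data and requires test MAE within 2× of the
drift-free run.

## Pattern recognition

Frequency profiles are one-sided DFT amplitude spectra computed with mean
removal and a rectangular window (the labeled segments are long relative to
the motion periods), with the DC bin — the stationary pose offset — reported
separately; an energy-conservation (Parseval) identity over this
representation is pinned in the tests.

The classifier is a 3-layer LSTM, hidden size 50, one fully connected layer
and softmax, cross-entropy and Adam (1e-3 / 1e-4), batch 64, 1000 iterations,
over look-back windows (default 1 step = 10 ms) of train-split-standardized
channels. Windows never span a label boundary. With one look-back step the
classifier sees single frames; classes are then separable exactly when their
pose limit cycles stay apart in the 38-channel space, which is what the
static and amplitude signatures above provide.

## Problem sizes and what the results mean

The shipped experiments run at matched protocol scale on a single CPU: the
single-joint session at its full ~387 s, the multijoint routine at 240 s, and
gait classes at 180 s each (the per-class recording length of the emulated
protocol; the package default segment is 1 minute). Representative results
(seed 1): single-joint calibration MAE ≈ 0.6°, multijoint ≈ 0.5° at
15.9°/10 ms, width classification ≈ 1.00, slopes ≈ 0.999, speeds ≈ 0.96, and
13–15 of the 15 shuffled gait classes majority-correct across seeds (15 at
seed 1). At the fixed 1000-iteration training budget the 15-class problem is
optimization-limited, not separability-limited: tripling the iterations
separates all 15 classes at ≈0.93+ accuracy.

What passing these experiments shows is that the *pipeline* — geometry,
placement, forward model, preprocessing, learning — is internally coherent
and reproduces the headline behaviour on data whose generative assumptions
match its own. What it cannot show is performance on real garments: the twin
has no soft tissue, no sensor migration over the skin, no hysteresis, no
electromagnetic coupling, idealized (sinusoidal, range-respecting) motion,
and session variability reduced to small seeded style offsets. Those gaps are
deliberate; they mark where synthetic validation ends.

## Reproducing the numbers

```{r}
library(stretchsuit)
body <- build_capsule_body()
design <- design_suit(body)
run_experiment("single_joint", seed = 1, body = body, design = design)
run_experiment("gait_widths", seed = 1, body = body, design = design,
               segment_s = 180)
```

`scripts/acceptance.R` re-runs the four gait classification experiments from
scratch and writes their accuracies to JSON; the test suite pins every other
property discussed here.
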