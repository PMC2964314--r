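# HexaTrack

Assisted 3D kinematic tracking of multi-marker insect legs from stereo
high-speed video.

## What it is for

Studying how an insect's nervous system controls walking requires the
joint angles — thorax–coxa (ThC), coxa–trochanter (CTr), trochanter–femur
(TrF) and femur–tibia (FTi) — of all six legs at once, at high temporal
resolution. In the tethered, oiled-plate preparation the animal walks in
place above two synchronized high-speed cameras, with small paint dots on
26 leg points (per leg: ThC, CTr, FTi, TiTa; plus one extra coxal dot on
each front leg). Manual digitization of such recordings costs days per
trial; HexaTrack automates the bulk of it while keeping the user in the
loop through sparse keyframe corrections.

The package implements, in one coherent pipeline:

- **Stereo geometry** — pinhole cameras, Direct Linear Transform
  calibration from a jig of known geometry with nonlinear refinement, ray
  back-projection, midpoint triangulation with its *triangulation error*
  (distance between the rays at closest approach), plus reprojection and
  retriangulation error metrics.
- **Image preprocessing** — background estimation from 100 evenly spaced
  Gaussian-filtered (σ = 5 px) frames, background subtraction clipped at
  zero, 5 px median filtering.
- **Tracking** — the core semi-automatic algorithm. For each marker the
  search volume is a flattened-sphere ellipsoid centered at the last known
  position: circular cross-section of radius r₀·gᵏ (chain depth k, ThC = 0)
  perpendicular to the leg segment, short radius half that along it. The
  ellipsoid projects to an ellipse in each camera; the brightness-weighted
  centroid inside it is the new measurement, with per-camera enlargement
  retries when the centroid is dim. Steps are accepted only when the
  triangulation error and the leg-segment length change pass their gates;
  otherwise the marker *reverts* to its last known position. Propagation
  runs forward and backward from every user keyframe, never beyond halfway
  to a neighbouring keyframe.
- **Body frame** — rotation/translation of raw jig coordinates into the
  animal frame (x forward, y left, z up): the z-axis from sign-aligned
  cross products of the per-leg median foot (TiTa) points, which lie on
  the substrate (z = 0); the x-axis from the principal line through CTr and
  ThC anchor means; y-translation from the median CTr heights.
- **Kinematics** — FTi and CTr triplet angles, the TrF inter-plane angle
  (middle/hind legs), the ThC₁/ThC₂ promotion and abduction angles, and
  the front-leg coxal rotation ThC₃ from the extra coxal marker.
- **Stride segmentation**, two ways: per-leg step frequency f from the FFT
  peak of the foot x-coordinate; candidates from derivative sign changes
  of a zero-delay 4th-order Butterworth-filtered series (cutoff 2f); then
  (a) anterior/posterior extreme positions (AEP/PEP) within windows of
  width 1/(4f) s, and (b) foot-height thresholds μ+σ / μ+2σ from a
  2-means Gaussian-mixture stance cluster.
- **Synthetic rig** — a programmable hexapod gait generator (frequency,
  duty cycle, per-leg phases, stride length, lift) plus a stereo renderer
  (Gaussian blobs, static clutter, sensor noise, occlusion schedules, 8-bit
  quantization) with exact ground truth, so the entire pipeline is testable
  without any recorded video.

## Worked example

Simulate a 2 s bout (1000 frames, 4 Hz tripod gait, default noise and
clutter), track it from keyframes placed every 25 frames (emulating the
sparse manual corrections of the assisted workflow), normalize, and
measure angles and strides:

```r
library(HexaTrack)

bout  <- simulateBout(1000, gait = gaitSpec(freq = 4, duty = 0.55, seed = 42),
                      keyframeEvery = 25, seed = 42)
track <- trackBout(bout$stacks[[1]], bout$stacks[[2]], bout$cameras,
                   bout$keyframes, bout$topology)
track
#> TrackState: 1000 frames x 26 markers @ 500 fps
#>   none: 0, user: 1040, tracked: 24959, reverted: 1

frame <- buildBodyFrame(track, bout$topology)
canon <- track
canon@pos3d <- applyFrame(frame, positions3d(track))

angles <- computeAllAngles(canon, bout$topology)
head(subset(angles, leg == "R2" & joint == "FTi"), 3)
#>       frame time_s leg joint angle_deg status
#> 10001     1  0.000  R2   FTi  62.95266     ok
#> 10002     2  0.002  R2   FTi  63.14774     ok
#> 10003     3  0.004  R2   FTi  63.43137     ok

strides <- analyzeStrides(footSeries(canon, bout$topology), 500)
strides$model
#> StrideModel: f = 4 Hz (window w = 62.5 ms)
#>   per-leg peaks: R1=4 L1=4 R2=4 L2=4 R3=4 L3=4 Hz
#>   stance cluster mu: 0.131 0.0999 0.115 0.0369 0.0682 0.0204

subset(strides$summary, leg == "R2")[, c("method", "n", "mean_period", "mean_duty")]
#>     method n mean_period mean_duty
#> 5  extrema 7        0.25 0.5600000
#> 11 zheight 7        0.25 0.6057162

round(attr(evaluateTrack(track, bout$truthWorld), "overall"), 3)
#> [1] 0.045
```

Reading the output: the tracker accepted essentially every step (1
reverted of 26,000); the spectral estimate recovers the programmed 4 Hz in
every leg, so stride periods are 250 ms; the AEP/PEP duty cycle (0.56)
sits at the programmed 0.55, while the foot-height method reads slightly
higher because its thresholds lie above the substrate; and the mean 3D
tracking error against ground truth is 0.045 mm — about a seventh of a
pixel at the 30 px/cm working scale.

A command-line interface wraps the same functions for shell use
(`exec/hextrack`): subcommands `simulate`, `calibrate`, `track`, `angles`,
`strides`, `evaluate`, with TIFF stacks, YAML cameras/config, JSON
keyframes and CSV products (schemas are recorded in each run's
`manifest.json`).

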