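---
title: "HexaTrack: methods and modelling choices"
author: "HexaTrack authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{HexaTrack: methods and modelling choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Walking insects move 26-odd salient points on six legs through a few cubic
centimetres at stride frequencies of 2-10 Hz. Reconstructing the full joint
kinematics — every thorax-coxa (ThC), coxa-trochanter (CTr),
trochanter-femur (TrF) and femur-tibia (FTi) angle on every leg — requires
3D positions of all those points at high frame rates, which manual frame-by
-frame digitization makes prohibitively slow and subjective. HexaTrack
implements a semi-automatic pipeline for the tethered, oiled-plate
preparation: the animal is fixed in space and walks in place, two
synchronized high-speed cameras view the painted leg markers from below
through the glass plate, and a user provides sparse keyframe annotations
that anchor an automatic tracker.

The package covers the whole chain — stereo calibration and triangulation,
image preprocessing, ellipsoid-constrained tracking, body-frame
normalization, joint angles, and dual-method stride segmentation — and
ships a synthetic stereo-video generator with exact ground truth so that
every stage can be validated end to end without any recorded data.

## Stereo geometry

Cameras follow the standard pinhole model `x_cam = R X + t` with square-
pixel focal lengths, a principal point, and an optional single radial
distortion coefficient (zero by default; the synthetic cameras are ideal).
Pixels are indexed with integer coordinates at pixel centers, origin at the
top-left, u rightward, v downward; quantization rounds half away from zero.

Calibration uses the Direct Linear Transform on at least six non-coplanar
jig correspondences (Hartley-normalized, SVD solution), decomposed by RQ
factorization into intrinsics and extrinsics and refined by BFGS on the
summed squared reprojection error. A planar iterative calibration would
need multiple poses of a checkerboard; with a synthetic (or machined)
non-coplanar jig the DLT route is simpler and fully determined by one view.
With exact correspondences the recovered model reprojects the jig to below
1e-6 px; with 0.5 px detection noise the mean reprojection error of the
default 27-point jig sits in the 0.3-0.9 px range expected of a practical
rig of this scale.

Triangulation uses the midpoint method: a 2D point in each camera back-
projects to a ray, and the estimate is the midpoint of the mutual
perpendicular between the two rays. The length of that segment — the
*triangulation error* — is the confidence measure used throughout the
tracker, which is why the midpoint construction is preferred over an
algebraic homogeneous least-squares triangulation: the gate quantity is
defined directly by the geometry.

### Rig geometry and the quantization floor

Because the legs of the animal are underneath its body, both cameras must
view the scene from below the plate; the stereo pair is therefore far from
the orthogonal optimum and the vertical (z) coordinate is reconstructed
worse than x/y. The default synthetic rig places one camera directly
ventral and the second 60 degrees from vertical toward the animal's front.
The angle was chosen from the quantization-error budget: with integer-pixel
rounding at 30 px/cm (3 px/mm) each ray carries up to 0.5 px ≈ 0.167 mm of
lateral error, and the midpoint z error scales as
`0.167 * (1 + cos a) / sin a` mm for axis separation `a`. Separations near
30 degrees would give z errors above 0.5 mm; at 60 degrees the worst-case z
error is 0.29 mm while x/y remain at the single-camera floor of ~0.17 mm,
reproducing the characteristic "z about twice x/y" anisotropy of a
below-plate rig. Note that the x/y floor cannot drop below 0.167 mm under
midpoint triangulation at this scale, whatever the geometry: the
best-constrained axis is limited by a single camera's half-pixel error.

## Image preprocessing

Markers are bright paint dots on a dark, cluttered scene. Preprocessing
(1) estimates a background image as the pixelwise mean of 100 evenly spaced
frames (indices `floor(i*T/n)`), each Gaussian-filtered with sigma 5 px;
(2) subtracts it, clipping at zero — markers are bright-on-dark, so
negative residuals are clutter; and (3) applies a 5 px median filter. Both
filters use reflect padding, implemented by explicitly padding before
calling the filter so border semantics do not depend on any library
internals. The Gaussian/median widths are the knobs that trade precision
(blurring shifts centroids slightly) against robustness (clutter and noise
suppression), and are exposed in `filterSettings()` and the YAML config.

## The tracker

The core assumption is that at 500 fps a marker barely moves between
frames, so its best a-priori position at frame *t* is its accepted position
at *t-1* (or *t+1* when tracking backward). Around that prior the tracker
builds a *flattened-sphere* search ellipsoid: circular cross-section of
radius `r0 * g^k` perpendicular to the leg segment and half that radius
along it, where *k* is the chain depth (ThC = 0, CTr = 1, FTi = 2,
TiTa = 3). The short axis encodes that leg segments resist length change;
the circular cross-section encodes ignorance about joint rotation; the
exponential depth scaling reflects that distal points move faster. The ThC
root, which cannot move in a tethered animal, gets a small sphere
(0.5 mm).

The ellipsoid is projected into each camera as the exact conic of the
quadric silhouette (with a sampled bounding-ellipse fallback for
ill-conditioned or distorted cases — containment of the true silhouette is
the contract either way). The new 2D measurement is the brightness-weighted
centroid (first image moments) of the pixels inside the ellipse. If the
image value at the centroid is dimmer than half the frame's median
brightness, the ellipsoid is enlarged (x2, at most twice) *for that camera
only* and the centroid re-measured; a region with no signal at all marks
the point lost outright, since enlarging an empty region could only
capture a neighbouring marker. Because processed frames are mostly zero,
the median-brightness threshold carries a floor of one 8-bit intensity
unit; without it the gate would never fire.

The two centroids are triangulated and the step is accepted only if
(a) both centroids were bright enough, (b) the triangulation error is at
most 1 mm, and (c) the leg segment length changed by at most a factor 1.3
relative to its length at the *nearest user-defined frame* — a stable
reference that, unlike the previous frame, cannot drift. A rejected step
*reverts*: the marker keeps its last accepted 3D position and is flagged,
never silently interpolated. Markers are tracked leg by leg from the ThC
root distally, so each step can use the already-updated proximal
neighbour.

Default search radii: `r0 = 1 mm`, depth scale `g = 1.3`, so the deepest
(TiTa) ellipsoid has a 2.2 mm long radius — roughly 6.6 px at the
reference scale. The scale was set from two constraints: the radius must
comfortably exceed the fastest per-frame marker motion (~0.3 mm at 4 Hz,
500 fps) and must stay below the smallest inter-marker image spacing of
the reference geometry (7-8 px in the oblique view), because the weighted
centroid integrates everything inside the ellipse and a neighbouring blob
inside the search region biases the measurement in the two cameras
differently, inflating the triangulation error and provoking revert/drift
cycles. Larger values of `g` (e.g. 1.5) violate the second constraint at
depth 3.

### Keyframes and bidirectional propagation

The user (or, in synthetic validation, the ground truth) supplies keyframe
annotations: per-camera pixel clicks for some or all markers at selected
frames. From every keyframe, tracking proceeds both forward and backward.
Between two keyframes each pass covers up to the midpoint (floor
division); a re-propagation after a user update never extends more than
halfway to an adjacent previously user-defined frame, so verified frames
are never overwritten. The forward and backward passes meet without
blending — small discontinuities at the meeting point are accepted and
visible, as they should be for honest error assessment. Markers not
annotated in a partial keyframe inherit their previously tracked
positions. User-flagged entries are never overwritten by propagation.

## Body-frame normalization

Raw triangulated coordinates live in the arbitrary frame of the
calibration jig. The canonical animal frame (x toward the head, y left,
z up, substrate at z = 0) is built from the data themselves:

* **z-axis** — the per-leg median TiTa (foot) points lie on the substrate
  for a tethered animal stepping in place. All pairwise cross products
  `(l_i - l_1) x (l_j - l_1)` of the leg-to-leg difference vectors are
  sign-aligned and averaged; the mean is normalized and oriented from the
  substrate toward the animal.
* **x-axis** — the first principal component of three anchors (mean CTr of
  the middle legs, mean CTr of the hind legs, mean ThC of the front legs),
  projected perpendicular to z and oriented so the front anchors have
  larger x.
* **Translations** — z places the median foot plane exactly at z = 0, x
  centers all data points, and y applies the mean of the per-leg median
  CTr y-values. (Centering z instead of pinning the foot plane would
  contradict the z = 0 ground-plane convention that the stride analysis
  relies on, so the foot-plane rule wins.)

Per-coordinate medians are not exactly rotation-equivariant, so rebuilding
the frame after an arbitrary 3D rigid disturbance recovers coordinates to
about 1-2% of the body scale (exactly, for rotations about z); this is a
property of the median-based definition itself, shared by any
implementation of it, and is far below the tracking error budget.

## Joint angles

All angles are reported in degrees; conversion is centralized.

* **FTi** and **CTr** are interior triplet angles (TiTa-FTi-CTr and
  FTi-CTr-ThC) via the arccosine of the normalized dot product.
* **TrF** (middle and hind legs; the joint is effectively fixed on the
  front legs of blaberid cockroaches) is the angle between the TiTa-FTi-CTr
  and FTi-CTr-ThC planes, with normals oriented by the chain winding and
  the result folded into [0, 180] degrees: a planar leg reads 0.
* **ThC1** (promotion/remotion) is the signed angle of the CTr-ThC
  segment's xz-projection from the downward vertical, positive toward +x.
* **ThC2** (adduction/abduction) rotates the segment back by -ThC1 about y
  and measures the signed angle from vertical in the yz-plane. Positive
  means abduction away from the body on either side (the sign is mirrored
  between left and right so series are comparable); the rotation axis for
  ThC2 is the once-rotated x-axis, i.e. intrinsic rotations in kinematic
  order.
* **ThC3** (front legs only) measures coxal long-axis rotation using the
  extra coxal marker. The reference plane is the yz-plane rotated by ThC1
  and then ThC2 in kinematic order; the ThC2 rotation acts about that
  plane's own normal and therefore leaves the plane invariant as a set,
  which is geometrically inevitable, not an approximation. By construction
  the rotated plane contains the ThC-to-CTr direction, so its intersection
  with the coxal plane (ThC, CTr, coxal marker) is the coxal long axis,
  and ThC3 is the signed dihedral angle about that axis, folded to
  (-90, 90] because a plane's orientation is defined modulo 180 degrees.
  It is zero when the coxal marker lies in the reference plane and is
  invariant to in-plane displacements of the marker.

FTi, CTr and TrF are invariant under rigid transforms of all inputs; the
ThC angles are frame-dependent by definition and only meaningful in the
canonical frame. Angles whose contributing markers are reverted or missing
are flagged absent, never interpolated.

## Stride segmentation

Two complementary definitions of swing and stance are computed per leg
from the canonical foot (TiTa) trajectory:

1. The per-leg step frequency is the peak of the FFT magnitude spectrum of
   the foot x-coordinate after mean removal, searched in a physiological
   band of 0.5-15 Hz (the band excludes DC and high-frequency tracking
   jitter; series shorter than 2 s are refused). The trial frequency `f`
   is the mean of the per-leg peaks.
2. The x-series is lowpass-filtered with a zero-delay (forward-backward)
   fourth-order Butterworth filter cut off at `2f`. Padding is by point-
   mirroring, sized to cover the IIR startup transient (`~9/wn` samples);
   a fixed small pad would leak edge transients far into the series at
   these low normalized cutoffs. Candidate transitions are the sign
   changes of the central-difference derivative of the filtered series.
3. **Extrema method (AEP/PEP)** — within a window of width `w = 1/(4f)`
   seconds centered on each candidate (25-125 ms over 2-10 Hz stepping),
   stance onset is the time of maximum x (anterior extreme position) and
   swing onset the time of minimum x (posterior extreme position); ties
   break to the earliest sample. Centered windows were chosen; the
   sidedness of the original is not documented anywhere, and centering is
   the symmetric default.
4. **z-height method** — foot heights are clustered into stance and swing
   by 2-means (a two-component Gaussian mixture fit with the k-means
   algorithm, seeded deterministically at the 5th and 95th percentiles so
   there is no randomness anywhere in the pipeline). With mu and sigma the
   mean and s.d. of the lower cluster, swing begins at the earliest upward
   crossing of `mu + sigma` in the window and stance at the latest
   downward crossing of `mu + 2 sigma`. "Went above / went below" are
   crossing events: reading them as "is above / is below" drags every
   stance onset to the window edge and biases duty cycles low by ~0.1. If
   no crossing falls inside a window the event is inherited from the
   extrema method and flagged.

Events within `w/2` of the series boundary are dropped, and runs of equal
type are reduced to their earliest event so onsets strictly alternate.
Stride period is the interval between consecutive stance onsets; duty
cycle is stance duration over period; incomplete boundary strides are
discarded.

The two methods deliberately disagree on real legs, which move backward
before touchdown and keep moving backward after liftoff: AEP/PEP stance
then brackets ground-contact stance and its duty cycle is larger. The
z-method also has an intrinsic bias worth knowing about: when the stance
cluster is contaminated by low swing samples (inevitable for smooth lift
profiles), its thresholds sit above the substrate and the z duty cycle
runs a few hundredths high. Both behaviours are reproduced and tested with
the synthetic generator.

## The synthetic rig

`gaitSpec()` + `generateTrajectories()` produce exact ground truth for a
tethered hexapod: each foot follows a stance (linear backward at z = 0) /
swing (forward with sinusoidal lift) cycle with programmable frequency,
duty cycle, per-leg phases (tripod by default), 10 mm stride and 3 mm
lift; CTr follows a fixed-length coxa that rocks gently (4 degrees) and
the knee solves the two-segment inverse kinematics with a deterministic
elbow choice. The default posture is sprawled — knees displaced
horizontally from the feet (anterior-dorsal for middle/hind legs,
posterior-dorsal for front legs) — as in a standing cockroach; this also
keeps distinct markers at workable image separations for a below-plate
camera pair, which a "knees-up" posture would not. The optional `xLead`
parameter adds the pre-touchdown/post-liftoff backward foot motion of real
legs (0 by default, so foot extremes coincide with contact transitions).

`renderStereo()` draws, per camera and frame, a static low-frequency
clutter field (smoothed white noise, up to 30% of the blob peak), Gaussian
blobs of sigma 1.5 px and peak 220 at the projected marker positions,
additive sensor noise of s.d. 2, then quantizes to 8 bits; occlusion
schedules blank chosen markers for chosen frame ranges and cameras.
Everything is bit-deterministic under a fixed seed. Defaults emulate
320x280 px at 500 fps and ~30 px/cm.

What the generator does *not* emulate — body wobble against the tether,
non-Gaussian marker shapes, paint smearing, limb self-occlusion geometry
(occlusions are scheduled, not emergent), lighting drift — bounds what
passing tests show: they validate the algorithms against their stated
models, not the full difficulty of real video. The manual-correction rates
and absolute accuracies on real recordings can be expected to be worse
than the synthetic figures.

## Validation scales and numerical choices

The test suite and the acceptance script run everything at sizes chosen to
exercise the full pipeline while staying desk-sized: the headline
end-to-end evaluation tracks a 2 s bout (1000 frames, 26 markers, two
320x280 px cameras) with ground-truth keyframes every 25 frames (4% of
frames, emulating the sparse corrections of the assisted workflow);
shorter 40-60-frame bouts cover the noiseless-exactness, occlusion and
determinism properties; stride-parameter recovery runs on 3-4 s of clean
trajectories across a frequency x duty grid. Tolerances asserted by the
tests come from the error budget above: quantization-limited triangulation
below 0.3 mm in z, tracked mid/hind-leg positions within 1 mm, triplet and
plane angles within 4 degrees, recovered frequency within one FFT bin and
duty cycle within 0.03.

Other numerical choices collected in one place: pixel quantization rounds
half away from zero; all filters reflect-pad; the silhouette conic falls
back to a sampled bounding ellipse only on numerical failure; k-means is
seeded at fixed quantiles; the tracker contains no randomness at all, so
identical inputs give bit-identical tracks; degenerate inputs (coplanar
jigs, collinear leg medians, coincident anchors, vanishing coxa
projections, constant spectra, single-cluster heights) raise explicit
errors or flagged-absent values rather than silent results.

## Known limitations

* The body frame is static by design (tethered preparation); free walking
  would need per-frame pose estimation.
* Only two cameras are supported; there is no bundle adjustment.
* The tracker is semi-automatic by philosophy: with no keyframe
  corrections it drifts on hard sequences, by design favouring honest
  reverts over optimistic interpolation.
* The two-component height mixture is a deliberate simplification; real
  foot-height histograms are not exactly two Gaussians, and the z-method
  duty bias discussed above is the price.
* The x/y triangulation floor of ~0.17 mm at 30 px/cm is a hard
  consequence of half-pixel quantization and midpoint triangulation; only
  finer optics/sensors or sub-pixel detections move it.
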