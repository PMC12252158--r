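---
title: "Methods: rule-based fall detection from keypoint tracks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: rule-based fall detection from keypoint tracks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fallwatch)
```

## The problem and the model

Falls among the elderly are a leading cause of injury, and camera-based
monitors must separate an accidental fall from two visually similar
behaviours: ordinary walking and deliberately lying down. `fallwatch`
implements the judgment layer of a top-down pipeline: given a per-frame
track of a person's bounding box and 17 COCO keypoints (from any
detector/keypoint network), it classifies the track as walking, lying or
fall, and raises an alert only on a fall.

Three per-track kinematic features carry the signal:

- **Aspect ratio** `A = (y_max − y_min)/(x_max − x_min)` of the bounding
  box. Upright people have `A` well above 1; a horizontal body has
  `A < 1`. `A` alone cannot separate lying from falling — both end
  horizontal — which is why the two dynamic features exist.
- **Centroid descent speed** `V`. The torso centroid (mean of the two
  shoulders and two hips) is tracked vertically; `V = Δy/Δt` in
  pixels/second over a 0.25 s window. We define downward motion as
  positive: in image coordinates y grows downward, so the naive
  "initial minus final" difference would make a drop negative; the
  package uses `(y_end − y_initial)/Δt` so that falls are positive and
  thresholds read naturally.
- **Trunk–ground angle change** `Ω`. Two trunk vectors are formed:
  `Z1` = centroid − neck and `Z2` = centroid − ground projection. The
  angle of each against the ground direction `x' = (1, 0)` is
  `θ = arccos(⟨x', Z⟩/|Z|) ∈ [0°, 180°]`. `Ω` is the absolute change of
  `θ` across one sampled interval (a change in degrees, not an
  instantaneous rate; a degrees-per-second mode is available via
  `fall_config(omega_mode = "rate")`). The rule engine uses the larger
  of the two per-vector changes, since with our ground-projection
  construction `Z2` stays vertical and `Z1` carries the rotation.

### Derived landmarks

COCO-17 has no neck, centroid or ground point, so the package derives
them and stores them separately from the base keypoints (robust to both
17- and 18-point inputs):

- neck = midpoint of the shoulders (confidence = min of the two);
- centroid = mean of shoulders and hips;
- ground projection = (centroid x, bounding-box bottom y).

These are the simplest constructions consistent with an upright torso
projecting vertically onto the ground; they are deterministic, exactly
translation-equivariant, and configurable in principle but not claimed
to match any particular upstream implementation.

## The judgment state machine

Thresholds (defaults in `fall_config()`): `V > 350` px/s, `Ω > 75°` per
sampled interval, sampling every 15 frames, walking band
`1.5 < A < 2.5`, horizontal cutoff `A < 1`, three samples per judgment
window. At 60 fps the 15-frame stride is exactly the 0.25 s window the
speed threshold was calibrated on; `dt` defaults to `stride / fps`.

Each frame contributes an aspect-ratio reading. Every 15th frame, `V`
and `Ω` are computed against the previous sampled frame and the triple
`(A, V, Ω)` is classified:

- **fall** iff `A < 1` AND `V > 350` AND `Ω > 75` — all three gates, so
  the verdict is monotone in `V` and `Ω`;
- **walking candidate** iff `A` lies in the open walking band;
- **lying candidate** otherwise.

A fall latches immediately: later frames cannot unset it, and the alert
hook (the stand-in for a voice-inquiry subsystem — audio is out of
scope) fires exactly once. Without a fall, the last three samples
resolve the status: walking if all three are walking candidates, else
lying.

Two interpretation choices deserve note. First, a literal reading of
the three-judgment loop terminates after 45 frames and never resumes; a
monitor must keep watching, so the package re-evaluates the
three-sample window as a sliding window advancing one stride per step,
preserving the per-window semantics. Second, the angle gate is applied
to the angle *change per sampled interval* (a fall rotates the trunk by
more than 75° essentially at once), not to a rate in °/s; both readings
are exposed. The walking band is `(1.5, 2.5)`; a wider `1.5 ≤ A < 3`
band is sometimes quoted for upright posture, and the band is
configurable where that is wanted.

The streaming judge (`stream_judge()`) is the primitive; the batch
`judge_sequence()` replays a track through it, so online/offline
equivalence holds by construction and is property-tested. Frames whose
torso keypoints are occluded are skipped as gaps (counted, never
fabricated).

## The trajectory simulator

The simulator generates labelled tracks with the signatures the rules
assume, by placing a proportioned stick figure (17 keypoints, body
height 300 px on a 640×480 canvas by default) and deriving the bounding
box as the tight keypoint hull plus a 3 px margin. Defaults are chosen
once to mirror the calibration conditions: 60 fps, 65-frame episodes
(lying uses 4 s so its transition can span 3 s), isotropic Gaussian
keypoint noise of 0.5 px.

- **Walking**: the aspect ratio oscillates sinusoidally inside
  (1.6, 2.4) with a 15-frame gait period; the oscillation is realized
  through leg spread so the hull width tracks the prescribed `A`
  exactly, the centroid bobs by ±2 px, and the figure drifts forward at
  40 px/s. By construction the V-gate is never approached.
- **Falling**: after 15 upright frames the trunk rotates 90° and the
  centroid drops with a constant-acceleration profile over 0.5 s. The
  total drop is `D = peak_drop / (1 − (1 − 0.25/T)²)` so that the
  steepest aligned 0.25 s window drops exactly `peak_drop` pixels
  (default 120 px, i.e. a 480 px/s peak against the 350 px/s gate); the
  default onset frame is sample-aligned, which is what makes this peak
  exact rather than approximate. The rotation is flat for the first
  40 % of the fall and then follows a smoothstep, concentrating more
  than 80° of rotation inside one sampled window — an accelerating
  topple rather than a constant-rate one.
- **Lying**: the same geometry over a 3 s transition with a 30 px peak
  window drop (120 px/s, well under the gate) and an 85° total rotation
  (≈ 7° per window), ending below `A = 1`.

Tracks are deterministic given their seed; occlusion marks each
keypoint invisible independently with a given probability, retaining
coordinates. The thresholds are *pixel-scale* quantities: they are
meaningful at this canvas/body scale, and the canvas and body height
are parameters precisely because a different image resolution rescales
`V` (but not `A` or `θ` — the tested scale law).

What the simulator does *not* emulate: detector jitter with structured
(non-isotropic) error, missed detections, multi-person interaction,
camera motion, perspective foreshortening, or limb articulation beyond
the trunk. Passing the recovery tests therefore shows that the rule
engine implements its thresholds faithfully on signals with the assumed
signatures, not that those thresholds are optimal on real video.

## Random erasing

Occlusion augmentation fills rectangles with the ImageNet channel means
(124, 116, 104 in 8-bit RGB; the fill is configurable). The rectangle's
area is `ratio` times its region — the whole image for IRE, the person
box for KRE, both for I-KRE — with a log-uniform aspect ratio clamped
to feasibility. Because pixels are whole, the achieved area fraction
differs from `ratio` by at most one pixel row, i.e. less than
`1/min(region width, region height)` in absolute terms — the tested
tolerance. Placement is uniform over feasible positions; in KRE an
option centres the rectangle on a randomly chosen visible keypoint
(clamped into the box), since occluding keypoint neighbourhoods is the
stated purpose of that mode. One rectangle per mode per image by
default (`count` raises it). The default ratio is 0.5, the
best-performing occlusion level; the augmentation's effect on trained
accuracy is out of scope here.

## Network blocks

The detection/keypoint network components are implemented as plain
base-R array operations (`[C, H, W]` maps; im2col + BLAS matrix
multiply for convolutions; inference-mode batch normalization). There
is no training: the blocks exist as shape- and value-contract
components, verified by forced-weight cases (identity convolutions,
zero gates), small-instance oracles (a scalar triple loop for the BAM
refinement, a brute-force max filter for SPPF pooling), and the
published shape tables.

Choices where the design was open:

- BAM uses reduction `r = 16` and dilation 4 (the standard values for
  this block; configurable). In the keypoint assembly the dilation is
  clamped per branch so the dilated 3×3 footprint `(k−1)d + 1` fits the
  smallest maps (the 8×6 branch uses dilation 2).
- The multi-scale fusion's downsampling path nominally keeps channel
  counts, but a path into a lower-resolution branch must end at that
  branch's channel count for the sum to type-check; the final stride-2
  convolution in each chain performs that mapping — a deliberate
  correction, following standard high-resolution-network practice.
- Upsampling is nearest-neighbour; batch-norm epsilon is 1e-5;
  activations are ReLU inside blocks and after fusion, sigmoid for all
  attention gates. The attention-map symbol collision in the refinement
  is resolved by naming: output = `I0 + I0 ⊗ σ(Mc + Ms)`.
- Shuffle attention uses two groups, each split into a channel
  sub-branch (global pooling with learnable scale/shift into a sigmoid
  gate) and a spatial sub-branch (group-normalized map with learnable
  scale/shift into a sigmoid gate), recombined and channel-shuffled.

The keypoint assembly reproduces, for a 256×192 input: branch maps
(32, 64, 48), (64, 32, 24), (128, 16, 12), (256, 8, 6), six BAM blocks
(one per non-top branch per stage — the highest-resolution path is left
unaltered), and a 17-channel heatmap head at 64×48. The detector
assembly reproduces stage widths 24/116/232/464, a 20×20 deepest map
into SPPF(5, 9, 13), a three-scale neck with shuffle attention per
stage, and heads emitting 4 box coordinates plus class scores per
scale. Both run forward on one CPU in a few seconds. Reproducing
benchmark accuracies (they require GPU training on external datasets)
is a non-goal.

## Numerical and interface choices

- Coordinates are continuous pixels, origin top-left, y down, 0-based
  frame indices; timestamps default to `frame_index / fps`.
- `arccos` arguments are clamped to `[−1, 1]`; zero-length trunk
  vectors are errors, not NaNs.
- The dominant gait period is the lag of the first positive local
  autocorrelation peak: the global ACF argmax of a short noisy sinusoid
  is biased toward lag 1 by the `(n − lag)/n` taper, so the first local
  peak is the right estimator for a periodicity of ~15 frames in a
  65-frame series.
- Track streams are JSONL (appendable, line-recoverable, versioned
  header); pose interop uses COCO keypoints JSON with v-flags mapped to
  visibility (2 → visible/1.0, 1 → occluded/0.5, 0 → unlabelled/0.0,
  excluded from derivation); configuration round-trips through YAML;
  rasters are PNG.

## Problem sizes

The test suite and the acceptance script run entirely on synthetic
data: 200 tracks per behaviour for label recovery, 50 falling tracks
for the speed measurement, 20 walking tracks for the period
measurement, 65–240 frames per track, and single forward passes of each
assembly at full input size. The whole suite runs in well under two
minutes on one CPU.

## Known limitations

- Single-person tracks only; association across people is upstream.
- Pixel-unit thresholds: no metric calibration, so camera distance and
  resolution shift the effective operating point.
- The rule engine sees only the three features; behaviours that mimic
  the conjunction (a fast crouch directly toward the camera combined
  with trunk rotation) can in principle false-alarm, which is exactly
  why the alert hook models a confirmation step.
- Network assemblies are untrained by design; their outputs are
  contract-checked, not meaningful detections.
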