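---
title: "Methods: fTIR gait tracking and the synthetic validation framework"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: fTIR gait tracking and the synthetic validation framework}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`ftirgait` measures rodent gait from below-plate video of an fTIR
(frustrated total internal reflection) walkway. This vignette documents
the model behind each stage, the tunable parameters, the numerical
choices, and what the synthetic validation framework does and does not
establish.

## Imaging model and segmentation

A trial is a sequence of frames at a known frame rate (default 250 Hz)
and spatial calibration (px/cm), both taken from the configuration file
and never inferred from the images. Pixels live on an 8-bit scale;
coordinates are 0-based with the origin top-left, `x` along the walkway
and `y` downward.

**Background.** Each pixel is modelled by the median of its channel
values over frames in which the animal is absent. Animal presence is
detected by the colour rules alone (`candidate_animal_mask()`): a pixel
matching the body or footprint colour box is excluded from the median
for that frame. We deliberately do not bootstrap presence from a
first-pass background median: at pixels the animal occupies for more
than half of the trial (common near the start position of a short run)
a first-pass median latches onto the body colour and a
background-referenced exclusion can never recover, whereas the
rule-based exclusion is self-correcting. Pixels excluded in every frame
receive the global median and are flagged. The median uses an evenly
spaced subsample of at most 75 frames: for a moving animal each pixel
is background in almost every frame, so subsampling costs nothing
statistically and bounds memory.

**Classification.** A pixel within `bg_tolerance` (default 12) of its
median is background; otherwise the footprint colour box is tested
before the body box (footprint precedence), and pixels matching neither
revert to background. The three masks therefore partition every frame.
The default grayscale boxes — body 70–169, footprint 170–255 on a
background near 30 — tile the intensity axis so that no mid-bright
pixel (e.g. the skirt of a paw spot over the body) falls into a gap.
Colour frames take per-channel boxes instead.

**Body decomposition.** The largest body component of at least
`min_body_area` px (default 200) is decomposed by local thickness. The
tail-thickness threshold is `tail_thickness_frac` (default 0.25) times
the maximum body width, measured as twice the maximum of the Euclidean
distance transform. Pixels deeper than half that threshold form the
body core; mask parts not reachable from the core within that
half-thickness are thin appendages, and the appendage with the largest
reach is the tail (two competing long appendages flag the frame
ambiguous; short spurs are re-absorbed). The tail is parameterised by
an 8-neighbour chamfer geodesic from its attachment, giving the tail
base, three points at 1/4, 1/2, 3/4 arc length, and local PCA
orientations signed anteriorly (tip toward base), so a straight tail
collinear with the body axis has zero relative angle. The nose is the
tail-less extremity farthest from the tail base; argmax ties are
resolved by averaging all pixels within half a pixel of the maximum,
which keeps the landmark mirror-symmetric. Body centre and orientation
come from the second central moments of the tail-less mask, with the
axis sign disambiguated toward the nose; the head is the tail-less
region within `head_distance_frac` (default 0.25) body lengths of the
nose. If no tail exists (a degenerate but legal silhouette), the nose
is taken as the extremity along the travel direction estimated from the
last five tracked body centres, and tail-dependent fields are left
undefined rather than guessed.

**Footprints.** Footprint blobs are 8-connected components of the
footprint mask (a 1-px morphological closing first bridges
sub-threshold gaps between the pad and toes of one paw — one paw is one
footprint), filtered at `min_blob_area` (default 4 px), each summarised
by pixel count, summed brightness and the brightness-weighted centroid.

## Tracking and leg identity

Linking is greedy nearest-centroid in frame order. Because fTIR prints
anchor to the floor, a true continuation is nearly stationary, so a
candidate must lie within both `max_link_dist_px` (default 20) and the
per-frame drift bound `max_stance_drift_px` (default 3). The drift
bound is what prevents the classic failure mode of this setup: a hind
paw landing centimetres per second of travel away from — but pixels
near — a just-lifted fore print would otherwise be fused into the fore
track whenever the two are separated by a frame or two. Tracks survive
`max_gap_frames` (default 2) missing frames, with centroids linearly
interpolated across the gap and area/brightness left undefined there;
tracks shorter than `min_stance_frames` (default 3, i.e. 12 ms at
250 Hz) are discarded as flicker.

Leg identity is read off the body frame at stance onset: the lateral
sign gives the side and the longitudinal coordinate relative to
`fore_hind_split` (default 0, the body centre) gives fore versus hind.
Because the camera views the animal from below, the anatomical left is
the +y side of the heading; the generator and the tracker share this
convention, and identity is invariant under image translation and under
rotating the arena 180°. Events within ±0.02 body lengths of the split
are resolved by continuity with the most recent event of the two
candidate legs and flagged when no such event exists. Merged fore/hind
blobs are not split; they surface as ambiguity rather than silent
misassignment.

Step cycles run stance-onset to stance-onset, so the swing belongs to
the cycle whose stance precedes it and stance time + swing time equals
the period exactly in frame counts. Step length is the distance between
consecutive same-leg mean print centroids.

## Kinematics and coordination

Instantaneous speed is the central-difference velocity of the body
centre smoothed by a centred moving average (`speed_smooth_win`,
default 5 frames, end-shrunk); average speed is net displacement over
elapsed time, matching trials in which the animal crosses the walkway
without turning back. The duty factor of a cycle is stance/period;
values ≥ 0.5 are walks. The per-trial duty factor averages each leg's
mean cycle duty equally, then averages the four legs, so no leg
dominates through a different cycle count; the alternative (pooling all
cycles) is indistinguishable on balanced trials. The duty-versus-speed
relationship is ordinary least squares, and the walk-to-run crossing is
where the fitted line reaches 0.5 — defined only for a negative slope,
flagged otherwise. A descriptive exponential fit `a·exp(−b·v)+c` is
offered for stance time against speed; its coefficients are reported,
never asserted.

Stance traces transform the per-frame print centroid into the body
frame (translate to the body centre, rotate by the orientation,
normalise by body length); the first and last points are the AEP and
PEP. Poses missing during a stance are interpolated linearly (angles on
the unwrapped circle); traces with under 80 % tracked frames are
flagged and excluded from aggregates. Footprint clustering is the 2-D
standard distance — the square root of the summed population variances
of the two body-frame coordinates — of the chosen endpoint across a
leg's steps, averaged over legs with at least two steps. We read the
"spread of endpoint coordinates per video" this way because one value
per trial is what the per-video readout requires; an SD of per-video
averages would need many videos to define at all. The stance linearity
index is the mean distance between a trace and its moving-average
smooth (`linearity_smooth_win`, default 15 frames = 60 ms at 250 Hz,
end-shrunk); it is exactly zero for straight, evenly spaced traces, and
the same statistic applied to the body-centre path (in mm) is the body
linearity index — the latter is our concretisation of an otherwise
undefined summary.

Leg-combination categories classify each frame by which legs swing:
none, single, diagonal ({LF,RH} or {RF,LH}), lateral (both left or both
right), front-or-hind, three, all — a total map over the 16 flag
combinations with census {1, 4, 2, 2, 2, 4, 1}. Flags come from the
gap-filled stance events, not raw per-frame detection, to keep the
indexes flicker-free, and frames are classified between the first
stance onset and the last stance offset of the trial (outside that
window the schedule is truncated and "swing" would be an artefact);
untracked frames are excluded from the denominator.

Contralateral phase is onset-based: for each reference-leg cycle, the
partner's onset position as a fraction of the cycle, summarised by the
circular mean and circular SD (`sqrt(-2 log R)`), both re-expressed as
cycle fractions. Circular statistics matter only near the wrap point —
anti-phase values near 0.5 are unaffected — but they make in-phase
gaits ({0.95, 0.05} → 0.0, not 0.5) correct too. A cross-correlation
phase over the whole cycle would be less local in time; onset-based is
chosen because it is also what the generator schedules, keeping truth
and measurement commensurable.

Relative pressure is fTIR brightness: per-frame area (cm²), summed
intensity, and intensity per pixel. No absolute calibration to force
units is attempted.

## The synthetic validation framework

The generator emulates the conditions the measurements target: a
straight walk at constant (optionally sinusoidally modulated) speed, a
four-leg schedule with stance fraction `duty` and contralateral offset
`pair_phase` (0.5 = anti-phase; diagonal pairing for trot, lateral for
pace), floor-anchored paw spots with touchdown jitter, and a rendered
image stream — dark background (30), mid-intensity body ellipse and
tapered tail (110), Gaussian paw spots (amplitude 240, σ ≈ 0.28 cm)
whose amplitude ramps over the first 10 % of stance and gains an
additive rostral toe component over the final third, shifting the
brightness centroid toward the toes as loading transfers. Defaults
describe an adult mouse: 7 cm body, 2.5 cm width, 7 cm tail, 250 Hz,
8 px/cm. Stride length defaults to `v / (3.5 + 0.07 v)` — a stride
frequency rising from ~4 to ~8 Hz across 10–80 cm/s, the typical range
for mice — and duty factor declines linearly with speed through the
walk-to-run transition near 53 cm/s. Schedules are quantised to the
frame grid; the recorded ground truth is recomputed from the emitted
schedule (not the requested spec), so recovery errors measure tracking,
not rounding. Liftoff jitter is realised as stance-duration jitter of
the anchored print — under the no-slip assumption, a paw cannot leave
from anywhere but where it landed, so PEP spread beyond AEP spread must
come from when it leaves.

Validation trials use 5–6 cycles per trial (a few hundred frames each)
at 15, 30, 45 and 60 cm/s with fixed seeds; these sizes give every leg
multiple cycles at each speed while keeping the whole suite fast enough
to run routinely. What passing shows: the pipeline recovers speed, duty
factor, step length, phases, placements and pressure patterns from
pixels alone, to tight tolerances, across the walk-run range. What it
does not show: robustness to fur-occluded silhouettes, heterogeneous
illumination, curved or hesitant walking paths, crossing or merged
footprints, or multi-animal scenes — real deployments should verify
thresholds on their own footage (the overlay debug images from
`run_track(..., overlays = TRUE)` exist for exactly that).

## Numerical and degenerate-input policy

Moving averages shrink their window symmetrically at sequence ends, so
smoothing never shortens a series and straight uniform inputs are fixed
points. Angle interpolation unwraps first. Circular means within 1e-9
of the wrap point report 0. CSV exports format floats to six
significant digits, making re-runs byte-identical. Degenerate inputs
prefer flags over guesses: no body → untracked frame; no tail → pose
without tail fields; no swing detected → duty 1 with a `degenerate`
flag; zero swing time → swing speed undefined and excluded from means;
fewer than two steps per leg → clustering undefined with a reason;
empty trials → a complete summary table whose undefined entries carry
explicit markers. The summary never silently omits a parameter.

## Known limitations

Greedy linking cannot re-identify a print after an occlusion longer
than `max_gap_frames`. Merged fore/hind contacts remain single blobs.
The fore/hind split at the body centre misassigns hind prints only in
gaits where hind paws land far anterior of the centre; the dead-zone
continuity rule covers the common case. Pressure is relative — absolute
calibration would require a reference load. Toe spreading is not
quantified automatically; the scale-calibrated footprint images support
manual measurement downstream.
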