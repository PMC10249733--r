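---
title: "Measuring jump height from single-camera keypoints: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring jump height from single-camera keypoints}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cmjump)
```

## The measurement problem

A countermovement jump (CMJ) is a vertical jump preceded by a rapid dip of
the centre of mass. Two laboratory ground truths measure its height: a
force plate, via the flight time during which the vertical ground-reaction
force is zero, and marker-based optical motion capture (OMC), via the
vertical excursion of a foot marker in millimetres. A single fixed camera
plus a human pose estimator produces the same kinematics — but in pixels,
contaminated by estimation noise and occasional gross failures, and with
no intrinsic metric scale. `cmjump` turns those pixel keypoint series into
jump heights and quantifies how well they agree with the ground truths.

## Physical model

During flight the body is ballistic. Two consequences carry the whole
method:

1. **Flight-time height.** If toe-off and landing occur at the same toe
   height, the apex is reached at mid-flight, so
   $h = \tfrac{1}{8}\,g\,T_f^2$ metres, reported as $100\,g\,T_f^2/8$ cm.
   `height_from_flight_time()` implements this; its tests check it against
   an independent numeric integration of the projectile motion.
2. **Gravity as a metric ruler.** In up-positive image coordinates the hip
   keypoint traces a parabola of curvature $-g/2$ (in metres) during
   flight. A free fall of $T$ seconds from the apex covers $500\,T^2 g$ mm
   and $|d_0-d_T|$ px, so one pixel equals
   $R = 500\,T^2 g / |d_0-d_T|$ mm. This "pixel-to-metric" (PTM)
   calibration needs no reference object — the calibrating jump is the
   measurement itself.

The alternative "reverse minmax" (RMM) rescaling maps the minmax-normalised
pixel series onto the range of the synchronized OMC series. It is exact for
any positive affine pixel mapping but requires the OMC reference, so the
API labels it evaluation-only and the keypoint-only pipeline path never
uses it.

## The processing chain

For each recording the pipeline runs: dropout repair (markers only) →
spike removal → Savitzky–Golay smoothing → hip-peak segmentation →
per-repetition QC → Fourier upsampling of keypoint segments to the 100 Hz
time base → rescaling (PTM and, when markers exist, RMM) → toe-displacement
height → agreement statistics. Spike removal always precedes smoothing:
a polynomial filter smears an undetected spike over its whole window.

### Spike removal

Pose-estimation failures appear as spike runs of one or two frames. The
detector works on first differences of each channel: differences are
detrended by a 7-sample running median (genuine motion has locally
piecewise-monotone differences, so its residual is zero), z-scored on the
median/MAD, and a spike is declared where a large difference into a short
run (threshold `z_thresh`, default 3) is undone within two frames by a
large, nearly-cancelling difference of opposite sign. Flagged frames are
replaced by linear interpolation and the pass repeats up to three times.

Two ingredients matter and were chosen after quantifying the failure of the
simpler scheme. A plain global z-score on first differences flags genuine
flight-phase motion, whose differences are large but same-signed — on
noise-free synthetic keypoints it interpolated away eleven airborne frames
and biased the scale calibration by 7–9%. The cancellation requirement and
the local detrending keep fast motion untouched while still catching
spikes superimposed on it. This is a deliberate reading of "z-score
smoothing" as a spike-specific detector; the literature does not fix the
exact scheme.

### Smoothing

Savitzky–Golay, polynomial order 2, window 21 samples
(`signal::sgolayfilt`; its edge handling is an off-centre evaluation of the
full-window fit, exact for quadratics). An order-2 filter reproduces any
quadratic exactly, so the ballistic arc is preserved — *provided the window
fits inside the flight phase*. At 100 Hz a 21-sample window spans 0.21 s,
inside the flight of any jump above ~6 cm. At 30 fps the same window spans
0.7 s and measurably flattens the apex (about 4.6 cm for a 20 cm jump on an
exact ballistic arc). The pipeline therefore applies the smoothing window
on the common 100 Hz time base: keypoint segments are spike-cleaned at
native rate, Fourier-upsampled, then smoothed. The 30 fps hip series is
smoothed at native rate only to steady peak finding, where apex attenuation
moves no peak location.

### Segmentation and QC

Each repetition is a dominant hip peak; a window of `window_t` (default
1.5 s) is taken to either side, peaks must have prominence of at least half
the global range and be `2*window_t` apart (the more prominent of two close
peaks wins). Windows clipped by the series bounds are flagged
`clipped_window`.

Per-repetition QC mirrors how failure cases are handled in practice:

* `uncharacteristic` — the window violates the single-dominant-peak
  template: at least two distinct bumps rise above 70% of the apex-to-
  baseline displacement, separated by a valley below 30% of it. Measuring
  against the baseline rather than the raw range matters: the
  countermovement dip stretches the range downward and would otherwise
  mask competing bumps for small jumps.
* `low_confidence` — median keypoint confidence below 0.3.
* `spiky` — more than 5% of window frames were interpolated.

Only `uncharacteristic` and `low_confidence` exclude a repetition from the
agreement statistics; spiky-but-smoothable repetitions are kept, excluded
repetitions are still reported with their flags (and as `F` markers in the
wide table).

### Fourier resampling

Keypoint segments are upsampled to the marker time base by zero-padding the
discrete spectrum (`resample_to_length()`), the minimum-distortion choice
for band-limited signals; the implementation splits the Nyquist bin
symmetrically so real input stays real, and refuses to downsample.
Confidence channels are carried by nearest neighbour — they are labels, not
band-limited signals.

### PTM scale estimation

`estimate_ptm_scale()` applies the free-fall relation to a least-squares
parabola fitted to the airborne hip samples (those above the baseline plus
`1 - alpha` of the apex displacement; `alpha = 0.5` keeps the window inside
the flight by symmetry). The fit supplies a sub-frame apex time and value.
This refinement is not optional at 30 fps: the free-fall window of a 20 cm
jump is ~0.14 s, so quantising the apex to the nearest frame misplaces
$d_0$ by up to half a frame and propagates a >20% error into $R$; the
fitted arc restores exactness on clean data. $T$, the pixel drop and the
evidence are retained in the returned `scale_estimate`. Repetitions whose
drop falls below a 2 px resolution floor (or whose airborne samples are
not concave) raise a typed not-estimable condition; the pipeline then
falls back to the mean fitted $R$ — averaged per participant, then pooled —
mirroring how gross pose failures are handled in practice.

### Heights and agreement

Jump height is the maximum toe (fifth metatarsal) elevation above its
quiet-stance baseline, the median over the leading 0.5 s of the segment —
legitimate because the toe stays grounded until toe-off. Heights are
reported in cm to two decimals. ICC(2,1) is computed from the two-way ANOVA
mean squares (two-way random effects, absolute agreement, single
measurement); Bland–Altman uses the sample (n−1) standard deviation, with
differences oriented candidate-method minus ground truth. All repetitions
from all participants enter as individual measurements, as is common in
this validation literature; this ignores within-participant clustering,
and the reported ICCs inherit that caveat.

## The synthetic-data generator

`simulate_motion()` builds a piecewise-analytic vertical trajectory: quiet
stance, a raised-cosine countermovement dip (default 25 cm, 0.6 s), a
raised-cosine-velocity propulsion ending exactly at ballistic take-off
speed, free flight whose apex exceeds the stance baseline by exactly the
requested height, a brief landing absorption and recovery. Raised cosines
keep the trajectory twice differentiable, so smoothing tests see no
spurious overshoot. Apex times are snapped to the 0.1 s grid — a common
multiple of the 1000 Hz, 100 Hz and 1/30 s sample grids — by stretching the
preceding stance, so all three renderings sample the true apex exactly and
exactness invariants hold without interpolation error.

The renderings add what each sensor adds: white force noise (default 2 N)
including on the unloaded plate; white marker noise (1 mm) and optional
occlusion dropouts to exact zero; white pixel noise (1 px), isolated spike
frames (probability 0.01/frame, displacement at least 20 pixel-noise sd)
with lowered confidence, in image-down pixel convention at 3.43 mm/px.
Cohorts draw participant heights from a truncated normal (mean 21 cm,
sd 8.8 cm — a realistic bilateral-CMJ spread), with 0.5 cm rep-to-rep
jitter. Failure modes render sustained limb swaps or a multi-bump non-jump
trajectory, the fixtures for the QC contract.

What the generator does *not* emulate: coloured or heteroscedastic pose
noise (white Gaussian plus sparse spikes is an assumption), horizontal
drift toward/away from the camera (which would change the true scale
mid-recording), perspective and lens distortion, soft-tissue artefact, and
multi-person scenes. Passing parameter-recovery tests therefore shows the
chain is correct and robust to the modelled imperfections — not that real
smartphone captures meet the same error bounds.

## Numerical choices and degenerate inputs

* Gravity 9.81 m/s²; all rates declared, never inferred from time stamps.
* Flight detection: stance baseline from the leading 0.5 s; 5% of the
  *mean* stance force as unloading threshold (mean vs peak is unspecified
  in the literature; configurable); boundary refinement against a
  mean ± 5 sd unloaded-noise band, sd from the central 50% of the
  candidate run; a departure must last ≥3 ms to count (a single 5σ noise
  sample would otherwise truncate a flight by ~100 ms); runs under 80 ms
  rejected as chatter; refinement bounded to 50 ms beyond the raw crossing.
* Constant series: segmentation returns an empty list; RMM and PTM raise
  typed errors; ICC of a constant matrix returns `NA` with a diagnostic.
* Occluded (exact-zero) baselines error rather than silently bias heights.
* The sign convention (image y grows downward) is inverted exactly once,
  in `px_to_up()`, before any rescaling.

## Test problem sizes

The suite exercises: single recordings at heights 10–45 cm over 20 seeds
for force-plate and scale recovery; 16-participant × 3-repetition cohorts
for end-to-end agreement; paired 16×3 cohorts at 1 px vs 2 px noise across
20 matched seeds for the monotone-degradation property (matched seeds reuse
identical noise draws, scaled); 100 random matrices against an independent
ANOVA decomposition for the ICC; and n = 1000 normal differences for
limits-of-agreement coverage. These sizes give stable statistics while the
full suite runs in well under a minute per heavy property.

## Known limitations

* PTM amplifies keypoint noise by the scale factor; its limits of agreement
  are intrinsically wider than RMM's, which borrows the OMC range.
* The free-fall fit assumes a stationary camera and in-plane motion; a
  participant drifting toward the camera changes R within a session.
* Unilateral jumps in side view are exactly where pose estimation fails
  most often; the QC flags such repetitions but cannot repair them.
* ICC confidence intervals are not computed (point estimates only), and
  the repeated-measures structure of pooled repetitions is ignored.
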