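---
title: "Methods: simulating and validating markerless gait analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and validating markerless gait analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gaitval)
```

## Scope and purpose

gaitval implements, as reusable and tested code, the analysis chain of a
device-validation study for markerless gait analysis: a 30 fps video
pose-estimation stream (2D pixel landmarks) is compared against a 100 fps
marker-based metric reference while a subject walks on a treadmill. Because
the per-subject data of such studies are rarely public, the package pairs
the analysis chain with a synthetic gait generator that produces both
device streams from one continuous-time model together with exact ground
truth, so that every stage — filtering, event detection, parameter
computation, agreement statistics — can be validated end to end.

## The synthetic gait model

### Event schedule

Walking is represented as an alternating sequence of left/right initial
contacts (IC). The interval after an IC of side *s* is that side's step
time, drawn per step from a normal distribution truncated at ±3 SD (with a
0.1 s physical floor). Toe-off (TO) of a foot occurs a fixed fraction of
its stride after its IC (`stance_fraction`, default 0.723/1.152 ≈ 0.628 so
that a 1.152 s stride carries a 0.723 s stance). The identity

stance_L + stance_R − stride = double support

holds exactly in the ground truth, and `stance_fraction > 0.5` guarantees
positive double support, as in real walking.

### Foot trajectories

During stance the foot translates backward at belt speed with the heel on
the ground. During swing:

- the **vertical** coordinate follows a plateau profile of height
  `swing_peak_height` (default 5 cm) with short smoothstep lift and descent
  ramps. Ramp lengths are fixed fractions (defaults 10%) of the *typical*
  swing duration, so every lift/descent has the same speed profile,
  including the open-ended cycle at the trial boundary;
- the **anteroposterior** coordinate performs a smoothstep transfer whose
  boundary velocities match the belt, completed *before* the final descent.
  Consequently, in the last ~43 ms before contact the foot's forward
  coordinate already lies on the stance (belt-speed) line, as a foot about
  to land does.

Why not a single symmetric raised-cosine hump? The package's event detector
(below) defines IC/TO through extrema of vertical foot velocity. A
symmetric hump places its velocity minimum at 75% of swing — more than
100 ms before true contact at ordinary walking speeds — which no kinematic
detector interprets as heel strike and which would make step length at
"IC" meaningless. Real heel trajectories concentrate the descent in the
final portion of swing; the plateau-with-ramps profile reproduces exactly
the feature that makes velocity-based detection work on real data: the
velocity extrema sit within one video frame of the true events (≈ ±21 ms
with the default ramps).

Mediolateral foot positions alternate around the body midline with a new
half-offset drawn at each landing, so the heel-to-heel distance at IC (step
width) has the configured mean and step-to-step SD. The hip is the midpoint
of the two foot centres; a head-top landmark at `subject_height` supports
pixel calibration.

### Devices

Each `device_spec` samples the same continuous model at its own frame rate,
in meters or pixels (`pixel_scale`, default 500 px/m for a ~1.74 m subject
filling a 1080 px-tall full-HD frame at a few meters distance), with
i.i.d. Gaussian landmark noise per coordinate and frame. Defaults state the
emulated protocol: a "VIC" metric reference at 100 fps with 0.5 mm noise
(marker-grade) and an "OV" pixel stream at 30 fps with 2 px noise
(pose-estimation grade), each observed in the sagittal and frontal planes.

### Cohort-level variation

`simulate_cohort()` draws per-subject characteristics at the scale reported
for healthy adults on a treadmill at 4 km/h: step time 0.576 ± 0.029 s,
step length 62.2 ± 3.3 cm, step width 10.6 ± 2.7 cm, height 1.74 ± 0.06 m,
with left/right asymmetries calibrated so that mean gait symmetry lands
near 97%. Within-subject SDs (12 ms step time, 1.9 cm step length, 1.2 cm
step width) are not printed in typical study tables; they were chosen once
to give a within-subject step-length CV of about 3%, the magnitude reported
as "gait variability" for healthy treadmill walking, and are not tuned
thereafter.

### What the generator does *not* emulate

No pose-estimation failure modes (identity switches, occlusion dropouts
beyond the optional uniform dropout, soft-tissue artifact), no camera
perspective or lens distortion (the pixel projection is a pure scaling), no
belt-speed fluctuation, and no foot rotation (heel and toe share one rigid
translation). A green test therefore establishes that the *pipeline*
recovers what the model encodes at realistic noise and sampling — not that
any particular commercial system would achieve the same numbers on video.

## Signal preprocessing

Pixel streams are smoothed with a zero-phase (forward–backward)
second-order Butterworth low-pass at 3 Hz — above the 0.5–1.5 Hz gait band,
below landmark jitter. Two consequences are documented rather than hidden:

- the effective −3 dB point of the double pass is ≈ 2.4 Hz, and the
  rolloff is gentle: re-filtering changes a 0.8 Hz component by < 0.03%,
  but a 1.5 Hz component by ~6%;
- a zero-phase filter preserves event *timing* (no lag) but overshoots
  around rapid position transitions by 1–3% of the transition amplitude.
  For the swing-to-stance transition of the foot this produces a
  centimetre-scale transient in the filtered forward coordinate around
  contact — the mechanism behind the small positive step-length bias of
  filtered video streams relative to ground truth.

Edges are handled by odd-symmetric extension of 3×(order+1) samples with
step-matched initial filter states (a constant series passes through
unchanged). The implementation was verified against an independent
reference implementation on frozen fixtures. Gaps up to 5 frames are
linearly interpolated; longer gaps reject the trial.

The metric reference stream is *not* filtered by default (its simulated
noise is sub-millimetre; the real counterpart is smoothed by the capture
software upstream); `apply_filter = TRUE` opts in.

Pixel-to-metre conversion multiplies by `subject_height /
reference_span_px`, the span being the median vertical head-to-lower-heel
distance. Taking the lower of two noisy heels biases the span upward by
σ/√π (≈ 1.1 px at 2 px noise) — about 0.13% of scale, negligible against
the ~1% agreement bands of interest, and the median makes it robust to
outliers.

Device clocks are aligned with `sync_by_events()`: the median signed time
difference between order-matched same-type/same-side events. The median
absorbs a few misdetections and also removes any common systematic
detection offset between the streams, which is exactly the convention a
real study applies when it synchronizes "in accordance with gait events".

## Event detection

The default velocity method: foot centre = heel/toe midpoint; vertical
velocity by central differences; IC = prominent local minima, TO =
prominent local maxima, at most one per cycle (minimum separation = half
the dominant stride period, estimated from the autocorrelation of heel
height; a flat autocorrelation raises a no-gait error). Peak prominence is
enforced as 25% of the 98th percentile of |velocity|, which rejects noise
wiggles without tuning per trial. Event times are refined by a quadratic
through the extremum and its neighbours; at 30 fps raw frame quantization
(±17 ms) would otherwise dominate the few-ms cross-device errors of
interest.

Known bias: with the default ramps, detected IC precedes true contact by
half the descent ramp (~21 ms) and detected TO lags true lift-off by half
the lift ramp (~21 ms), in *both* devices. Cross-device timing errors and
all step/stride intervals are unaffected (the bias cancels); stance time
and double support carry it with respect to ground truth (~ +43 ms and
+86 ms respectively) but remain comparable *between* devices, which is what
a method-comparison study measures. Step length is immune because the foot
already travels on the stance line when detection fires.

The coordinate method (heel forward-position maxima / toe backward-position
minima relative to the hip) is provided as an alternative for
sagittal-plane data; the two methods label the same cycles with small,
stable systematic offsets relative to one another.

Matching between device streams is greedy nearest-in-time, one-to-one,
within ±100 ms (below half of any plausible step time), per event type and
side; unmatched reference events count as misses.

## Gait parameters

Step time: IC(side) → IC(contralateral). Stance time: IC → next TO of the
same foot (seconds primary; percent-of-stride exposed as `stance_pct`).
Double support per stride: stance_L + stance_R − stride (seconds primary;
percent variant exposed). Step length: anteroposterior toe-to-toe distance
at IC, interpolated at the refined event time (instantaneous, as the
treadmill convention defines it — not belt-displacement integrated). Step
width: mediolateral heel-to-heel distance at IC. Cadence: 60·(n_IC −
1)/span of ICs. Gait variability: mean over sides of the per-side CV of
step length (sample SD, n−1, as in the gait literature). Gait symmetry:
100·(1 − 2|Xr − Xl|/(Xr + Xl)); the absolute difference is a deliberate
choice — the index must not exceed 100 or depend on which side is labelled
right — resolving a sign ambiguity in the printed formula of the emulated
study.

Summaries compute per-side means first, then average sides ("mean of both
sides"), yielding seven sagittal metrics and five frontal metrics.

## Agreement statistics

Lin's CCC uses the original 1/n-moment estimator (the study this package
emulates cites Lin without naming a variant; the population form makes the
hand-computable test oracles exact). Heuristic bands follow the
conventional table. Bland–Altman limits are mean ± 1.96 sample SD of the
differences; points strictly outside count as outside (ties are inside).
CVs are reported per device. Pearson correlation is computed internally
only to verify the attenuation property |CCC| ≤ |r| in tests — it is not
reported, since location/scale shifts make it misleading for agreement.
No confidence intervals are attached to the CCC (point estimates only).
Shapiro–Wilk normality and a Breusch–Pagan regression of squared residuals
of (x − y) on the pairwise means annotate the analysis; they never block
it. Display rounding is 3 decimals, half away from zero; internal
computation keeps full precision.

## Numerical and edge-case choices

- Truncated-normal step draws (±3 SD, floors) prevent non-physical
  negative times/lengths without changing the draw count, keeping seeded
  streams aligned.
- The virtual post-trial landing of each foot is placed beyond the trial
  end so no untracked touchdown appears inside the analyzed window; the
  virtual pre-trial toe-off *is* part of the trajectory and of the ground
  truth.
- Sub-frame refinement offsets are clamped to ±0.5 frames.
- Seeds: per-subject seeds are derived from the cohort seed by a fixed
  integer recurrence kept below 2^31; identical config + seed is
  bit-reproducible, and the caller's RNG state is restored.
- Degenerate inputs raise typed, named errors (configuration, pairing,
  plane, no-gait, insufficient-data) rather than returning NA silently.

## Limitations

Stance-phase durations inherit the detector bias against ground truth noted
above; absolute stance/double-support values should be read as
device-comparable, not as gold-standard contact times (a force-plate, not
kinematics, would provide those). The agreement tables of a 16-subject
simulated cohort reproduce the *structure* and error scale of a real
validation study, not its exact printed coefficients, which depend on
per-subject data that are not public; the package ships those printed
summary rows as `benchmark_values()` for arithmetic cross-checks only.
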