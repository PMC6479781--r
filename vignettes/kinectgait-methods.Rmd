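---
title: "Validating markerless gait kinematics: models, calibration and agreement statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating markerless gait kinematics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kinectgait)
```

## The problem

Clinical three-dimensional gait analysis (3DGA) with optical marker systems
is the reference standard for quantifying lower-limb kinematics, but it is
expensive, slow to set up and demanding for restless pediatric patients.
Consumer depth sensors track a reduced skeleton without markers and could
bring gait screening to clinics and homes — if their joint angles can be
trusted, or made trustworthy by calibration. `kinectgait` implements a
complete desk-scale replica of that validation problem: joint kinematics from
both measurement streams, two calibration methods, and the agreement
statistics with which such devices are judged (RMSE, the coefficient of
multiple correlation, normality-gated correlation, Bland–Altman limits of
agreement, ICC(2,k) and the standard error of measurement).

Because the underlying clinical recordings of studies in this area are
essentially never deposited, the package ships a synthetic-gait generator as
a first-class module: ground-truth angle profiles drive a rigid
forward-kinematic chain that emits both the optical marker set and the
depth-sensor landmark set, the latter through a parameterized distortion
model. Every downstream stage is therefore testable against known truth.

## Kinematic models

**Coordinate conventions.** Lab frame: +X walking direction, +Y up, +Z the
right-handed completion (the subject's right). Canonical anatomical segment
axes: x mediolateral (subject's right), y anterior, z longitudinal
(proximal). All angles are degrees; positions are metres; time is seconds.

**Marker-based (reference) segment frames.** The pelvis frame sits at the
midpoint of the mid-ASIS point and the sacrum, x toward the right ASIS, z
normal to the ASIS–sacrum plane (superior), y completing the triple. The hip
joint center is placed from the pelvis origin by fractional offsets of the
inter-ASIS distance along the pelvis axes (Bell-style regression offsets,
default `(0.36, -0.19, -0.30)`; injected configuration, never hard-coded).
Thigh and shank frames use the medial/lateral joint-marker midpoints as
origins with the longitudinal axis toward the proximal origin; the foot frame
sits at the 2nd metatarsal head. The published definition of the foot frame
lists its y axis twice and never defines z; we use the unique right-handed
reading consistent with the other segments (y toward the shank origin, x
normal to the heel–toe–shank-origin plane pointing right, z = x × y).

Medial knee/ankle markers are removed after the static calibration trial, as
in standard protocols. Their gait-time positions are reconstructed as
segment-fixed points: rigid (SVD/Kabsch) fits of the thigh and shank cluster
markers map the static-trial medial positions into each gait frame. On rigid
noiseless data this reconstruction is exact.

**Euler sequence and signs.** Joint angles decompose the relative rotation
`R = proximal^T distal` in the intrinsic mobile-axis sequence
flexion/extension → ab/adduction → internal/external rotation (x–y–z on
canonical frames). For a right limb the signs come out clinical: flexion,
adduction and internal rotation positive. Knee flexion is negated from the
raw Euler term so a flexed knee is positive; ankle dorsiflexion is positive.
Gimbal proximity (|adduction| > 89°) is flagged, never thrown, since the
middle angle stays far below this in gait.

**Depth-sensor frames.** The reduced landmark set supports full Euler angles
at the hip only: the pelvis frame comes from spine base/mid and the two hip
landmarks; the thigh frame needs the ankle landmark to span a plane, which
makes its mediolateral axis flip sign when the knee crosses full extension.
The implementation re-anchors that axis to the pelvis so hip angles stay
continuous, and carries the previous frame forward when the three landmarks
are exactly collinear (interpolating would fabricate axial rotation). Knee
and ankle are vector angles: the knee angle is the turning angle between the
hip→knee and knee→ankle vectors (0° when straight); the ankle angle is the
angle between ankle→knee and ankle→foot referenced to 90°. The printed
convention "angle − 90°" would be plantarflexion-positive; we report
`90° − angle` so dorsiflexion is positive in both systems, which is what the
calibration step requires.

A consequence worth knowing: hip axial rotation from the depth stream is
ill-conditioned near knee extension (the thigh plane degenerates), so its
errors are large and survive linear calibration — the same qualitative
behavior reported for real depth sensors.

## Signal processing

* Depth-sensor streams arrive at a fluctuating ~30 Hz; they are resampled to
  a uniform grid by cubic splines before filtering (resample-then-filter is
  mandated; the alternative order is unstated in the source protocols).
  Dropout gaps longer than 0.2 s invalidate the segment rather than being
  bridged.
* Both streams are low-passed with a 4th-order Butterworth at 6 Hz, applied
  forward–backward (zero phase, so event timing is preserved; effective
  order 8). No IIR filter design exists in the dependency stack, so the
  bilinear-transform design and the odd-reflection-padded, steady-state
  initialized filtfilt are implemented in the package and tested against the
  analytic magnitude response.
* Gait cycles run from one right-foot initial contact to the next and are
  resampled to the closed 101-point grid 0%–100% by cubic interpolation.

**Event detection.** Initial contacts are found coordinate-style (Zeni): local
maxima of the heel's (depth dialect: right ankle's) anterior displacement
relative to the pelvis center, with a minimum spacing of half the median
stride and a 1 cm excursion floor (a standing trial has no cycles). The rule
is threshold-free and needs no force plates, matching the markerless use
case. Events are detected independently per system and cycles paired by
temporal overlap, which tolerates a missed event on either side.

## Calibration

Cycles are stacked as gait tensors `G (n × 101 × 5)` in the DOF order hip
flexion/extension, hip ab/adduction, hip internal/external rotation, knee
flexion/extension, ankle dorsi/plantarflexion. The two methods are fitted on
different data, following the study design they replicate: the linear
regression on a designated *calibration subject* (one additional subject
recorded as an individual calibration dataset, disjoint from the evaluation
cohort), the LSTM on the evaluation tensors themselves — its reported
performance is training-set performance. We verified the alternative
(fitting the LSTM on the calibration subject too): three near-identical
cycles from one subject make the sequence model collapse to predicting that
subject's mean curve, and it then transfers worse than linear regression on
every DOF. The cohort-trained LSTM is what the source protocol describes,
and its shape-memorization tendency is a real, documented weakness of that
design — visible here exactly as in the original (collapsed output SDs,
poor discrete-parameter correlations, yet the best waveform RMSE).

**Linear regression** fits, per DOF, ordinary least squares of the reference
angle on the markerless angle pooled over all trials and time points. It is
exactly idempotent (refitting its own output returns slope 1, intercept 0)
and exact on affine distortions.

**LSTM.** A two-layer LSTM with 100 memory cells per layer and a linear
per-time-step read-out, trained full-batch with plain gradient descent at
learning rate 0.006 — both stated architecture/optimizer facts honored
literally. Choices the source leaves open, with our defaults and reasons:

* *Standardization*: inputs and targets are z-scored per DOF with training
  statistics and de-standardized on output. The stated learning rate is only
  usable on scaled data; we document this as an interpretation.
* *Loss*: mean squared error over all time steps and DOFs.
* *Gradient clipping*: global norm 5, on by default, purely to prevent
  divergence of plain gradient descent; it never activates near convergence.
* *Epochs*: configuration (default 500 with early stop when the relative
  loss change stays below 1e-6 for 20 epochs). Plain full-batch gradient
  descent is slow; the acceptance-grade runs use 3000 epochs, which fits in
  a few CPU-minutes at this data scale.
* *Initialisation*: uniform(−1/√H, 1/√H) with forget-gate biases at 1,
  seeded; training is bit-deterministic given the seed.

## The synthetic world

`generate_true_angles()` samples per-DOF truncated Fourier series (order ≤ 4)
at 100 Hz. The defaults mimic mildly crouched pediatric sagittal curves (hip
flexion ≈ 35 ± 15°, knee ≈ 5–55°, cadence 120 steps/min). The sagittal
channels use cosine (even) harmonics only, which pins the heel-forward
extremum — the generator's initial-contact definition — exactly onto the
cycle boundary; frontal/transverse channels may use sine terms freely.
`perturb_profile()` turns the base profile into synthetic subjects (amplitude
scaling ±15%, per-DOF mean shifts of SD 2°, anthropometry ±8%, cadence
±10%); two-day cohorts add a per-day mean shift (SD 2°) emulating day-to-day
gait and sensor placement changes.

`forward_markers()` and `forward_kinect()` place landmarks by inverting the
exact frame constructions of the analysis side, so the marker pipeline
recovers the generated angles to ~1e-14° before filtering (< 0.1° with the
6 Hz filter, which slightly attenuates the 3rd/4th harmonics) and the depth
pipeline recovers identity-distorted angles to interpolation error (< 0.5°).
One deliberate idealization: the virtual 2nd-metatarsal marker sits directly
distal along the foot's longitudinal axis, which makes the printed foot-frame
construction exactly invertible; real marker placement would add a constant
offset that a static trial would absorb.

The distortion model is affine per DOF (`gain · θ + offset`) plus an optional
cubic term, additive landmark noise (default SD 4 mm), Gaussian timestamp
jitter clipped to keep time strictly increasing (default SD 3 ms), and
Bernoulli frame dropout (default 2%). The default world gives the sagittal
hip a gain of 0.7 (the device under-reads flexion and over-reads extension),
modest affine error elsewhere, and a strongly nonlinear ankle distortion
(gain 0.6, offset −8°, cubic 8e-3 deg⁻²): foot tracking is the documented
dominant failure mode of depth sensors, its error is systematic rather than
random, and making it non-affine is precisely what separates the two
calibration methods — the linear method cannot remove it, the LSTM can.
These magnitudes are free parameters of the synthetic world, not estimates
of any physical device.

**What a green test does and does not establish.** The generator produces
rigid segments, periodic even-harmonic gait, stationary Gaussian noise and a
pointwise-in-angle distortion. Real data have soft-tissue artifact,
aperiodic variability, occlusion-correlated tracking failures and
distortions that depend on pose and distance. Green round-trip and
direction-of-effect tests establish that the pipeline's mathematics and the
calibration machinery are correct — not that any physical sensor achieves
these error levels.

## Agreement statistics

* **RMSE** per cycle pair over the 101-point grid; across-subject summaries
  are mean ± SD.
* **CMC** (Kadaba): `sqrt(1 − within-time-point variance / total variance)`
  over a waveform set. When between-waveform variance dominates, the
  radicand is negative; the printed convention in this literature is the
  sentinel `<0.001`, which we reproduce (the raw radicand is kept for
  diagnostics). All-identical waveforms are defined as CMC 1 with a
  degeneracy flag. In report cells, sentinel per-subject values enter the
  mean as 0 and a cell mean below 0.001 prints as the sentinel. Bands:
  excellent 0.95–1, very good 0.85–0.94, good 0.75–0.84, moderate 0.6–0.74,
  poor below.
* **Correlation of discrete parameters** (per-DOF maximum, minimum, ROM and
  angle at initial contact): each variable is screened with Shapiro–Wilk at
  α = 0.05; Pearson if both pass, Spearman otherwise. Either variable
  failing triggers Spearman — the source is silent on the pairwise logic, so
  the conservative reading is used.
* **Bland–Altman**: mean difference ± 1.96 sample SD of the differences.
* **ICC(2,k)**: two-way random effects, absolute agreement, mean of k
  ratings, computed from the ANOVA mean squares with the McGraw & Wong
  F-based 95% CI (single-rating bounds Spearman–Brown stepped up to k). It
  is hand-rolled so the CI method is explicit and testable; the
  implementation reproduces an independent reference implementation to six
  decimals. k is taken from the data's repeated dimension (2 for a two-day
  design, even where a source reports k = 3 from its three-trial structure —
  the repeated factor in the reliability question is the day). Negative
  estimates are legitimate and reported (bands: excellent 0.75–1, modest
  0.4–0.74, poor below, flooring negatives).
* **SEM** = SD·√(1 − ICC), with SD the pooled standard deviation of all
  measurements entering the ICC; a negative ICC yields SEM > SD, as it
  should.

Per-cycle discrete parameters are extracted per cycle and then averaged
(the alternative — averaging waveforms before extraction — is exposed by
composing `average_cycles()` first).

## Numerical choices and degenerate inputs

* Frames are validated orthonormal to 1e-6 and right-handed at construction;
  collinear marker triples raise named errors.
* The CMC sentinel and the ICC degenerate case (zero between-subject
  variance → 0 with a flag) are explicit rather than NaN.
* `fit_linear_calibration()` refuses constant predictors per DOF.
* LSTM divergence (non-finite loss) raises an error advising a lower rate.
* Cycle normalization requires ≥ 4 samples; resampling requires ≥ 2 frames
  and refuses gaps > 0.2 s.

## Known limitations

* No left-limb analysis; left landmarks exist only so pelvis frames are
  constructible (synthesized by half-cycle phase shift).
* No pelvis-vs-lab angles (pelvic tilt/obliquity), no toe-off detection, no
  spatiotemporal parameters, no stance/swing sub-phase statistics.
* The LSTM is desk-scale: full-batch CPU training on tens of cycles; no
  hyperparameter search, no cross-validation machinery.
* The synthetic distortion is pointwise in the angle; it cannot emulate
  occlusion bursts or distance-dependent bias.
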