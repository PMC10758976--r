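---
title: "Quantifying pad-induced mobility restriction: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying pad-induced mobility restriction: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(padrom)
```

## The problem

Protective equipment such as ice hockey shoulder and elbow pads must absorb
impacts without destroying the wearer's mobility. padrom implements a
complete analysis chain for quantifying that trade-off from inertial motion
capture: frame-wise unit-quaternion orientations of upper-body segments are
turned into clinical joint angles, ranges of motion (ROM) are extracted for
static single-joint tasks and for event-segmented shooting motions, pad
conditions are compared with repeated-measures statistics, and the objective
restriction is related to subjective Likert comfort ratings. The reference
design is nine players x eleven tasks (nine static, wrist shot, slap shot)
x six equipment conditions (an unpadded control and five pad models) x five
repetitions, sampled at 96 Hz.

## Kinematic model

Each body segment carries a scalar-first unit quaternion
$q = (w, x, y, z)$ in a shared global frame (Hamilton convention; $q$ and
$-q$ encode the same rotation and canonicalization forces $w \ge 0$). The
rotation of a joint is the relative rotation between its two segments,

$$q_{\mathrm{joint}} = q_{\mathrm{prox}}^{-1} \otimes q_{\mathrm{dist}},$$

where $\otimes$ is quaternion multiplication and the proximal segment is
always the inverted operand. Descriptions of this formula in the
literature occasionally swap which operand is called "rb1"; the package
fixes the convention above and documents it rather than guessing from
context.

Joint quaternions are decomposed in the intrinsic Y--X'--Z'' order with a
single configurable channel-to-plane table: Y carries flexion/extension, X
abduction/adduction, Z axial rotation (internal/external rotation at the
shoulder, pronation/supination at the forearm). Ranges are
$(-180, 180]$ for Y and Z and $[-90, 90]$ for X. At the $|X| = 90^\circ$
singularity the Y and Z rotations share an axis; the tie-break sets
$Z = 0$, folds the coupled rotation into Y, and flags the frame
(`gimbal_tol` = 0.01 deg).

Because X is the bounded middle axis, a single-plane excursion beyond
90 deg (full shoulder abduction reaches ~166 deg) makes the raw
decomposition fold back: X reflects while Y and Z both jump by 180 deg.
`unfold_gimbal()` detects these simultaneous jumps between consecutive
frames and reconstructs the continuous channel, so static ROM on the X
channel is not truncated at 90 deg. This is a property of every
three-angle parameterization, not of the data.

### Filtering

Smoothing is a 4th-order Butterworth low-pass at 6 Hz applied to the four
quaternion components (after antipodal sign alignment of consecutive
frames), followed by frame-wise renormalization — the components, not the
derived angles, are what gets filtered. The filter is run forward and
backward, so it has zero phase lag and a doubled effective attenuation
order; this is the standard treatment for movement signals, where phase
distortion would shift event timing. Edges are handled by odd reflection
plus steady-state initialization of each pass, which makes the DC gain
exactly 1 in practice (a constant stream is reproduced to ~1e-13); naive
zero-initialized passes would bend the first ~0.2 s of every trial.
Both cutoff and order are arguments throughout.

## ROM extraction

**Static tasks.** ROM is the absolute difference between the initial
anatomical angle and the task-direction extremum of the task's channel.
The anatomical baseline is the mean of the first 0.25 s (24 frames at
96 Hz) — a held starting posture is part of the protocol, and a short mean
is robust to single-frame noise; the window length is configurable. Left
and right sides are averaged within each repetition, then repetitions are
averaged, giving one value per participant x condition x task cell.

**Shots.** Two events segment the wrist shot (shot initiation SI, shot
release SR) and three the slap shot (SI, swing top ST, SR). Detection
criteria, with configurable thresholds:

* SR — the frame of peak lead-hand angular speed (geodesic frame-to-frame
  rotation angle times the sample rate, smoothed with the same low-pass);
* SI — walking backward from the peak, the first frame of the contiguous
  run in which the speed stays above 10% of the peak;
* ST — the extremal backswing: the maximum of the lead-shoulder flexion
  channel between SI and SR.

A motionless trial fails loudly (`min_peak_speed`, default 200 deg/s).
All shooters are pooled in left-handed form: right-handed trials are
mirrored by swapping left/right segment labels and negating the X and Z
rotation components (equivalently the abduction and axial-rotation Euler
channels), which leaves sagittal-plane motion untouched. The geometric
mirror is an involution; the pipeline wrapper applies it only to
right-handed trials.

Phase ROM is the max minus min of a channel inside the closed event
window (SI-SR for the wrist shot, SI-ST and ST-SR for the slap shot).
The windowed-extrema definition was chosen over the end-point difference
because condition tables for such designs report plane-pair ROMs
(flexion/extension and the like), which only an extremum difference can
produce; the alternative is noted in the function documentation.

## Statistics

For each joint plane a complete participants x conditions matrix feeds a
one-way repeated-measures ANOVA: $SS$ is decomposed into condition,
subject and error terms, $F = MS_{\mathrm{cond}} / MS_{\mathrm{err}}$, and
partial eta-squared is $SS_{\mathrm{cond}} / (SS_{\mathrm{cond}} +
SS_{\mathrm{err}})$ with bands 0.01 / 0.06 / 0.14 (below / small / medium
/ large). The Greenhouse–Geisser epsilon is estimated from the
double-centered sample covariance of the conditions and bounded in
$[1/(k-1), 1]$.

How the correction is applied is a policy argument. Always-on correction
is markedly conservative when sphericity actually holds at this sample
size: with $n = 9$, $k = 6$ the estimated epsilon is biased well below 1,
and null simulations of the design reject at roughly 2% instead of the
nominal 5%. The package therefore defaults to the common workflow of
gating the correction on Mauchly's test (`sphericity = "mauchly"`), which
calibrates to ~4.5% under the spherical null while still correcting when
sphericity fails; `"always"` and `"never"` are available, and both
corrected and uncorrected p-values are always returned so the policy is
transparent.

Post-hoc comparisons follow the least-significant-difference procedure:
uncorrected pairwise paired t-tests, run only when the omnibus test is
significant (the gate is the caller's, or the pipeline's, responsibility).
Survey scores are ordinal, so inference uses the Friedman rank test
(average-rank ties; an all-tied matrix degenerates to statistic 0, p = 1)
followed by Wilcoxon signed-rank tests. Zero differences are dropped
(the classical treatment) and tied absolute differences get average ranks;
the two-sided p-value is exact up to n = 25 — computed by dynamic
programming over the doubled observed ranks, so ties are handled exactly —
and tie-corrected normal beyond. Spearman correlations use Pearson on
average ranks with an exact permutation p-value up to n = 8 (the five-pad
comparisons are exact) and the t approximation above; strength bands are
0.1 / 0.3 / 0.5 (negligible / low / moderate / high). Alpha is 0.05
throughout. One further naming note: sources describing this analysis
occasionally misspell the method ("Spielman"); the implemented statistic
is Spearman's rank correlation.

## The synthetic study generator

The generator exists so that every downstream stage can be validated
against known ground truth without laboratory data. It emulates the
reference design's structure and effect sizes, not raw biomechanics:

* **Effect sizes.** Per-condition, per-plane restriction factors
  $f \in (0, 1]$ (pad ROM over control ROM) are seeded from the published
  condition tables. Two printed static control means are internally
  inconsistent with the same study's restriction percentages (shoulder
  external rotation and elbow flexion appear transposed in print); the
  generator uses the percentage-consistent values (70.7 and 138.6 deg)
  via `reference_control_rom()`, while `printed_table()` keeps the tables
  verbatim. A few printed dynamic pad/control ratios marginally exceed 1
  and are clipped to 1.
* **Trajectories.** Static tasks follow a minimum-jerk profile: 0.5 s
  anatomical hold, 1.5 s rise to the peak, 0.75 s hold, 0.75 s return —
  smooth, bounded, and differentiable, with the held baseline the static
  ROM definition expects. Shot channels rise monotonically from SI to ST
  and fall to SR (a single monotone excursion for the wrist shot) with
  raised-cosine segments; the cosine keeps the curvature at the swing-top
  peak non-zero so the extremum stays localizable under noise, and
  monotonicity makes the designed amplitudes exactly the per-phase ground
  truth. A dedicated wrist-snap rotation gives the lead hand an angular
  speed profile that plateaus after SI and peaks (1200 deg/s) exactly at
  SR. Ground-truth events are recorded by running the event criteria on
  the noiseless streams.
* **Noise model.** ROM varies additively: between participants (SD 8 deg),
  participant x condition (SD 3 deg), repetition (SD 1.5 deg), side
  asymmetry (SD 1 deg); dynamic amplitudes use proportional counterparts
  (8% / 8% / 5%). Orientation noise is white Gaussian on the Euler
  channels (SD 0.5 deg per frame) added before composition into
  quaternions, then attenuated naturally by the pipeline's filter. These
  are repeatability levels typical of controlled inertial-capture
  protocols; the per-plane condition means they produce sit in the regime
  of the published tables, though the implied F statistics are larger than
  the published ones (whose error terms suggest an interaction SD nearer
  8 deg — at that level per-condition restriction estimates from nine
  participants would carry ~2.3 percentage points of standard error).
* **Comfort.** Each protector's injected restriction (mean $1 - f$ over
  its planes) drives a latent comfort variable with coupling coefficient
  0.9: comfort and willingness-to-wear fall with restriction, perceived
  restriction rises, safety is independent. Scores are rounded onto the
  1–5 scale; a deterministic per-participant leniency offset spreads the
  rounding thresholds so five-pad mean scores resolve finely. At coupling
  1 with no orthogonal noise the recovered ranking is exactly the inverse
  restriction ranking.
* **Reproducibility.** Every draw comes from a counter-based substream
  keyed by the global seed and the trial labels, so a single trial is
  reproducible in isolation and `write_study()` output is byte-identical
  across runs.

What the generator does *not* emulate — soft-tissue artifact, sensor
drift, inter-joint coordination variability, pad-fit idiosyncrasies,
fatigue — bounds what passing tests demonstrate: the pipeline recovers
known effects from clean, correctly-labelled quaternion streams; it says
nothing about sensor-fusion quality upstream of those streams.

## Validation sizes and tolerances

The test suite and `scripts/acceptance.R` use these problem sizes, chosen
to estimate each quantity stably: 2000 null simulations and 500
effect-size simulations of the 9 x 6 design for type-I error and power;
20 seeds of the full default single-task design (9 participants x 6
conditions x 5 repetitions) for restriction recovery within 3 percentage
points; 10 seeds of single-repetition static studies for the
comfort-correlation recovery; a single-repetition full design for the
594-cell count (the cell count depends only on the participant x task x
condition crossing); and 500-quaternion batches for the 1e-6-degree
decomposition round trip. Exact-test implementations are checked against
full enumeration (2^9 sign assignments, 5! permutations) and the ANOVA
against a brute-force sums-of-squares oracle at 1e-8.

## Known limitations

* The YXZ plane mapping is fixed per joint type; protocols that use
  joint-specific rotation orders need a different mapping table.
* Event detection assumes the lead hand produces the dominant angular
  speed peak; unorthodox shooting styles may need threshold tuning.
* The Likert model treats questions as conditionally independent given
  the latent restriction; real surveys show halo effects.
* Exact Wilcoxon p-values are computed up to n = 25 and exact Spearman
  p-values up to n = 8; larger samples use the stated approximations.
* BVH ingestion is limited to the quaternion trial CSV dialect plus the
  manifest; hierarchy-bearing capture formats must be converted upstream.
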