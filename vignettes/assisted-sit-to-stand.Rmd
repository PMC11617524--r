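---
title: "Gaze and kinematics of assisted sit-to-stand: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gaze and kinematics of assisted sit-to-stand: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(standgaze)
```

## The problem

When a therapist helps a patient stand up from a chair, two data streams
describe the interaction: where the therapist looks (a wearable eye
tracker sampling gaze at 50 Hz), and how the patient's body moves (optical
motion capture at 100 Hz plus six force plates at 1,000 Hz, with the chair
standing on the two rear plates). `standgaze` implements the full
quantitative chain for this setting:

* **gaze**: I-VT fixation detection, landmark-anchored areas of interest
  (AOI) on the patient's body, and the four standard AOI metrics (total
  duration of fixation as % of the support period, number of fixations,
  mean fixation time per visit, latency to first fixation);
* **kinematics**: zero-phase smoothing, virtual reconstruction of occluded
  pelvis markers, a ten-segment whole-body centre of mass (COM), trunk
  Cardan angles, seat-off and peak-ankle-dorsiflexion events, and the
  three per-trial indices — deepest forward trunk flexion, forward COM
  velocity between seat-off and maximum dorsiflexion, and the signed
  COM-to-heel (base-of-support) distance at seat-off;
* **statistics**: a two-factor mixed-design ANOVA (experience group ×
  AOI) with simple main effects and Bonferroni pairwise comparisons for
  the gaze metrics, and pooled trial-level t-tests for the kinematic
  indices;
* **a seeded synthetic-data generator** that emulates the recording
  setup, so that every stage is testable end to end without any human
  recordings.

The laboratory frame is x lateral-right, y forward (positive), z up;
positions are metres, forces newtons, angles degrees with anterior tilt /
flexion / dorsiflexion positive.

## The synthetic cohort

The generator is a first-class module, not a fixture. Its defaults are the
study conditions the analysis targets: 7 expert and 17 novice therapists,
5 trials per participant, 5 consecutive stand-up/sit-down cycles per
trial, markers at 100 Hz (34 body markers plus a 3-marker sacral jig),
six plates at 1,000 Hz, gaze at 50 Hz. Group-level distributions of the
kinematic indices and of the per-AOI gaze profiles default to the
published group means and standard deviations
(`default_group_params()`).

### Motion model

Each trial realises a planar (sagittal) articulated chain — feet fixed on
the ground, shank, thigh, pelvis, trunk-with-head, hanging arms — driven
by minimum-jerk joint-angle profiles through a fixed phase sequence per
cycle: seated pause, forward lean (trunk flexion rises to its scripted
peak), a short hold during which the chair unloads (seat-off at the hold
midpoint), rise, quiet stance, and sit-down. All the reported indices are
sagittal, which is why a planar chain with small lateral noise suffices.
The deepest flexion is reached at the end of the lean and relaxes by 3%
through the hold, so the per-cycle flexion maximum is unique and always
precedes seat-off even under measurement noise.

Three scripted quantities define a trial (`motion_script()`), and two
per-trial calibrations make them exact at zero noise:

* **Deepest trunk flexion** is the lean peak directly.
* **COM-BOS distance at seat-off** is met by solving (bracketed root
  search) for the seated shank angle — i.e. where the feet are planted
  relative to the body — which monotonically moves the whole-body COM
  relative to the heel line.
* **Forward COM velocity** between seat-off and maximum dorsiflexion is
  met by a smooth whole-body forward translation ramp inside the rise.
  Because it is a rigid translation it changes no joint angle, no trunk
  angle and no COM-to-heel distance at seat-off; it only sets the COM
  forward travel across the window.

The indices are anchored at the instant the summed rear-plate force
crosses the event detector's default 5 N threshold. The rear plates
unload along a minimum-jerk profile reaching exactly 0 N at the scripted
seat-off; the crossing instant therefore sits a computable fraction of
the unloading window before the zero (the quintic is solved exactly), and
because the profile has no slope discontinuity, zero-phase filtering does
not displace it. The body is posturally static at that instant, so
event-timing jitter of a few milliseconds barely perturbs the recovered
indices.

ASIS markers are blanked whenever trunk flexion exceeds a configurable
occlusion threshold (default 25°), emulating the forward-bent torso
hiding the pelvis from the cameras; the sacral jig stays visible and the
pipeline must reconstruct the ASIS from it.

### Parameter hierarchy

Participant-level parameters are drawn from the group distributions and
held fixed across that participant's trials; trials vary around them.
Seventy percent of each group variance is allocated between participants
and thirty percent within (configurable), a conventional split when only
pooled spreads are reported. Kinematic indices use normal draws. The gaze
dwell fractions and fixation counts have standard deviations comparable
to their means, so normal draws would need truncation that inflates the
mean by up to three points; instead they are drawn from Gamma
distributions moment-matched to the configured mean and sd (exact
moments, non-negative support). Dwell and count on an AOI are tightly
coupled in real data — dwell is count times a much less variable mean
fixation duration — so the two are drawn through a Gaussian copula with
correlation 0.95 while keeping both marginals exact.

One master seed is split hierarchically per participant, trial and
stream, so enlarging a cohort never perturbs the trials already
generated, and a fixed configuration is byte-reproducible.

### Gaze streams

Gaze is generated directly in the analysis plane (see below): fixation
episodes are low-velocity point clusters placed at a jittered position
inside the target AOI band evaluated at the episode midpoint, separated
by two-sample saccades through distant points; leftover time is filled
with off-AOI fixations in the lower-shank strip that belongs to no AOI.
Episode durations are laid out on the 20 ms sample grid, accounting for
the arrival sample that the I-VT filter classifies as saccadic, so the
realized dwell equals the drawn dwell almost exactly. Every episode is at
least 60 ms so the filter can recover it; when a drawn count is too large
for the drawn dwell at that floor, the count is capped (with the copula
correlation this is rare).

### What the generator does not emulate

Real recordings contain soft-tissue artefact, marker swaps, gaze-tracker
drift and blinks, non-planar motion, and patient-initiated corrections.
Passing the recovery tests therefore shows that the *pipeline* is
correct and unbiased under the modelled conditions; it does not validate
the pipeline against every artefact of real data. The canonical CSV/TSV
bundle (`write_trial_bundle()` / `read_trial_bundle()`) is the on-ramp
for real recordings.

## Preprocessing

Processing order is synchronise → gap-fill → smooth, which avoids fitting
splines through filtered noise. `synchronize()` anti-alias filters every
force channel (zero-phase Butterworth at 80% of the target Nyquist) and
interpolates onto the marker clock, reproducing the conventional
1,000 → 100 Hz downsampling (10 ms resolution). `lowpass_filter()` is a
4th-order Butterworth run forward and backward (zero phase, squared
magnitude) with odd-reflection padding of at least three characteristic
lengths; cutoffs default to 6 Hz for markers and 18 Hz for forces, the
biomechanics convention. Neither the filter order nor the phase handling
is uniquely fixed by convention, so both are exposed as arguments.
`interpolate_gaps()` fills missing runs up to 0.2 s with a cubic spline
and reports longer runs; leading/trailing gaps are never extrapolated.

## Kinematics

**Virtual ASIS.** A static frame with all 37 markers visible calibrates
the two ASIS offsets in the orthonormal frame of the sacral jig
(`calibrate_virtual_asis()`); during motion, occluded ASIS samples are
reconstructed from the jig under the rigid-pelvis assumption
(`reconstruct_asis()`), and where the real marker is visible the
measured-versus-virtual discrepancy is kept as a quality metric.

**COM.** The body is divided into ten segments (trunk, pelvis, both upper
limbs, thighs, shanks, feet). Because no anthropometric table is uniquely
implied by the setting, the defaults are de Leva's (1996) adjustment of
the Zatsiorsky parameters, with the head-and-neck mass folded into the
trunk segment (the ten-segment division carries no separate head), and
the table is a plain tibble argument so a population-specific table can
be swapped in. The whole-body COM is the mass-fraction weighted sum of
segment COMs.

**Angles.** Segment orientations use an X-Y-Z Cardan decomposition
referenced to the laboratory axes; the x-component is anterior-posterior
tilt (flexion positive). Ankle dorsiflexion is the sagittal angle between
the shank axis and the foot axis, zero for a vertical shank over a flat
foot.

**Events.** Seat-off is the first time the summed rear-plate vertical
force drops below ε = 5 N and stays there for 50 ms, refined to
sub-sample precision by a local quadratic through the bracketing samples
(exact on linear ramps; ε = 0 recovers the literal 0 N definition on
clean data). Maximum dorsiflexion is the earliest maximum of the smoothed
ankle angle after seat-off within the cycle. Per-trial indices are the
mean over the five cycle values; the trial — not the participant — is the
observation unit for the kinematic group tests, matching a pooled
analysis with 120 trial-level observations (df = 118).

## Gaze analysis

**Analysis plane.** The published workflow annotates AOIs on first-person
scene video by hand. Here the AOIs live in a body-anchored 2-D plane
(longitudinal × transverse): six half-open bands `[lower, upper)` bounded
by landmark levels recomputed every frame — chin (head-marker centroid
minus a configurable offset along the trunk axis), acromion, the midpoint
of the acromion-to-hip span, hip line, mid-thigh, mid-shank, lateral
malleolus. The head band is closed above; the lower-shank strip and
everything below the feet belong to no AOI. A shared boundary belongs to
the upper band, which makes the bands pairwise disjoint with a
deterministic tie-break. Using real recordings would require an external
gaze-to-plane registration step, which is out of scope.

**I-VT.** Point-to-point angular velocity (displacement over an assumed
1 m viewing distance) below 30°/s marks fixation samples; runs shorter
than 60 ms are discarded. The threshold and floor are the common vendor
defaults and are exposed as arguments. A fixation's AOI is decided by its
centroid at its midpoint time. Latency for an AOI never fixated is
reported missing and excluded listwise from that metric's ANOVA.

## Statistics

`mixed_anova()` fits the classical split-plot decomposition via
`stats::aov` with an `Error(participant)` stratum: for 24 participants
and 6 AOIs the dfs are (1, 22) for the experience effect and (5, 110)
for the AOI effect and interaction. No sphericity correction is applied
by default; Greenhouse-Geisser is available behind a flag. Simple main
effects of experience at each AOI use the pooled error term
(participants-within-groups plus within-cell error). Because that pooled
mean square mixes two strata, its naive df makes the test slightly
liberal; the implementation uses a Welch-Satterthwaite effective df,
which restores the nominal 5% size (verified by the 1,000-cohort null
calibration in the test suite). Within-group AOI pairwise comparisons are
paired t-tests with Bonferroni adjustment over the 15 AOI pairs;
`bonferroni()` is the plain `min(1, m p)` rule. `trial_t_test()` pools
trial-level observations across participants (35 vs 85) into a
pooled-variance two-sample t-test — this replicates the conventional
trial-level analysis and knowingly ignores within-participant
correlation; a mixed-model alternative is out of scope.

## Numerical choices and problem sizes

* Marker noise defaults to 0.5 mm white noise, force noise to 1 N, gaze
  within-fixation jitter to 1 mm; all configurable.
* The seated-shank solve is bracketed on [-10°, 23°]; a scripted COM-BOS
  outside the reachable seated range (possible for extreme draws from
  the wide novice distribution) is clamped to the nearest reachable
  posture with a warning.
* Zero-noise round trips are tested to 0.1° (trunk), 10 ms (seat-off),
  1 mm (COM travel); under default noise, recovered indices are unbiased
  to within a tenth of the corresponding group sd (40 replicate trials in
  the unit suite).
* The acceptance checks run one seeded default cohort per domain and
  compare recovered group means within Bonferroni-calibrated multiples of
  the standard error implied by the configured spread; the null
  calibration uses 1,000 table-level cohorts, and oracle-equivalence
  checks use 1,000 random gaze streams plus dozens of random poses,
  tables and ramps. These sizes were chosen to keep the whole suite in a
  few minutes on a single core while leaving Monte-Carlo error well below
  every tolerance; the methods do not depend on them.

## Known limitations

* The motion model is planar; frontal-plane indices would need a richer
  chain.
* The generator's feet slide by a few centimetres during the rise when
  the velocity-calibration ramp is active — harmless for the supported
  indices (COM-BOS is measured at seat-off, before the ramp moves), but
  visible if one inspects foot trajectories.
* C3D ingestion is not provided; real motion-capture files should be
  exported to the canonical CSV bundle first.
* Group comparisons at the trial level inherit the pooled analysis's
  optimism about independence; treat the kinematic p-values accordingly.
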