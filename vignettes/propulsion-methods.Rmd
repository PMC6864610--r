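---
title: "Methods: hand-rim propulsion biomechanics in rimdyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hand-rim propulsion biomechanics in rimdyn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rimdyn)
```

## Scope and data model

`rimdyn` analyzes manual wheelchair propulsion on a treadmill from two
synchronized streams: 3D trajectories of a reduced 15-marker upper-limb
model (nominally 50 Hz) and per-side instrumented-wheel recordings of
hand-rim force, moment and wheel angle (nominally 240 Hz). The lab frame is
x forward (travel direction), y to the left, z up. The marker set covers
trunk (`c7`, `acrr`, `acrl`, plus the humeral-head pair `hha`/`hhp` riding
with the trunk), arm (reference cluster `rm1`–`rm3`, epicondyles
`epc`/`ipc`) and hand (styloids `ulr`/`rdl`, metacarpals `2m`/`3m`/`5m`);
the forearm carries no markers of its own and is framed by the elbow and
wrist centres. Streams arrive through a plain CSV dialect (one `# rate=<Hz>`
header line, then named columns); gaps in marker data are flagged at read
time and never silently interpolated — filling is an explicit, bounded
preprocessing step.

## Signal conditioning

Kinetic channels are low-passed with a 4th-order Butterworth filter at
20 Hz applied forward and backward, giving zero phase lag and a net
amplitude of 0.5 at the cutoff (the squared −3 dB point). Edges are handled
by odd reflection over 3× the filter order together with steady-state
initialization of the filter memory, so constants pass exactly and there is
no startup transient. Marker trajectories receive the same filter at a 6 Hz
cutoff before numerical differentiation; this is a package extension (the
protocol filters only kinetics) and is configurable (`marker_filter`),
because inverse dynamics double-differentiates positions and amplifies
everything the filter leaves in.

Both streams start at a shared hardware trigger, so synchronization is
resampling onto one timebase, by default the kinetic rate: derivative-based
variables (force/moment rates of rise) live in the kinetic stream, so the
kinematics are upsampled rather than the kinetics downsampled. Resampling
uses cubic splines in time; a 240→50→240 Hz round trip of a 2 Hz component
stays within 10⁻³ of its amplitude, which linear interpolation cannot do.
Gap filling interpolates only gaps of at most 0.2 s that are bracketed by
valid samples (natural cubic spline); boundary gaps are never extrapolated.

## Events, cycles and temporal–spatial variables

A push starts when the filtered axle moment `M_z` rises above 1 Nm and ends
when it falls back below; pushes shorter than 0.1 s are discarded as
threshold chatter (both thresholds configurable). The axle component is
used because it is the propulsion moment. Consecutive pushes define
hand-on→hand-on cycles; the configured analysis window replaces the
protocol's manually chosen "most representative minute", and the first
`n_cycles` (default 5) consecutive cycles inside it are analyzed. Each
cycle is time-normalized to 101 stations (0–100%) by linear interpolation
with exact endpoints.

Within a cycle the five propulsion instants are: HO (hand on), TC (the
push sample whose grip angle is nearest top dead centre), HR (hand
release), FT (most anterior hand position) and AR (most posterior). FT/AR
use the third metacarpal, a mid-hand landmark; TC and the contact/release
angles use the wrist centre projected onto the rim circle, since that is
also where the rim load is applied. Angles on the rim are measured from the
backward horizontal, increasing with forward rotation (top centre = 90°).
This convention is explicit and configurable because published CA/RA
values are not reconstructible from a single stated convention; the package
therefore reports its own convention rather than imitating any particular
table. Cadence is cycles over elapsed time; distance per cycle is the wheel
radius times the wheel rotation per cycle.

## Hand-rim kinetics

With `F = (Fx, Fy, Fz)` and wheel angle θ from the sensor, the package
computes the total force `Ftot = |F|`, the tangential force
`Ftang = −Fx sinθ + Fy cosθ`, the effective force fraction `Feff` as the
push-phase mean of the per-sample ratio `Ftang/Ftot` (samples with
`Ftot < 1 N` excluded for numerical stability at the push edges), and the
elevation rates ERF/ERM as the maximum central-difference derivative of
`Ftot`/`Mtot` during the loading portion of the push (hand-on to in-push
peak) — a peak rate-of-rise, which is what makes the reported magnitudes
(hundreds to thousands of N/s) meaningful, not a mean slope. Per-cycle
values are averaged over the selected cycles; the push/recovery ratio is
reported as mean(Pphase)/mean(Rphase), with per-cycle ratios also kept.

A note on the tangential formula: with θ a monotone wheel-rotation angle
and a hand that re-grasps at a fixed lab angle every cycle, the formula
cannot be interpreted as a fixed change of basis — the encoder offset would
drift by the recovery rotation each cycle. The package therefore *defines*
its storage convention so the formulas are exact: `Fx`/`Fy` are stored such
that evaluating the tangential and radial expressions at the recorded θ
yields the physical tangential and radial components at the hand, and `Fz`
is axial. The lab-frame load is reconstructed by applying those components
at the hand's angular position on the rim (from the projected wrist
centre). The simulator writes its streams under the same convention, and
the rim moment satisfies `Mz = r_rim · Ftang` during the push.

## Joint kinematics

Segment frames follow ISB-style conventions (y longitudinal pointing
proximally, z lateral, x anterior), built directly from markers: trunk from
the acromia and c7; arm from the glenohumeral centre (midpoint of
`hha`/`hhp` — the only available landmarks; regression estimates of the
joint centre are out of scope) and the epicondyle axis; forearm from the
elbow centre (midpoint `epc`–`ipc`) to the wrist centre (midpoint
`ulr`–`rdl`); hand from the wrist centre, the styloid axis and the third
metacarpal. All frames are orthonormal right-handed by construction.

Joint angles decompose the distal-in-proximal rotation with the
conventional sequences: shoulder Y–X′–Y″ (plane of elevation, elevation,
axial rotation), elbow and wrist Z–X′–Y″ (flexion–extension,
deviation/carrying angle, axial rotation). The elbow's third rotation is
implemented as forearm pronation–supination. Angles are reported in
degrees, unwrapped over time; samples within 1° of a sequence singularity
(elevation near 0°/180°, middle Z–X′–Y″ angle near ±90°) are flagged and
linearly interpolated from their neighbours.

When dependent markers drop out, rigid cluster templates calibrated from a
static trial (epicondyles referenced to the arm cluster; 2nd/5th
metacarpals to the hand reference markers) are re-applied per frame with
the least-squares rigid transform (orthogonal Procrustes); frames with
fewer than three visible reference markers leave the dependents flagged.

## Joint kinetics

Segment inertial parameters default to standard mass fractions (arm 2.8%,
forearm 1.6%, hand 0.6% of body mass), COM fractions of 43–51% of segment
length, and inertia tensors of homogeneous frusta of revolution with the
anthropometric radii; the table is fully overridable because these values
are modelling choices, not measurements. Frustum inertia integrals are
evaluated numerically (Simpson, 2001 nodes), which reproduces cylinder
closed forms to 10⁻⁶ relative.

The Newton–Euler recursion runs hand → wrist → elbow → glenohumeral joint.
The external load on the hand is the reaction of the measured rim load,
applied at the wrist centre's projection onto the rim circle; any part of
the measured hub moment not explained by the contact force is carried as a
couple (the force distribution across the grasp is unobservable, so the
net load is all a hub-mounted sensor can deliver). Linear accelerations
are central differences of COM positions; angular velocity is the skew
part of `Ṙ Rᵀ`; angular acceleration differentiates that. Joint loads are
reported as the action of the proximal segment on the distal one, in lab
axes, whose components carry the usual anatomical reading for a
forward-facing subject (Fx +anterior, Fy +lateral, Fz +superior; Mx
+adduction/−abduction and +cubital/−radial at the wrist, My +flexion, Mz
+pronation and +internal rotation at shoulder and wrist). Only the
glenohumeral joint is modelled at the shoulder; scapulothoracic and
clavicular mechanics are out of scope.

## Group statistics

Variables are compared between two groups with a two-sided Wilcoxon
rank-sum test: exact enumeration of all group assignments for combined
samples of at most 12 without ties, a seeded 10⁴-draw permutation test with
ties at that size, and the tie- and continuity-corrected normal
approximation otherwise. No multiplicity adjustment is applied by default,
matching per-variable reporting at α = 0.05 (Holm is available). Summaries
are median ± IQR (type-7 quantiles) or mean ± SD (n−1). At n = 6 vs 6 the
corrected normal approximation agrees with exact enumeration to within
0.02 over all achievable statistics (the worst case sits in the extreme
tail); claims tighter than that are not attainable for every draw.

## The simulator and what passing tests mean

`simulate_propulsion()` is a forward model, not a fixture file: the wrist
centre rides the rim arc during the push (locked to the wheel, so the push
arc equals the wheel rotation) and returns along a C¹ Hermite path dipping
below the rim — the semicircular pattern the protocol imposes. Arm posture
comes from two-link planar inverse kinematics under a fixed shoulder with
the elbow-back branch, which keeps shoulder elevation away from the Y–X′–Y″
singularity throughout the cycle; a prescribed smooth wrist flexion
oscillation (±10°) exercises the wrist sequence. All 15 markers are placed
rigidly on their segments so that the frame constructions above recover the
generating frames exactly. Rim kinetics are a half-sine total-force profile
(default peak 47 N) split into tangential/radial/axial shares (defaults
0.75/√(1−0.75²−0.1²)/0.1), written under the package's storage convention;
defaults reproduce the study conditions (0.833 m/s, 600 mm wheel, cadence
1.25 strokes/s, push arc 1 rad, 1 mm marker and 0.5 N force noise, seeded).
Ground truth — frames, joint angles, external load, event times — is
recorded before noise.

`forward_loads()` is the independent inverse-dynamics oracle: a separate
Newton–Euler implementation that exploits the trial's planarity (rotations
about the lab y axis, closed-form angular terms) and uses its own finite
differences; it shares no code with the analysis modules and refuses
non-planar input.

The simulator emulates kinematic consistency, load consistency and the
push/recovery structure. It does **not** emulate soft-tissue artefact,
marker occlusion patterns, grip-force distribution, trunk motion,
left/right asymmetry, or wheel-speed fluctuation within a cycle. Passing
the recovery tests therefore demonstrates that the pipeline's mathematics
is right (events within a sample, angles to fractions of a degree, joint
loads to the oracle within 2%/5% noise-free), not that real recordings of
patients would be recovered with those accuracies.

## Numerical choices and problem sizes

Detection uses strict threshold crossings with a one-sample memory, so a
series that starts above threshold contributes no push until it falls
below. Ties in FT/AR/TC break to the earliest index. Euler round trips are
exact to 10⁻⁹ degrees away from singularities. The test suite runs trials
of 6–8 s (7–10 cycles) at 240 Hz, 10⁴ Euler triples, 50 random static
poses, 100-signal detection sweeps and 1000-frame reconstruction
Monte-Carlo; the acceptance script uses the same sizes plus a 10-subject
simulated cohort. These sizes were chosen so every oracle comparison is
well-resolved while the whole suite stays interactive.

## Known limitations

- One side is analyzed at a time; bilateral asymmetry requires two runs.
- The glenohumeral centre from the humeral-head midpoint is a landmark
  approximation; no joint-centre regression is provided.
- The hand is a single rigid segment; finger/grip mechanics are absorbed
  into the net rim load.
- C3D input is not implemented; the CSV dialect is the interchange format.
- Reported CA/RA depend on the declared angle convention and are not
  comparable across conventions.
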