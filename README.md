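# rimdyn

Upper-limb biomechanics of hand-rim wheelchair propulsion.

Manual wheelchair users load their shoulders, elbows and wrists with every
push, and the repetitive nature of propulsion makes those loads clinically
important — particularly for people with spinal cord injury, where pain or
overuse injury in the upper limb directly limits independence. `rimdyn`
implements the full measurement-to-statistics chain used in propulsion
studies: it takes synchronized motion-capture marker trajectories (a reduced
15-marker upper-limb model, nominally 50 Hz) and instrumented-wheel
recordings of hand-rim force, moment and wheel angle (nominally 240 Hz), and
produces

- **temporal–spatial variables**: cadence *PF*, push/recovery phase durations
  and their ratio, distance per cycle, contact and release angles;
- **hand-rim kinetics**: total force `Ftot = √(Fx²+Fy²+Fz²)`, tangential
  force `Ftang = −Fx sinθ + Fy cosθ`, effective force fraction
  `Feff = Ftang/Ftot` (push-phase mean), and the peak rates of rise ERF and
  ERM of total force and moment;
- **joint kinematics**: ISB-style segment frames and Euler joint angles
  (shoulder Y–X′–Y″: plane of elevation, elevation, axial rotation; elbow and
  wrist Z–X′–Y″: flexion, deviation, pronation–supination), time-normalized
  over hand-on→hand-on cycles with max/min/ROM and push/recovery phase tags;
- **joint kinetics**: Newton–Euler inverse dynamics from the measured rim
  load through hand, forearm and arm to the glenohumeral joint, with the
  sign conventions Fx +anterior, Fy +lateral, Fz +superior, Mx
  +adduction (+cubital at the wrist), My +flexion, Mz +pronation
  (+internal rotation at shoulder and wrist);
- **group comparisons**: two-sided Wilcoxon rank-sum tests (exact
  enumeration for small untied samples, seeded permutation with ties,
  corrected normal approximation otherwise) with median±IQR or mean±SD
  summaries.

Push phases are detected where the filtered axle moment crosses 1 Nm; all
kinetic channels go through a 4th-order zero-phase Butterworth low-pass at
20 Hz. A forward-model simulator (`simulate_propulsion()`) generates
semicircular propulsion trials with consistent markers, rim kinetics and
ground-truth joint loads, so every stage of the pipeline is testable without
patient data; `forward_loads()` is an independent Newton–Euler oracle for the
inverse dynamics.

## Worked example

Simulate a trial under the study conditions (treadmill at 0.833 m/s, 600 mm
wheel, cadence 1.25 strokes/s, 47 N peak rim force, 1 mm marker and 0.5 N
force noise) and run the full analysis:

```r
library(rimdyn)

p  <- sim_params(seed = 42L)
tr <- simulate_propulsion(p, duration = 8)
an <- analyze_trial(tr$markers, tr$rim, study_config(),
                    p$anthro, tr$geometry)
an$temporal_spatial
#> temporal_spatial (5 cycles):
#>   PF    1.250 st/s
#>   Dist  0.666 m
#>   Pphase 0.334 s  Rphase 0.466 s  ratio 0.717
#>   CA 63.6 deg  RA 117.3 deg
an$handrim
#> handrim_summary:
#>   Ftot_max    47.04 N    Ftang_max   35.24 N   Feff 0.750
#>   ERF         431.9 N/s  Mtot_max     9.29 Nm  ERM     83.2 Nm/s
an$joint_kinetics
#> wrist     |F| peak   45.38 N   |M| peak   1.059 Nm
#> elbow     |F| peak   41.20 N   |M| peak   5.335 Nm
#> shoulder  |F| peak   51.22 N   |M| peak  12.351 Nm
```

Reading the output: the five selected cycles recover the commanded cadence
(1.25 strokes/s) and speed (Dist × PF = 0.833 m/s); the hand grips the rim
at 63.6° from the backward horizontal and releases at 117.3° (top centre =
90°); the peak total rim force matches the simulated 47 N and `Feff` equals
the simulated tangential share 0.75; the shoulder carries the largest loads,
as expected for propulsion. `report_json()` serializes the full result
(including per-joint angle ROM tables and force/moment values at the five
propulsion instants HO/TC/HR/FT/AR).

Group comparison on a simulated two-group cohort (low-force/high-efficiency
vs high-force/low-efficiency propulsion):

```r
kit <- simulate_two_groups(n_per_group = 5, seed = 42L, duration = 4)
compare_groups(kit, c("Ftot_max", "Feff", "ERF"))
#>   variable   loc_a spread_a  loc_b spread_b  U       p significant
#> 1 Ftot_max  46.751 9.76e+00  90.32 3.67e+01  0 0.00794        TRUE
#> 2     Feff   0.759 2.22e-04   0.49 3.70e-04 25 0.00794        TRUE
#> 3      ERF 555.626 1.10e+02 931.21 3.77e+02  2 0.03175        TRUE
```

With 5 subjects per group the smallest achievable exact p is 2/252 ≈ 0.0079
— the value the fully separated variables reach.

A command-line wrapper lives in `inst/cli/rimdyn.R`
(`analyze` / `simulate` / `compare` subcommands).

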