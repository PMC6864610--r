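Package: rimdyn
Title: Hand-Rim Wheelchair Propulsion Biomechanics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for hand-rim wheelchair propulsion: reading and
    synchronizing 3D marker trajectories with instrumented-wheel force, moment
    and wheel-angle streams; zero-phase Butterworth filtering; push-phase event
    detection and propulsion-cycle segmentation with time normalization;
    temporal-spatial and hand-rim kinetic variables (total, tangential and
    effective force, elevation rates); rigid marker-cluster calibration and
    reconstruction; ISB-style segment frames, Euler joint kinematics and
    Newton-Euler inverse dynamics of the upper limb from hand to glenohumeral
    joint; Wilcoxon rank-sum group comparisons; and a forward-model simulator
    of semicircular propulsion that provides ground-truth joint loads for
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    signal,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
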