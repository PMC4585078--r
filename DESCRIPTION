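Package: fourlink
Title: Four-Link Inverse and Forward Dynamics of Hind-Leg Swing Over a
    Remembered Barrier
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Planar four-link rigid-rod model of a cat hind leg (thigh,
    shank, paw, toes) for analysing memory-guided stepping over a lowered
    barrier.  Provides inverse dynamics (joint torques and interaction
    forces from motion-capture kinematics via a 20-equation Newton-Euler
    system), forward dynamics (fixed-step fourth-order Runge-Kutta
    simulation of swing driven by joint-torque profiles), motion-capture
    processing (knee triangulation, zero-phase Butterworth filtering,
    interpolation to 1 ms, finite-difference derivatives), EMG burst
    quantification, a synthetic-trial generator with known ground truth,
    and the fixed-command experiments that separate mechanical from
    neuronal contributions to toe-trajectory slope.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    signal,
    jsonlite,
    yaml,
    stats,
    graphics,
    grDevices,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
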