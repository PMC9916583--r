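Package: exogait
Title: Virtual Simulator of Exoskeletal-Assisted and Unassisted Locomotion
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Subject-specific multibody simulation and measurement processing
    for gait analysis with and without a lower-extremity powered exoskeleton.
    Builds a 24-segment, 37 degree-of-freedom human model and a 7-segment,
    4 degree-of-freedom exoskeleton model, couples them at the pelvic band,
    scales them to subject anthropometry, and lumps device inertia into the
    human segments. Provides marker-based inverse kinematics (damped
    Gauss-Newton), recursive Newton-Euler inverse dynamics with external
    ground loads, a forward-dynamics oracle for verification, Butterworth
    conditioning chains for ground reaction forces and electromyography with
    maximum-voluntary-contraction normalization, gait event detection, cycle
    time-normalization and ensemble statistics, readers and writers for TRC
    and MOT/STO motion-capture formats, and a synthetic-trial generator with
    known ground truth so the full pipeline is testable end to end.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    signal,
    deSolve,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
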