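Package: phenogait
Title: Deep Neurobehavioral Phenotyping of Locomotor States
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolchain for joint analysis of synchronized kinematic
    trajectories and neural field-potential recordings during locomotion.
    Converts 3D marker data and multichannel ECoG/LFP signals into
    sliding-window feature time series (speed, joint angles, Hjorth
    parameters, band amplitudes, burst metrics), classifies locomotor
    states (gait, stationary movement, akinesia; or gait vs. freezing of
    gait) with linear discriminant and supervised contrastive-embedding
    models, ranks the features that separate states by permutation
    importance, and characterizes feature modulation around akinesia
    onset. Includes a seeded synthetic-cohort generator so every stage is
    testable end to end without experimental data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    zoo,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    MASS
Config/testthat/edition: 3
RoxygenNote: 7.3.3
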