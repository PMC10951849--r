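Package: thetareg
Title: Theta-Band EEG Analysis of Emotion Regulation by Cognitive Reappraisal
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis workflow for sensor- and source-level
    theta-band (3.5-8.5 Hz) EEG correlates of emotion regulation in a
    two-group cognitive-reappraisal paradigm. Provides a spherical-head
    forward model and cohort simulator with planted induced-theta effects,
    BrainVision I/O and preprocessing (filtering, channel interpolation,
    artifact rejection, average reference, ICA-based ocular cleanup),
    induced time-frequency analysis with a sliding Hanning window,
    sensor-level cluster-mass permutation statistics, the eLORETA
    distributed inverse solution with baseline-ratio source power and
    voxel-wise permutation inference, volume-conduction-robust connectivity
    via the multivariate interaction measure (MIM), and the behavioural
    mixed ANOVA and regression models, orchestrated as a reproducible
    pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    igraph,
    MASS,
    withr
Config/testthat/edition: 3
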