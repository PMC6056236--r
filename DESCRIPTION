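Package: vestcoh
Title: Time-Frequency Coherence Analysis of Vestibular Stimulation and
    Ground Reaction Forces
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates stochastic electrical vestibular stimulation (EVS)
    together with forceplate recordings of quiet standing, locomotor
    initiation/termination and lateral weight-shift trials, detects gait
    events and movement-phase boundaries from the ground reaction forces,
    computes trial-averaged Morlet time-frequency coherence between the
    stimulus and the shear forces with analytic significance limits, and
    summarises coherence null periods around motor-state transitions and
    per-phase coherence peaks, including the associated multivariate
    phase-comparison statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    signal,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
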