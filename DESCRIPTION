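Package: fogsim
Title: Cortico-Basal-Ganglia Simulation of Freezing of Gait in Parkinson's Disease
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: An actor-critic reinforcement-learning simulator of gait in a
    virtual corridor with doorways and Stroop word cues. Two cortico-basal-
    ganglia loops (a cognitive cue network and a motor navigation network)
    each learn risk-sensitive Utility functions (Utility = Value minus a
    sign-weighted Risk term); a Go/Explore/NoGo actor climbs the motor
    Utility landscape and a drift-to-threshold accumulator converts the two
    evidences into footstep latencies. Dopamine-clamp and medication
    parameters reproduce group-level gait phenomena of healthy controls and
    Parkinsonian freezers and non-freezers: conflict-driven footstep latency,
    doorway effects, cognitive-load-driven motor arrests, and medication
    effects, with repeated-measures statistics over simulated subjects.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
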