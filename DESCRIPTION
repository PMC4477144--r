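Package: protodist
Title: Prototype-Distortion Category Learning Simulations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying heterogeneous perceptual category learning
    with prototype-distortion dot-pattern stimuli. Generates nine-dot
    polygon stimuli at graded distortion levels, encodes them as 12x12
    occupancy matrices, builds A/not-A training regimens and the fixed
    60-item generalization test, trains 144-144-144 feedforward
    auto-associator networks under typical and atypical plasticity
    settings (reduced learning rate, negative weight decay, truncated
    training), classifies endorsement profiles into performance types,
    and simulates synthetic behavioral cohorts with per-task profile
    switching for closed-loop validation of the analysis pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    mgcv,
    withr,
    jsonlite,
    yaml,
    rlang,
    ggplot2
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
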