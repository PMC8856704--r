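Package: gonogo
Title: Go/No-Go Operant Task Simulation and Peri-Cue Calcium Trace Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A pure-software re-implementation of a miniscope-compatible
    Go/No-Go operant conditioning setup for mice. Provides a deterministic
    event-driven finite-state machine for the task and its training stages
    (stage 0 pretraining through the full stage 4 Go/No-Go contingency), a
    stochastic virtual-mouse agent that plays the task and generates cohorts
    of behavioral event logs with control and socially defeated groups,
    behavioral analytics (trial parsing, hit/commission/premature rates,
    correct response rate, social-interaction-test phenotyping, mixed-design
    repeated-measures ANOVA), and a calcium-imaging pipeline for extracted
    fluorescence traces: sliding-window photobleaching correction, z-scored
    dF/F, peri-cue alignment, population median/MAD time courses, rank-sum
    screening of cue-modulated neurons, and peak-latency-sorted heat-map
    matrices. A synthetic GCaMP-like transient generator with known ground
    truth makes every analysis step testable end to end.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    tools,
    graphics,
    grDevices,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
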