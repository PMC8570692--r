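Package: gonogo
Title: Simulation and Analysis of Go/No-Go Odor Discrimination Behavior
    and Single-Unit Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to simulate and analyze head-fixed go/no-go odor
    discrimination experiments with appetitive and aversive outcomes and
    simultaneous extracellular single-unit recordings. Includes a
    synthetic-data generator (task schedules with truncated-exponential
    inter-trial intervals, cue-locked anticipatory licking, inhomogeneous
    Poisson spike trains, optogenetic identification protocols, spike-sorting
    cluster features), anticipatory lick-rate and learning/extinction curve
    analysis with logistic learning-rate fits, spike-sorting quality control
    (L-ratio, interspike-interval violations, minimum firing rate),
    event-aligned rasters and peri-stimulus time histograms, 100-ms-binned
    auROC discriminability with neuron classification, antidromic optotag
    identification with collision tests, and Poisson regression of cue-evoked
    spike counts on odor-mixture proportion and aversive-history group.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    MASS,
    minpack.lm,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    optparse
Config/testthat/edition: 3
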