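Package: soclas
Title: Closed-Loop Auditory Stimulation Phase-Response Analysis for Slow-Wave Sleep EEG
Version: 0.1.0
Authors@R:
    person("soclas", "developers", email = "soclas@dev.null", role = c("aut", "cre"))
Description: Simulation and analysis toolkit for closed-loop auditory
    stimulation (CLAS) of sleep slow oscillations. Generates ground-truth
    labelled synthetic slow-wave sleep EEG with slow oscillations, sleep
    spindles and a configurable phase-dependent click response; simulates
    online trough-detection stimulation protocols with adaptive thresholds;
    detects slow oscillations and sleep spindles offline; estimates the
    slow-oscillation phase at each click with an FIR Hilbert transformer;
    pools post-stimulus measures into overlapping time and phase bins; and
    provides the bespoke statistics needed to recover the optimal
    stimulation phase (Monte Carlo bin comparisons, pairwise response
    index, circular-covariate binomial logistic regression with acrophase).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
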