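Package: avoidrl
Title: Actor-Critic Simulation of Signaled Lever-Press Avoidance
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates acquisition and extinction of signaled lever-press
    avoidance with a linear actor-critic temporal-difference learner: softmax
    action selection with an explore/exploit temperature, a decaying
    perseveration (choice-kernel) trace, a linear critic trained by prediction
    error, and a trial/session/inter-session event scheduler. Ships parameter
    presets for outbred Sprague-Dawley (SD) and behaviorally inhibited Wistar
    Kyoto (WKY) rats, an experiment battery (shock intensity, warning-signal
    duration, inter-session interval, round-the-clock housing, parameter
    sweeps), behavioral metrics (percent avoidance, response latency,
    trial-by-trial session-block curves, warm-up difference scores), and a
    command-line interface producing tidy CSV trial records and JSON
    summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    optparse,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
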