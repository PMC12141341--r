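Package: replaynet
Title: Voltage-Clamp Replay Experiments in a Small Hodgkin-Huxley Network
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates a five-neuron recurrent visual-cortex model built from
    single-compartment Hodgkin-Huxley neurons, conductance synapses with
    short-term depression, and two lateral geniculate nucleus (LGN) input
    nodes that encode stimulus hue as Poisson spike trains.  Membrane-voltage
    recordings from a reference run can be replayed into the same network
    either by feedforward voltage overwrite or by a feedback voltage clamp
    that injects corrective current only where ongoing activity deviates from
    the command voltage.  Includes a scenario battery contrasting congruent
    and incongruent stimuli during replay, clamp-current summaries that
    distinguish the two ways a clamp can "do nothing", and a discrete
    Turing-machine analogue of the replay with reachable-state analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    rlang,
    stats,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
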