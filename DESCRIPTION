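Package: crowdconsensus
Title: Hybrid Force- and Agent-Based Simulation of Consensus Decision
    Making in Human Crowds
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.com")
Description: Simulates small and large groups of pedestrians walking in a
    circular arena in which a minority of informed individuals steers an
    uninformed majority to a target on the arena periphery.  Individual
    motion is driven by force-like behaviour effects (seek-to, wandering,
    keep-in-group cohesion/alignment, crowd repulsion) derived from a
    single core kernel, selected per agent and per frame by an
    agent-level decision rule, and integrated with a fixed 1/60 s time
    step.  Includes batch experiment runners for informed-position
    treatments, walking-speed sweeps and informed-percentage grids, and
    arrival-time/accuracy metrics including the speed-accuracy trade-off
    and emergent-leadership diagnostics.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats
LinkingTo: Rcpp
Suggests:
    ggplot2,
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
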