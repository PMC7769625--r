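Package: cscburst
Title: Bursting Dynamics of Cerebellar Stellate Cells
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and dynamical analysis of an expanded Hodgkin-Huxley
    model of cerebellar stellate cells that includes high-voltage-activated
    calcium and calcium-activated potassium currents together with cytosolic
    calcium dynamics. Provides stiff integration of the full and fast
    (frozen-slow-variable) subsystems under current-step, hold-and-release and
    synaptic protocols; spike and burst feature extraction with interspike
    interval return maps and regime classification (tonic, square-wave,
    pseudo-plateau, chaotic bursting, depolarization block); pseudo-arclength
    continuation of equilibria with saddle-node, Hopf and SNIC
    characterization; shooting-based continuation of periodic orbits with
    Floquet multiplier event detection; two-parameter regime sweeps with
    bistability probing; slow-fast dissection of bursting via the critical
    manifold over the slow variables; and synthetic surrogate voltage traces
    with known ground truth for validating the feature-extraction stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
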