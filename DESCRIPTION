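Package: selfheal
Title: Agent-Based Self-Healing Dynamics on Elastic Tissue Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying tissue self-healing as a two-variable
    dynamical system coupling fibroblast activity to extracellular-matrix
    stiffness, together with its agent-based realization on a pre-stressed
    hexagonal elastic spring network. Provides fixed-point and stability
    analysis, adaptive time-domain integration, network construction and
    strain-energy equilibration, biaxial network-stiffness readouts,
    stiffness-biased (durotactic) random-walk agents, injury-resolution and
    halo-dynamics experiments, fibrosis under sustained non-equilibrium
    forcing, and a slowed-healing aging parameterization.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
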