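Package: drlandscape
Title: Dimension Reduction of Energy Landscapes for Multistable Gene
    Regulatory Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Quantifies the Waddington-style energy landscape U = -ln Pss of
    stochastic Hill-kinetics gene regulatory network models. The steady-state
    probability density of a multistable Langevin system is approximated by a
    weighted Gaussian mixture via truncated moment equations (one component per
    stable fixed point, covariance from the algebraic Lyapunov equation), then
    projected onto the maximal-variance coordinates of the mixture covariance
    to obtain a low-dimensional landscape. Includes barrier-height
    quantification via union-find saddle flooding, Langevin-simulation
    reference landscapes, Freidlin-Wentzell minimum action paths and transition
    actions between attractors, parameter-perturbation robustness analysis
    with hierarchical clustering of stable states, and link-strength
    sensitivity of transition actions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    deSolve,
    jsonlite,
    MASS,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
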