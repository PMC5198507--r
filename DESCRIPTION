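Package: viraldelay
Title: Delayed Within-Host Viral Dynamics with CTL and Antibody Immune
    Responses
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Tools for a five-compartment within-host viral infection
    model (uninfected cells, infected cells, free virus, CTLs,
    antibodies) with three discrete delays, a general target-cell growth
    law, a general nonlinear incidence function and state-dependent
    removal rates.  Computes the five reproduction numbers gating
    infection, antibody establishment, CTL establishment and immune
    competition; solves the infection-free, immune-free, antibody-only,
    CTL-only and coexistence equilibria; classifies the global-stability
    regime; locates characteristic roots of the transcendental
    linearisations; integrates the delay system by the method of steps
    with dense output; evaluates Lyapunov functionals along trajectories;
    and scans the immune-response delay for Hopf bifurcations and
    stability switches.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    grDevices,
    jsonlite,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    deSolve,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
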