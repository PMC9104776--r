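Package: ibicg
Title: Iterative Boltzmann Inversion for Structure-Based Coarse-Graining
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Derives coarse-grained (CG) pair force fields from target
    structural distributions by Iterative Boltzmann Inversion (IBI).
    Maps all-atom configurations to center-of-mass beads, measures radial,
    bond-length and angle distributions under periodic boundaries, inverts
    them into potential-of-mean-force tables, and refines the non-bonded
    table by running its own tabulated-potential NVT molecular dynamics
    (leapfrog integrator, canonical velocity-rescaling thermostat) until
    the CG radial distribution function matches the target under a
    weighted least-squares convergence functional. Includes generators for
    toy carbon-nanotube and capped-amino-acid systems and self-consistent
    closure fixtures, plus readers and writers for GRO structures and
    GROMACS-style tabulated potentials.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    graphics,
    grDevices,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
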