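Package: npckin
Title: Templated-Assembly Kinetics and Small-Angle Scattering Observables
    for Viral Capsid Self-Assembly
Version: 0.1.0
Authors@R:
    person("npckin", "maintainers", email = "npckin@example.org",
           role = c("aut", "cre"))
Description: Quantitative analysis of time-resolved small-angle X-ray and
    neutron scattering (TR-SAXS/SANS) experiments on viral capsid subunits
    assembling on a genome or polyelectrolyte template.  Implements the
    templated assembly kinetic model (a reversible one-subunit-at-a-time
    binding ladder with uniform rate constants) with deterministic and
    stochastic propagators and its equilibrium solution; the mapping from
    complex distributions to forward scattering intensity and the
    distribution-free upper bound on the mean number of bound subunits per
    genome; Guinier extraction of forward intensity and radius of gyration
    from 1-D scattering curves; estimators for relaxation times, critical
    concentration, binding free energy, diffusion-limited rate constants
    and Arrhenius activation energies; and a synthetic-data generator that
    emulates TR-SAXS frame series with photon-counting noise so the whole
    pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
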