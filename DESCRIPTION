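Package: pdmslab
Title: Desk-Scale Molecular Simulation of Organic Partitioning at
    PDMS-Water Interfaces
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for studying the partitioning of small organic
    compounds between water and a polydimethylsiloxane (PDMS) slab at
    the molecular level. Provides a united-atom PDMS / SPC water /
    OPLS-style organics force field, builders for oligomer mixtures and
    two-phase slab systems with repulsive walls, a compact velocity-Verlet
    molecular dynamics engine (Nose-Hoover thermostat, SHAKE-constrained
    rigid water, simulated-annealing protocol), and a trajectory-analysis
    chain that turns trajectories into density profiles, phase
    occupancies, PDMS/water partition coefficients (log P), molar
    solubilities, and Einstein-relation diffusion coefficients with
    block-averaged uncertainties. Synthetic-trajectory generators and a
    Widom-insertion chemical-potential oracle make every analysis stage
    testable without large-scale dynamics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
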