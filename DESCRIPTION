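Package: pepDMD
Title: Event-Driven Coarse-Grained Molecular Dynamics of Peptides with
    Replica Exchange and WHAM Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Discrete (event-driven) molecular dynamics of coarse-grained
    peptides interacting through step-function potentials, with exact
    collision dynamics, reaction-style backbone hydrogen bonding, an
    Andersen thermostat, temperature replica exchange with ladder tuning,
    weighted-histogram (WHAM) thermodynamics including specific-heat
    transition detection, and structural analysis of trajectories:
    residue contact-frequency maps, Kabsch RMSD, hierarchical
    conformational clustering with centroid extraction, and bead-level
    secondary-structure assignment.  Ships amylin (human and rat IAPP)
    and insulin sequence fixtures plus toy systems with analytic
    thermodynamic references for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    Biostrings,
    bio3d,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
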