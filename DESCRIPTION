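Package: loxdyn
Title: Trajectory Analysis of Membrane-Gated Lipoxygenase Complexes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Analysis toolkit for molecular-dynamics trajectories of
    peripheral membrane-protein complexes, built around the human
    15-lipoxygenase-1 (15LOX-1) / PEBP1 system. Provides a domain-opening
    order parameter based on centers of mass, RMSD-based model stability
    triage, protein-protein interface contact and hydrogen-bond
    reorganization statistics, catalytic-iron-to-substrate-carbon distance
    distributions with a regioselectivity proxy, grid-based detection of
    the substrate-access tunnel from the catalytic site to the protein
    surface, and a coarse residue-charge screened-Coulomb model for
    interface electrostatics with in-silico point mutations. A
    deterministic synthetic-structure and two-state trajectory generator
    makes every stage testable without molecular-dynamics input.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    bio3d,
    jsonlite,
    yaml,
    stats,
    tools,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
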