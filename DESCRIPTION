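Package: viasm
Title: Viability-Evolution Integrative Modeling of Symmetric Protein Assemblies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts the architecture of cyclic-symmetric (Cn) macromolecular
    assemblies from subunit structures and heterogeneous experimental restraints
    (inter-subunit residue distances, cryo-EM density maps, fractional
    disulfide-crosslinking profiles). The search engine is a memetic Viability
    Evolution optimizer: a population of (1+1)-CMA-ES local search units under
    per-constraint viability boundaries that tighten over time, recombined by
    Differential Evolution. Each restraint and a coarse 9-6 Lennard-Jones
    inter-subunit potential act as independent viability constraints rather
    than terms of a weighted fitness function. Includes Gaussian-kernel density
    map simulation and cross-correlation ranking (MRC/CCP4 and SITUS ASCII
    I/O), rigid-body map fitting with optional Laplacian filtering,
    complete-linkage clustering of viable models, positive-predictive-value
    auditing of restraint sets, a crosslink-correlation assembly mode for
    homodimers, and a synthetic-fixture generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    bio3d,
    Rcpp,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
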