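Package: tcomfa
Title: Template-Guided Comparative Molecular Field Analysis (3D-QSAR)
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Template-guided CoMFA (comparative molecular field analysis) for
    3D-QSAR modelling of bioactivity data. Candidate structures described only
    by 2D connectivity are aligned automatically to pre-aligned 3D templates by
    anchor-bond atom-chain matching with coordinate transfer and deterministic
    topomer-style completion of unmatched atoms. Steric (Lennard-Jones) and
    electrostatic (Coulomb) interaction fields are sampled on a Cartesian
    lattice and related to affinity by NIPALS partial least squares with
    leave-one-out cross-validation and progressive Y-scrambling. Includes
    ChEMBL-style bioactivity curation (discordant-assay filtering, odd/even
    splitting), a Tanimoto fingerprint nearest-neighbour baseline,
    active/inactive classification with prediction combination, template
    perturbation protocols, and a seeded synthetic-data generator with planted
    field-linear activities.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    igraph,
    jsonlite,
    ChemmineR
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    ChemmineOB,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
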