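Package: sumd
Title: Supervised Molecular Dynamics Sampling and Trajectory Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Engine-agnostic implementation of the supervised molecular
    dynamics (SuMD) control algorithm for sampling ligand-binding pathways,
    together with the trajectory-analysis stack used to characterise them:
    Kabsch superposition and RMSD series, pairwise-RMSD matrices with
    density-based (DBSCAN) clustering of ligand positions, grid-based
    pocket-volume tracking with a spherical inclusion region, residue
    contact frequencies, and toy nonbonded interaction energies. A built-in
    coarse-grained receptor-ligand system with a funnel-shaped orthosteric
    pocket and a metastable vestibular site, integrated by an NVT Langevin
    (BAOAB) engine, allows the whole pipeline to run end-to-end on one CPU.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    bio3d,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
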