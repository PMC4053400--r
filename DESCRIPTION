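Package: mdsie
Title: Post-Simulation Analysis of Protein-Ligand Binding with Solvated
    Interaction Energy
Version: 0.1.0
Authors@R:
    person("Maintainer", "Dev", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Desk-scale analysis of molecular dynamics trajectories of
    protein-ligand complexes. Reads PDB structures, multi-model PDB
    trajectories and per-atom parameter tables; computes Kabsch
    superposition, RMSD/RMSF and dynamic cross-correlation matrices;
    evaluates solvated interaction energy (SIE) endpoint binding free
    energies from intermolecular Coulomb and Lennard-Jones terms, a
    finite-difference Poisson reaction field and a Shrake-Rupley surface
    area term; scores hydrogen bonds with an empirical distance well and
    per-residue polar interactions with a sigmoidal distance-dependent
    dielectric; performs computational alanine scanning by C-gamma
    truncation; and ships a synthetic-data generator so every stage is
    testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
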