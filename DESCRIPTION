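Package: pepsurf
Title: Peptide-Gold Interface Trajectory Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Post-simulation analysis of peptides adsorbed at the aqueous
    Au(111) interface. Computes per-residue surface-contact fractions from
    molecular-dynamics trajectories, combines them with amino-acid
    adsorption free energies into residue binding scores, cumulative
    sequence-range scores and a position-9 helix-propensity
    classification, performs Daura-style greedy RMSD clustering of
    conformational ensembles with cross-variant cluster matching, and
    estimates umbrella-sampling potentials of mean force by the weighted
    histogram analysis method (WHAM) with trajectory-bootstrap errors.
    Ships a synthetic-data module that generates adsorbed-peptide
    trajectories with prescribed contact statistics, planted-cluster
    conformational ensembles, and exact Boltzmann umbrella-window samples
    from known free-energy profiles, so every stage is testable without a
    molecular-dynamics run.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
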