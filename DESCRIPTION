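Package: pspredict
Title: Structure-Based Prediction of Phase-Separating Proteins
Version: 0.1.0
Authors@R: person("Maintainer", "pspredict", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Predicts the phase-separation propensity of proteins from
    AlphaFold-style structure models. From a single-chain PDB file with
    per-residue pLDDT stored in the B-factor column, the package calls
    intrinsically disordered regions (IDRs), assigns secondary structure
    with an internal Kabsch-Sander implementation, computes per-residue
    solvent accessibility (Shrake-Rupley) and relative solvent
    accessibility, derives structured superficial regions (SSUP), detects
    charged sticker clusters on the protein surface by net-charge-index
    screening and centroid-linkage clustering, assembles a residue- and
    structure-level feature vector, and scores proteins with an ensemble
    of gradient-boosted decision trees trained with inverse-frequency
    class weights on repeated negative subsamples. ROC/PRC evaluation
    utilities and a synthetic-structure fixture generator are included.
License: MIT
Encoding: UTF-8
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
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
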