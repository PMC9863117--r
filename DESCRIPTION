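Package: peptraj
Title: Structure-Formation Analysis of Restricted-Alphabet Peptide Trajectories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify the structure-forming ability of short random
    peptides built from restricted amino-acid alphabets (such as the primitive
    [GADV] set and its five-letter extensions). Provides composition-weighted
    random sequence generation, an internal-coordinate peptide builder,
    multi-model PDB trajectory input/output, a Kabsch-Sander secondary-structure
    assigner with helix-occupancy classification, RMSF-based rigidity analysis
    about an iterated average structure, geometric hydrogen-bond counting,
    Shrake-Rupley solvent-accessible and polar surface areas, per-set summary
    statistics, and a seeded synthetic-trajectory generator with exact ground
    truth for validating every stage without molecular dynamics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    bio3d,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    ggplot2
Config/testthat/edition: 3
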