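Package: krabstrat
Title: Stratification of Ancestral and Modern KRAB Domains with Profile HMMs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to stratify Krueppel-associated box (KRAB) protein domains
    into ancestral (aKRAB) and modern (mKRAB) classes. Builds profile hidden
    Markov models from multiple alignments, scores sequences with forward and
    Viterbi recursions, calibrates E-values against a Gumbel null, and applies
    the curation pipeline used for KRAB catalogs: iterative E-value filtering,
    within-species deduplication, clamped -log10 score matrices, subgroup
    assignment, and rank-based group comparisons. Also provides sequence-logo
    information-content matrices, positional residue frequency tables, an
    edit-script engine for aKRAB-to-mKRAB mutagenesis roadmaps, and
    alpha-helix geometry (axis fitting, inter-helix angles, Kabsch
    superposition, azimuthal side-chain register rotation) on PDB models.
    A synthetic-data generator emulates subgroup-specific KRAB sequence
    catalogs and ideal helix coordinates so the whole pipeline runs without
    external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    stringr,
    readr,
    generics,
    ggplot2,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    Biostrings,
    bio3d,
    withr
Config/testthat/edition: 3
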