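Package: hdclms
Title: Hierarchical Target-Decoy FDR and Structural Validation for
    High-Density Cross-Linking Mass Spectrometry
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Downstream analysis of high-density cross-linking/mass
    spectrometry (HD-CLMS) identifications. Implements hierarchical
    target-decoy false discovery rate estimation for cross-linked residue
    pairs (PSM -> unique peptide pair -> unique residue pair, with
    root-sum-of-squares score aggregation and automatic pre-filter
    optimization), validation of accepted residue pairs against crystal
    structures via Calpha-Calpha distances and a configurable linkability
    bound, run-order permutation saturation analysis, in-silico protease
    digestion and theoretical-observability analysis of cross-link
    coverage, and secondary-structure / relative-solvent-accessibility
    bias analysis. A fully seeded synthetic-data generator produces toy
    folds, ground-truth cross-links and scored target/decoy PSM tables so
    that every stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    bio3d,
    jsonlite,
    seqinr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
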