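Package: msh2triage
Title: Feature-Based Triage of MSH2 Missense Variants of Uncertain
    Significance
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for classifying missense variants of uncertain
    significance (VUS) in the DNA mismatch-repair gene MSH2. The package
    curates pathogenic/benign/VUS variant sets from ClinVar-style and
    population-database-style tables, computes per-variant sequence,
    structure and dynamics features (evolutionary conservation from a
    multiple sequence alignment, residue property distance, relative
    solvent accessibility, geometric hydrogen-bond counts, crystallographic
    B-factors, and RMSD/RMSF trajectory statistics), screens features by
    ROC-AUC, trains a k-nearest-neighbor classifier on curated
    pathogenic/benign variants and classifies VUS. A seeded synthetic-data
    module generates class-conditional feature tables, alignments, toy
    structures and trajectories so that the full pipeline can be exercised
    and calibrated without access to the original simulations and database
    extracts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    Biostrings,
    e1071,
    jsonlite,
    stats,
    utils
Suggests:
    class,
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
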