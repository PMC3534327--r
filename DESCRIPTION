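Package: secretomeSurvey
Title: Genome-Wide Survey of Putative Secreted and Transmembrane Proteins
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for a genome-wide survey of putative secreted and
    transmembrane proteins from precomputed annotations. Reconciles
    signal-peptide and transmembrane-segment predictions into topology
    classes, builds a putative secretome by removing organelle-resident
    proteins, classifies domain architectures and groups proteins into
    families, assigns a phylogenetic origin (nematoda, metazoa, eukaryota)
    through a three-tier ortholog-evidence cascade, sorts transmembrane
    proteins into broad functional categories, and scores stage-, sex- and
    infection-associated expression enrichment from dcpm matrices. Includes
    a synthetic-proteome generator with planted ground truth so every
    pipeline stage is testable without external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
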