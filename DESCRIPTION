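Package: pairshare
Title: Shared Amplicon Sequence Variants in Cohabiting Host Pairs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for paired-host longitudinal 16S rRNA gene
    amplicon surveys, built around the detection of amplicon sequence
    variants (ASVs) shared within cohabiting host pairs (for example a
    human and a dog sampled at matched time points). Provides readers and
    writers for ASV count tables, sample metadata, taxonomy maps and
    rooted phylogenies; taxonomy-based filtering, rarefaction and genus
    summaries; Shannon diversity, weighted UniFrac distances, principal
    coordinate analysis and PERMANOVA; ANCOM differential abundance
    between hosts; and a synthetic cohort generator that injects
    ground-truth transfer events so that every stage of the pipeline can
    be validated against known answers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    stats,
    tools,
    utils,
    vegan
Suggests:
    jsonlite,
    optparse,
    phyloseq,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
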