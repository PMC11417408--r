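Package: EpiContact
Title: Chromatin Compartment and Histone-Mark Redistribution Analysis for
    Binned Hi-C Data
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to integrate binned Hi-C contact maps with epigenomic
    signal tracks in plant genomes. Provides a contact-matrix core
    (ingestion of cooler-style COO triplets and pairs text, low-coverage
    masking, iterative-correction balancing, distance-expected and
    observed/expected transforms, Pearson correlation maps), A/B
    compartment calling from the leading eigenvector with saddle-plot
    compartment strength and compartment-pair (pentad-style) averages,
    insulation-score profiles with boundary calling and aggregate
    TAD/anchor-pair analyses, distance-stratified Z-score differential
    interactions between genotypes, and a rule-based classifier of
    H3K27me3 redistribution between facultative and constitutive
    heterochromatin. A synthetic-genome module simulates matched
    wild-type and DDM1-loss-like datasets (contact matrices, mark and
    methylation tracks, gene/TE annotations, expression tables and truth
    labels) so that every stage of the pipeline can be validated against
    planted structure at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    GenomicRanges,
    GenomeInfoDb,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
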