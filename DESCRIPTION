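Package: mirtfnet
Title: miRNA-TF Regulatory Network Construction and Subtype-Specific
    Marker Discovery
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Reverse-transcriptomics biomarker discovery for disease
    subtypes from curated miRNA association tables. Assigns Gene Ontology
    categories to miRNAs from the annotation of their experimentally
    validated targets (hypergeometric enrichment with Benjamini-Hochberg
    control), builds GO-filtered miRNA-TF composite regulatory networks
    per disease cohort, classifies genes by differential network
    subtraction, and calls marker panels by intersecting key-node,
    shortest-path and gene-set-enrichment evidence. Ships a synthetic
    regulatory-network generator with planted markers for end-to-end
    validation, plus readers and writers for TSV, GMT and SIF.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
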