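Package: cladebench
Title: Clade-Exclusion Benchmarking of Metagenomic Taxonomic Classifiers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A harness for evaluating shotgun-metagenomics taxonomic
    classifiers with clade exclusion. Provides NCBI-taxdump-style taxonomy
    loading with lineage, canonical-rank and lowest-common-ancestor queries;
    packaged mock-community definitions and fully synthetic test worlds;
    error-free shotgun read simulation with ground truth; rank-level clade
    exclusion of reference genome sets; normalized classifier-output parsing
    (generic TSV and Kraken dialects); path-based read scoring with
    sensitivity, precision and taxonomic-distance metrics in per-genome and
    pooled modes; species-overprediction tables with relative-abundance
    cutoffs; and a synthetic classifier with programmable error behaviour for
    closed-loop testing. A command-line interface ties the pieces into
    reproducible benchmark runs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    jsonlite,
    methods,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
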