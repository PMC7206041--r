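Package: sololens
Title: Single-Subject Transcriptome Dysregulation and Interaction Network
    Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis of paired treated/untreated transcriptomes from a
    single subject without replicates. Genes are scored by the absolute
    log2 fold change between the two conditions, partitioned into
    upregulated, downregulated and unaltered groups with a two-component
    Gaussian mixture fitted by expectation-maximization, and gene sets are
    tested for bidirectional dysregulation enrichment with one-sided
    Fisher's exact tests under Benjamini-Yekutieli false-discovery-rate
    control. Differentially expressed genes seed a confidence-weighted
    protein-protein interaction network built from STRING-style link
    tables, on which hub nodes (top decile of degree) and overlapping
    cohesiveness-maximizing clusters with Mann-Whitney significance are
    identified and functionally enriched against GMT collections. A
    negative-binomial paired-count simulator with implanted pathway
    dysregulation and a planted-partition interactome generator provide
    ground-truth fixtures, and a seeded pipeline driver chains all stages
    reproducibly.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    igraph,
    jsonlite,
    yaml,
    S4Vectors,
    SummarizedExperiment
Suggests:
    mclust,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
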