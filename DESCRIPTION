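Package: xhyb
Title: Cross-Species Microarray Hybridization Modeling and Probe Reannotation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for heterologous (cross-species) two-color microarray
    experiments. Models probe-to-transcript cross-hybridization as a bipartite
    graph built from sequence-similarity hits, estimates probe specificity and
    redundancy, and collapses differentially expressed probes to an approximate
    gene count via connected components. Projects Gene Ontology and InterPro
    annotations from orthologous protein clusters (Markov clustering of
    similarity graphs) onto ESTs and then onto array probes. Implements the
    full two-color differential-expression chain from first principles:
    flag-based spot weights, normexp background correction with offset,
    print-tip loess normalization, within-array duplicate-spot consensus
    correlation, per-probe generalized least squares, empirical-Bayes variance
    moderation, and FDR control with a two-line direction classification.
    Includes hypergeometric GO-term enrichment with true-path propagation,
    cross-species co-expression grouping by hierarchical clustering of Pearson
    correlations, and seeded synthetic-data generators with planted ground
    truth so the whole workflow is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    xml2
Suggests:
    limma,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
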