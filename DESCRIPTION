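Package: ewGO
Title: Expression-Weighted Gene Ontology Enrichment Across Ordered Samples
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Hypothesis-unbiased Gene Ontology (GO) enrichment for
    multi-sample and time-series transcriptomes. Instead of testing a short
    list of differentially expressed genes, every expressed gene contributes
    to a per-term, per-sample enrichment score weighted by its mRNA level
    (RPKM/FPKM abundance or microarray log fold change). Cross-sample
    statistics (stepwise and geometric-mean fold changes, enrichment
    proportions, monotone trend flags) summarize each term's trajectory, a
    Grubbs outlier test with recursive ascent through GO levels pinpoints
    terms with exceptional average fold change, and chi-square /
    Kolmogorov-Smirnov tests compare whole enrichment distributions between
    two samples. Includes OBO and GAF 2.x readers, true-path annotation
    propagation, and a deterministic synthetic-data generator with planted
    signal for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    Matrix,
    igraph,
    jsonlite,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
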