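Package: fragwise
Title: Hypothesis-Driven Fragment-Level Transcriptomics for Non-Model Organisms
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Curation and differential-expression analysis of multi-fragment
    transcript expression data from de novo assembled transcriptomes, as used
    in ecotoxicological studies of non-model organisms. Implements annotation
    confirmation from alignment hits, expression-level fragment filtering,
    trimmed-mean-of-M-values (TMM) scale factors, coefficient-of-variation
    based housekeeping-gene selection and housekeeping-referenced
    standardization, exact nonparametric tests (Kruskal-Wallis, Mood's median,
    pairwise rank tests) treating fragments as replicates, a collapsed-gene
    negative-binomial exact test with common-dispersion estimation,
    cross-approach concordance and heatmap-style response classification,
    geometric-mean qPCR normalization, and a negative-binomial synthetic-data
    generator with ground truth emulating a five-treatment duplicate design.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    SummarizedExperiment,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    edgeR,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
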