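Package: regucircuit
Title: Regulatory-Circuit Mapping from Expression and Promoter Acetylation Counts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Integrates differential gene expression, differential histone
    acetylation at promoter windows and cAMP-response-element (CRE) regions,
    expression-contextualized gene regulatory networks, and master-regulator
    inference into one tested pipeline. Provides negative-binomial Wald tests
    for count matrices (single-factor and genotype-by-time designs),
    strand-aware promoter-window construction and interval algebra on genomic
    features, motif-to-gene assignment by TSS distance, contextualization of a
    general TF-to-target network by expressed transcription factors, and an
    iterative out-degree pruning procedure that extracts a densely
    inter-regulating transcription-factor core validated by mutual regulation
    and physical interaction. A synthetic-data generator with planted
    differential effects and a planted regulator core makes every stage
    testable end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    igraph,
    MASS,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    DESeq2,
    optparse
Config/testthat/edition: 3
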