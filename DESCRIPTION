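Package: cisenrich
Title: Cis-Proximity Functional Enrichment for Non-Coding RNA Gene Sets
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Functional annotation transfer for non-coding RNA genes via
    their protein-coding neighborhood on the linear genome. Given a set of
    ncRNA genes and a GTF annotation, the package curates the proximal
    protein-coding genes within a configurable upstream/downstream window,
    optionally refines that pool by TAD co-membership, co-expression,
    miRNA-target evidence, and ncRNA biotype, and tests the pooled coding
    genes for over-representation in user-supplied gene-set collections
    using exact and asymptotic tests (hypergeometric, Fisher, binomial,
    chi-square). Results are reported as ranked tables, dot-plot data, and
    a modularity-clustered term-gene network. A deterministic synthetic
    fixture generator (genome annotation, TADs, expression, targets,
    gene sets with planted signal) supports fully offline testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    BiocGenerics,
    rtracklayer,
    igraph,
    jsonlite,
    yaml,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    fgsea,
    ggplot2
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
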