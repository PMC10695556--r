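Package: pseudobulkDE
Title: Pseudobulk Versus Pseudoreplication Differential Expression for Single-Nucleus RNA-Seq
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to study how treating individual cells as independent
    replicates ("pseudoreplication") inflates false discoveries in
    single-cell and single-nucleus RNA-seq differential expression, relative
    to donor-level pseudobulk analysis. Provides a hierarchical
    negative-binomial count simulator with gene-by-donor random effects,
    dying cells, and doublets; a nucleus-level quality-control cascade
    (library-size and expressed-gene minimums, adaptive MAD thresholds,
    mitochondrial-fraction cut-off, doublet removal) with multi-criterion
    accounting; pseudobulk differential expression by sum aggregation, TMM
    normalisation, and a negative-binomial GLM likelihood-ratio test;
    cell-level Wilcoxon rank-sum differential expression; a donor-label
    permutation benchmark contrasting the two procedures; and diagnostics
    including DEG-count/cell-count correlations and summaries of published
    reference DEG tables shipped as fixtures.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    edgeR,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
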