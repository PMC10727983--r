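Package: cfrepeat
Title: Repeat-Aware Cell-Free RNA Profiling and Diagnostic Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds repeat-aware transcriptome catalogs that unify annotated
    genes with individual repeat-element insertions aggregated to the
    subfamily level, aggregates transcript- and instance-level quantifications
    to feature-level count matrices, and analyses the resulting cell-free RNA
    profiles: median-of-ratios normalization, Shannon entropy and repeat
    composition statistics, covariate-adjusted negative-binomial differential
    expression with Benjamini-Hochberg correction, elastic-net diagnostic
    classifiers evaluated at a 90 percent specificity probability threshold,
    and long-read fragment-length analysis with closest-length annotation
    resolution. Includes a synthetic-data module that generates toy genomes
    with planted repeat instances, an exact-match toy quantifier, negative
    binomial count cohorts with planted disease signatures and covariates,
    and bimodal SINE-like fragment length sets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    MASS,
    S4Vectors,
    glmnet,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    DESeq2,
    pROC,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
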