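Package: tsrnakit
Title: Identification and Interactome Analysis of 5'-tRNA-Derived Small RNAs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for calling and quantifying 5'-tRNA-derived small RNAs
    (5'-tsRNAs) from small RNA sequencing reads: tRNA reference clustering by
    5' sequence identity to resolve multi-mapping, adapter trimming and rRNA
    filtering, mismatch-bounded alignment, per-base coverage profiling,
    median-of-ratios normalization with negative-binomial differential
    abundance, Fisher-exact pulldown enrichment with cell-state allocation,
    emPAI-based protein interactome analysis, and one-site equilibrium
    binding-curve (Kd) fitting. Includes a synthetic-data generator that
    emits every input the pipeline consumes together with a ground-truth
    manifest.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    rlang,
    stringr,
    ggplot2,
    generics,
    minpack.lm,
    fgsea,
    yaml,
    withr,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    DESeq2,
    edgeR,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
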