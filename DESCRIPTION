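Package: dmrpatterns
Title: Differential Methylation Regions and Collaborative Promoter Crosstalk
    Patterns from Binned MBD-seq Coverage
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Calls differential methylation regions (DMRs) from 100-bp binned
    MBD-seq coverage by per-bin Wilcoxon rank-sum testing and a
    consecutive-bin run rule, within four gene-anchored genomic regions
    (distal promoter, TSS, gene body, TES). Genes are classified into twelve
    TSS-anchored collaborative differential methylation patterns (CDMPs),
    pattern gene sets are compared by hypergeometric overlap tests, and
    results are integrated with differential-expression tables. A seeded
    negative-binomial simulator plants region-specific methylation shifts
    and differentially expressed genes with machine-readable ground truth,
    so every stage of the pipeline can be verified end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    rtracklayer,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
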