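Package: rdcnv
Title: Replication-Stress Copy-Number Variation at Recurrent DNA-Break Clusters
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detection and quantification of replication-stress-induced copy
    number variants at recurrent DNA-break clusters (RDCs). Implements
    coverage-erosion scoring of binned log2 read-depth ratios against a
    length-preserving shuffled-region null, template-strand-based single-cell
    copy-number calling from Strand-seq bin counts with Welch-t label
    permutation tests, clustered per-cell per-chromosome permutation tests for
    breakpoint-RDC enrichment, and LAM-HTGTS translocation-junction metrics
    (junction density, microhomology usage, bait-end length). A synthetic-data
    module generates binned coverage pairs with planted subclonal deletions,
    Strand-seq cohorts with haplotype-specific losses, clustered breakpoint
    sets, and junction tables with tunable microhomology spectra, so every
    stage is testable without sequencing data.
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
    IRanges,
    purrr,
    readr,
    rlang,
    S4Vectors,
    stats,
    tibble,
    tidyr,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
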