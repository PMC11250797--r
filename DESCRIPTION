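Package: prc2index
Title: PRC2-AgeIndex: DNA Methylation of PRC2-Bound Low-Methylated
    Regions as an Aging Biomarker
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Computes the PRC2-AgeIndex, an assay-agnostic DNA methylation
    aging score defined as the average methylation within low-methylated
    regions (LMRs) that are highly bound by Polycomb Repressive Complex 2
    (PRC2). Provides readers for per-CpG methylation formats (methcounts,
    bedMethyl, array beta tables), symmetric CpG dyad merging, a two-state
    beta-binomial hidden Markov model for LMR segmentation, aggregation and
    ranking of EZH2/SUZ12 ChIP signal over regions, blacklist filtering,
    the site-level low-methylated CpG (LMC) variant for arrays, RRBS and
    single-cell data, ranked sliding-window methylation profiles, group
    comparisons, and a bisulfite methylome simulator that plants ground
    truth for every stage of the pipeline.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
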