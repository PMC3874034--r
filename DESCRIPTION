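Package: stmaburden
Title: Stochastic Monoallelic Gene Burden in Disease-Associated CNV Regions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies genes as stochastic-monoallelic (StMA), biallelic or
    consistently monoallelic from clonal allelic-expression measurements,
    merges copy-number-variant (CNV) coordinates into maximal and minimal
    overlap regions, maps annotated genes to regions, and tests StMA gene
    enrichment in case CNV datasets against merged population controls using
    three size-aware burden measures (per 1000 mapped genes, per megabase,
    percentage of regions hit) with chi-squared/Fisher contingency tests and
    a transcriptome-resampling permutation null. Ships a synthetic-data
    generator that plants known allelic statuses and CNV enrichment so the
    whole pipeline can be validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    stats,
    utils,
    GenomicRanges,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    withr,
    tidyr
Config/testthat/edition: 3
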