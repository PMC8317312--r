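Package: cnvkindred
Title: Family-Based Prioritization of Copy Number Variants in Dementia Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for prioritizing array-based copy number
    variant (CNV) calls in family-structured disease cohorts. Provides quality
    filtering and merging of PennCNV-style calls, masking of problematic
    genomic regions, gene annotation, common-variant exclusion against
    gnomAD-SV and DGV style reference tables, within-family segregation
    analysis, cohort-wide shared-gene analysis, targeted gene screening, and
    copy-number-stratified case/control association with Fisher's exact test
    and diagnostic likelihood ratios. A seedable synthetic-cohort generator
    emulates PennCNV output with planted segregating, shared, and common CNVs
    so every stage can be exercised without restricted genotype data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
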