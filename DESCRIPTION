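Package: episcreen
Title: Two-Stage Variant-Interaction Screening in Simplex Families
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Family-based search for statistically interacting variant pairs
    (epistasis) in simplex-family case-control cohorts. Implements a two-stage
    chi-square screen over carrier presence profiles with a bit-packed pair
    scan, variant-to-gene network mapping with region and inheritance
    classification, repeated family-wise case-status prediction with weighted
    metrics, PAM/gap-statistic subtype clustering with chi-square FPR feature
    selection, hypergeometric GO-term overrepresentation with FDR control, and
    a gene-triplet finder linking statistical to biological interactions. A
    built-in simplex-family cohort simulator with a planted pairwise
    interaction architecture makes every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    cluster,
    e1071,
    vcfR,
    GenomicRanges,
    GenomeInfoDb,
    IRanges,
    S4Vectors,
    rtracklayer
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
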