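Package: fpsnp
Title: Diagnosing False-Positive SNP Calls Caused by Read Mismapping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A desk-scale pipeline for diagnosing the causes of false-positive
    SNP calls in mapping-based variant discovery. Simulates repeat-structured
    toy genomes and fragmented, misassembled derived references; generates
    provenance-named, error-free paired-end and mate-pair reads so that every
    called SNP is a false positive by construction; maps and calls with naive
    desk-scale stand-ins (or ingests externally produced SAM/VCF); applies a
    standard SNP filter chain (biallelic, quality, depth, mapping quality);
    quantifies per-SNP read mismapping from read provenance; annotates SNP
    sites against genomic features with enrichment tests; and analyses
    balanced multi-factor false-positive count tables with a replicate-stratum
    factorial ANOVA, percentage sums of squares, permutation tests and
    standard errors of differences between cell means.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    Rcpp,
    rtracklayer,
    Rsamtools,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    vcfR
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
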