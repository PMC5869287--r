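Package: haplodiag
Title: Diagnostics for Haplotype Separation in Diploid Genome Assemblies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects and characterises haplotype separation in long-read
    assemblies of heterozygous diploid genomes. Provides a synthetic diploid
    genome and read simulator, an exact/k-mismatch paired-end read mapper with
    bounded multi-mapping, windowed mode-coverage classification of contigs
    into haplotype-separated and allele-collapsed classes, a genome-size model
    based on the separated span fraction, paired-contig detection from
    doubly-mapped read pairs with anchor-based intra-pair alignment and contig
    walks, single-copy-ortholog duplication crosstabs with a Fisher exact
    association test and missing-gene triage, chromosomal-quotient scans for
    male-specific sequence, RPKM expression thresholding with gene-family
    presence reports, and cascade host-read subtraction with stagewise
    accounting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    stringr,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    withr,
    stats,
    methods,
    utils,
    Biostrings,
    IRanges,
    S4Vectors,
    Rsamtools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
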