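Package: haplotally
Title: Combinatorial Haplotype Enumeration and Genotype Abundance from
    Deep Amplicon Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Quantifies within-isolate genotypic diversity from deep
    amplicon sequencing of short, polymorphism-rich "barcode" regions.
    Starting from a consensus sequence and hard-filtered polymorphisms
    (VCF), haplotally enumerates every combination of alternate alleles as
    a concrete reference sequence identified by a bitmask genotype ID,
    assigns quality-filtered, primer-trimmed amplicon reads to genotypes
    by exact indel-aware matching, and reports per-genotype read counts
    and relative abundances. A seeded community simulator produces
    consensus sequences, variant calls, genotype mixtures and
    error-bearing reads with known truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stringr,
    tibble,
    tidyr,
    vcfR,
    withr,
    yaml
Suggests:
    optparse,
    rtracklayer,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
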