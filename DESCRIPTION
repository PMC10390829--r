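Package: tandemcall
Title: Targeted Tandem Repeat Allele Calling from Indexed Alignments
Version: 0.2.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Genotypes short tandem repeat (STR) and VNTR loci as exact
    sequence haplotypes, with forensic length-based allele designations,
    from coordinate-sorted indexed BAM alignments of short or long reads.
    Spanning reads are retrieved through the alignment index, repeat
    boundaries are projected through each read's CIGAR, identical extracted
    sequences are tallied into haplotypes, and alleles are called under
    coverage, proportion, PCR-stutter and ploidy-by-donor filters, for
    single-source and mixed-donor samples. Includes a seeded read simulator
    with machine-readable truth sets for sensitivity analysis across read
    lengths and depths.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    GenomicAlignments,
    GenomicRanges,
    IRanges,
    Rsamtools,
    S4Vectors,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    optparse,
    purrr,
    readr,
    rlang,
    stringr,
    tibble,
    tidyr,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
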