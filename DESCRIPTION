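Package: ddradtools
Title: In Silico Design and Genotype Analysis for Double-Digest RAD-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for planning and analysing double-digest restriction
    site-associated DNA sequencing (ddRAD-Seq) experiments. Predicts
    restriction fragments and single-nucleotide polymorphism (SNP)
    detectability from a reference genome for any pair of restriction
    enzymes, simulates SNP-discovery saturation as a function of read
    budget, applies a high-confidence genotype filtering cascade to
    variant calls from inbred crosses, and validates genotypes by
    two-point F2 linkage mapping with Haldane map distances. A synthetic
    data module generates genomes, annotations, variant sets and F2
    populations with known structure so the whole workflow can be tested
    end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    methods,
    purrr,
    readr,
    rlang,
    rtracklayer,
    S4Vectors,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
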