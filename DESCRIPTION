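Package: sbgtools
Title: Sequence-Based Genotyping: Simulation, Demultiplexing, SNP Calling and Linkage Mapping
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A self-contained sequence-based genotyping (SBG) workflow for
    mapping populations. Simulates restriction-site complexity-reduced,
    inline-barcoded multiplexed sequencing libraries of backcross (BC1) and
    selfed recombinant inbred line (RIL) populations with full truth tables;
    demultiplexes and quality-filters reads; builds reference contigs by
    exact clustering of unique full-length reads with abundance thresholds;
    calls co-dominant biallelic SNP genotypes with a Phred-based diploid
    likelihood model and coverage/genotype-quality/site-quality filters;
    scores offspring against the parents as A/B/H marker codes; removes
    suspect SNPs by missingness and genotypic-frequency rules; and builds
    linkage maps via pairwise recombination fractions, LOD scores,
    shortest-path re-estimation, anchored grouping, multi-start ordering
    with best-map selection, and marker-order stability analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0),
    vcfR
Config/testthat/edition: 3
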