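Package: sdrmap
Title: Mapping and Dating Sex-Determining Regions from Family-Based
    Transcriptome Genotypes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Locates a sex-determining region (SDR) from multi-family
    genotype data under male heterogamety, reconstructs Y-linked gametolog
    sequences from allele-bearing sequence reads, and quantifies and dates
    X:Y divergence. Provides pedigree quality control (allele-sharing
    relatedness), segregation-distortion filtering, a genome-wide scan for
    Y-specific SNPs, sexSNP-augmented two-point linkage mapping with
    Haldane distances, integration of genetic and physical maps,
    read partitioning by Y-specific alleles with mate propagation and
    per-gametolog consensus calling, Nei-Gojobori (1986) synonymous and
    non-synonymous divergence with Jukes-Cantor correction, divergence
    dating, Tajima's relative-rates test, and FPKM-based X/Y expression
    ratio summaries. A synthetic-data generator emulating half-sib crosses
    segregating for a non-recombining Y-specific region provides ground
    truth for parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    stats,
    utils,
    vcfR
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
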