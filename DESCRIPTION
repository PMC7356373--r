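Package: domestiscan
Title: Domestication-Signature Screening for Yeast Population Genomics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A desk-scale pipeline for the population-genomic
    characterization of Saccharomyces cerevisiae strains: quality-threshold
    masking of per-strain consensus sequences, construction of a concatenated
    whole-genome SNP matrix under a call-rate rule, read-backed haplotype
    phasing of highly heterozygous strains, neighbor-joining phylogenies with
    column-bootstrap support, k-mer-seeded screening of domestication marker
    genes (STA1, SUC2, MEL, RTM1, BIO1/BIO6, AQY1/AQY2, horizontally acquired
    regions A/B/C), coverage-ratio gene copy-number estimation, MEL
    allele-group typing with recombinant detection, and a rule-based
    wild/domesticated/feral lifestyle call per strain. A synthetic-data
    module generates reference genomes, strain panels, reads, coverage tracks
    and truth tables so that every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
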