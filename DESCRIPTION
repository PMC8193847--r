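Package: haploXO
Title: SNP-Density Crossovers, Dimorphic Transposable Elements and
    Haplotype Shuffling in Phased MHC Haplotypes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Comparative analysis of phased major histocompatibility
    complex (MHC) class II haplotype sequences. Provides anchor-based
    co-linear comparison of near-identical long haplotypes, SNP
    extraction with deterministic artifact-exclusion rules, windowed
    SNP-density profiles, segmentation into SNP-poor and SNP-rich
    blocks with crossover (XO) breakpoint calling, RepeatMasker
    annotation parsing, dimorphic (presence/absence) transposable
    element locus calling, PRDM9 motif scanning with repeat-overlap
    classification, multi-locus haplotype and linkage tabulation, and
    p-distance neighbor-joining phylogenies. A mosaic-haplotype
    simulator with exact truth sets makes every stage testable at desk
    scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    ape,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
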