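Package: allelome
Title: Allele-Specific ChIP-Seq Binding and Motif-Architecture Analysis in Hybrid Mouse Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying allele-specific transcription-factor binding
    from ChIP-seq in F1 hybrid mouse embryonic stem cells carrying two
    SNP-distinguishable haplotypes (e.g. C57BL/6 x JF1 reciprocal crosses).
    Builds an alternate-haplotype pseudogenome from a reference plus a
    biallelic SNV set, assigns reads to parental haplotypes under stringent
    (0-mismatch) and mapping-bias control (up to 3 mismatches) contracts,
    computes per-peak allelic percentages and a combined two-line allelic
    score, and classifies peaks as bi-allelic, parental-origin or
    strain-specific. Includes strand-aware scanning for KRAB zinc-finger
    binding hexamer motif variants (TGCCGC, GGCCGC), SNP-driven motif
    disruption calling, detection of closely spaced motif clusters and their
    genome-wide density enrichment, and a seeded synthetic hybrid-genome
    ChIP data generator with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    stringr,
    readr,
    ggplot2,
    generics,
    jsonlite,
    stats,
    Biostrings,
    IRanges,
    S4Vectors,
    GenomicRanges,
    Rsamtools,
    rtracklayer,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
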