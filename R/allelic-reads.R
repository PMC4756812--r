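#' Write read placements as SAM
#'
#' Minimal single-end SAM: flag 0/16, MAPQ 255, full-length match CIGAR.
#' Following the SAM convention, minus-strand reads are stored as the
#' forward-strand (reverse-complemented) sequence.
#'
#' @param reads placement tibble with `read_id, chrom, start, strand, seq`.
#' @param genome a [haplotype_genome()] supplying `@SQ` lengths.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_reads_sam <- function(reads, genome, path) {
  sq <- sprintf("@SQ\tSN:%s\tLN:%d", names(genome), nchar(unclass(genome)))
  seq_fwd <- ifelse(reads$strand == "-", revcomp(reads$seq), reads$seq)
  body <- sprintf("%s\t%d\t%s\t%d\t255\t%dM\t*\t0\t0\t%s\t*",
                  reads$read_id, ifelse(reads$strand == "-", 16L, 0L),
                  reads$chrom, reads$start, nchar(reads$seq), seq_fwd)
  readr::write_lines(c("@HD\tVN:1.6\tSO:unknown", sq, body), path)
  invisible(path)
}

#' Read placements from a SAM file
#'
#' The SAM is converted to BAM with Rsamtools and scanned; only placement,
#' strand and sequence are used (the CIGAR is assumed full-length match).
#' Sequences are returned as sequenced, i.e. minus-strand records are
#' reverse-complemented back to read orientation.
#'
#' @param path SAM file.
#' @return placement tibble `read_id, chrom, start, strand, seq`.
#' @export
read_reads_sam <- function(path) {
  bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                          indexDestination = FALSE)
  on.exit(unlink(c(bam, paste0(bam, ".bai"))), add = TRUE)
  res <- Rsamtools::scanBam(bam, param = Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "strand", "seq")))[[1]]
  strand <- ifelse(bitwAnd(res$flag, 16L) > 0L, "-", "+")
  seq_fwd <- as.character(res$seq)
  tibble(
    read_id = res$qname,
    chrom = as.character(res$rname),
    start = res$pos,
    strand = strand,
    seq = ifelse(strand == "-", revcomp(seq_fwd), seq_fwd)
  )
}

#' Count mismatches of placed reads against a haplotype genome
#'
#' The placement-level analogue of remapping with a fixed mismatch budget:
#' each read (reverse-complemented first when on the minus strand) is compared
#' base-by-base to the genome substring it claims to cover.
#'
#' @param reads placement tibble with `chrom, start, strand, seq`.
#' @param genome a [haplotype_genome()].
#' @return integer vector of Hamming distances, one per read.
#' @export
count_mismatches <- function(reads, genome) {
  if (nrow(reads) == 0L) return(integer(0))
  L <- nchar(reads$seq)
  ends <- reads$start + L - 1L
  lens <- nchar(unclass(genome))[reads$chrom]
  if (anyNA(lens))
    abort("read placed on a chromosome absent from the genome.")
  if (any(reads$start < 1L | ends > lens))
    abort("read placement outside chromosome bounds.")
  ref <- substring(unclass(genome)[reads$chrom], reads$start, ends)
  fwd <- ifelse(reads$strand == "-", revcomp(reads$seq), reads$seq)
  hamming(fwd, ref)
}

#' Remove positional duplicate reads
#'
#' Single-end duplicate marking: one representative is kept per
#' `(chrom, start, strand)`, in stable input order. Idempotent.
#'
#' @param reads placement tibble.
#' @return the deduplicated tibble.
#' @export
dedup_reads <- function(reads) {
  reads |> distinct(.data$chrom, .data$start, .data$strand, .keep_all = TRUE)
}

#' Remove reads overlapping insertion/deletion intervals
#'
#' Reads whose footprint intersects any indel interval (1-based inclusive)
#' by at least one base are dropped, because haplotype assignment by
#' substitution-only comparison is undefined across indels.
#'
#' @param reads placement tibble.
#' @param indels tibble with `chrom, start, end` (1-based inclusive); may be
#'   empty.
#' @return the filtered tibble.
#' @export
filter_indel_overlap <- function(reads, indels) {
  if (is.null(indels) || nrow(indels) == 0L || nrow(reads) == 0L) return(reads)
  r <- GenomicRanges::GRanges(reads$chrom, IRanges::IRanges(
    reads$start, reads$start + nchar(reads$seq) - 1L))
  i <- GenomicRanges::GRanges(indels$chrom,
                              IRanges::IRanges(indels$start, indels$end))
  hit <- GenomicRanges::countOverlaps(r, i) > 0L
  reads[!hit, ]
}

#' Assign reads to parental haplotypes
#'
#' Implements the dual-genome mapping contract at placement level.
#'
#' A read is *informative* when its footprint overlaps at least one SNP
#' distinguishing the haplotypes; otherwise its call is `non_informative`.
#'
#' In **stringent** mode (the allelic signal), a read is assigned to the
#' haplotype it matches with zero mismatches -- the placement-level equivalent
#' of remapping against each genome with no mismatches allowed. Since the
#' genomes differ at the overlapped SNPs, at most one haplotype can be a
#' perfect match; reads matching neither (e.g. carrying a sequencing error)
#' are `ambiguous` and excluded from all counts.
#'
#' In **control** mode (the mapping-bias calibration), each genome is tested
#' independently with a budget of up to `max_mismatches_control` mismatches,
#' mirroring a lenient remapping in which a read typically maps to *both*
#' genomes (its SNP alleles only add a mismatch or two). Calls are `B6`,
#' `JF1`, `both` or `neither`; `both` reads later count once on each side of
#' the control tally, which is what centres the control percentage near 50
#' and lets its dispersion measure residual mapping bias rather than true
#' allelic imbalance.
#'
#' @param reads placement tibble (`read_id, chrom, start, strand, seq`).
#' @param b6,jf1 the two [haplotype_genome()]s.
#' @param snps SNP tibble (`chrom, pos, allele_b6, allele_jf1`).
#' @param mode `"stringent"` or `"control"`.
#' @param max_mismatches_control mismatch budget in control mode (default 3).
#' @return `reads` with added columns `mm_b6`, `mm_jf1`, `n_snps_overlapped`,
#'   `call` and `mode`.
#' @export
assign_alleles <- function(reads, b6, jf1, snps,
                           mode = c("stringent", "control"),
                           max_mismatches_control = 3L) {
  mode <- match.arg(mode)
  out <- reads
  out$mm_b6 <- count_mismatches(reads, b6)
  out$mm_jf1 <- count_mismatches(reads, jf1)
  out$n_snps_overlapped <- count_snp_overlaps(reads, snps)
  informative <- out$n_snps_overlapped > 0L
  if (mode == "stringent") {
    out$call <- case_when(
      !informative ~ "non_informative",
      out$mm_b6 == 0L ~ "B6",
      out$mm_jf1 == 0L ~ "JF1",
      TRUE ~ "ambiguous"
    )
  } else {
    maps_b6 <- out$mm_b6 <= max_mismatches_control
    maps_jf1 <- out$mm_jf1 <= max_mismatches_control
    out$call <- case_when(
      !informative ~ "non_informative",
      maps_b6 & maps_jf1 ~ "both",
      maps_b6 ~ "B6",
      maps_jf1 ~ "JF1",
      TRUE ~ "neither"
    )
  }
  out$mode <- mode
  out
}

count_snp_overlaps <- function(reads, snps) {
  if (nrow(reads) == 0L) return(integer(0))
  if (is.null(snps) || nrow(snps) == 0L) return(rep(0L, nrow(reads)))
  r <- GenomicRanges::GRanges(reads$chrom, IRanges::IRanges(
    reads$start, reads$start + nchar(reads$seq) - 1L))
  s <- GenomicRanges::GRanges(snps$chrom, IRanges::IRanges(snps$pos, snps$pos))
  GenomicRanges::countOverlaps(r, s)
}

#' Tally per-peak informative and allele-specific read counts
#'
#' Counts assigned reads whose footprint intersects each peak by at least one
#' base. In stringent mode `IR = ASR_B6 + ASR_JF1` (ambiguous and
#' non-informative reads are excluded from both). In control mode a read
#' called `both` increments the B6 and JF1 control counts once each, so
#' `IR_C = ASR_C_B6 + ASR_C_JF1` still holds with `both` reads counted twice
#' by construction.
#'
#' @param assignments output of [assign_alleles()] (one mode).
#' @param peaks peak tibble (`peak_id, chrom, start, end`).
#' @return tibble `peak_id`, and either `IR, ASR_B6, ASR_JF1` (stringent) or
#'   `IR_C, ASR_C_B6, ASR_C_JF1` (control); one row per peak, zero counts for
#'   peaks with no assigned reads.
#' @export
tally_alleles <- function(assignments, peaks) {
  mode <- if (nrow(assignments) > 0L) assignments$mode[1] else "stringent"
  keep <- assignments$call %in% c("B6", "JF1", "both")
  asg <- assignments[keep, ]
  b6_n <- jf1_n <- rep(0L, nrow(peaks))
  if (nrow(asg) > 0L) {
    r <- GenomicRanges::GRanges(asg$chrom, IRanges::IRanges(
      asg$start, asg$start + nchar(asg$seq) - 1L))
    p <- GenomicRanges::GRanges(peaks$chrom,
                                IRanges::IRanges(peaks$start, peaks$end))
    ov <- GenomicRanges::findOverlaps(r, p)
    qi <- S4Vectors::queryHits(ov)
    si <- S4Vectors::subjectHits(ov)
    calls <- asg$call[qi]
    b6_tab <- table(factor(si[calls %in% c("B6", "both")],
                           levels = seq_len(nrow(peaks))))
    jf1_tab <- table(factor(si[calls %in% c("JF1", "both")],
                            levels = seq_len(nrow(peaks))))
    b6_n <- as.integer(b6_tab)
    jf1_n <- as.integer(jf1_tab)
  }
  out <- tibble(peak_id = peaks$peak_id,
                b6 = b6_n, jf1 = jf1_n, ir = b6_n + jf1_n)
  if (mode == "stringent") {
    out |> select("peak_id", IR = "ir", ASR_B6 = "b6", ASR_JF1 = "jf1")
  } else {
    out |> select("peak_id", IR_C = "ir", ASR_C_B6 = "b6", ASR_C_JF1 = "jf1")
  }
}

#' Per-peak allelic counts for one or both cell lines, both modes
#'
#' Convenience pipeline stage: deduplicates reads, assigns alleles under the
#' stringent and control contracts, and tallies per peak, per cell line.
#'
#' @param reads placement tibble; a `cell_line` column groups lines (a single
#'   unnamed line is labelled `"all"`).
#' @param b6,jf1 the two [haplotype_genome()]s.
#' @param snps SNP tibble.
#' @param peaks peak tibble (`peak_id, chrom, start, end`).
#' @param indels optional indel interval tibble for read exclusion.
#' @param dedup remove positional duplicates first (default `TRUE`).
#' @return tibble with one row per peak x cell line: `peak_id, cell_line,
#'   chrom, IR, ASR_B6, ASR_JF1, IR_C, ASR_C_B6, ASR_C_JF1`.
#' @export
peak_allelic_counts <- function(reads, b6, jf1, snps, peaks, indels = NULL,
                                dedup = TRUE) {
  if (!"cell_line" %in% names(reads)) reads$cell_line <- "all"
  purrr::map(unique(reads$cell_line), function(line) {
    r <- reads[reads$cell_line == line, ]
    if (dedup) r <- dedup_reads(r)
    r <- filter_indel_overlap(r, indels)
    s_tab <- tally_alleles(assign_alleles(r, b6, jf1, snps, "stringent"), peaks)
    c_tab <- tally_alleles(assign_alleles(r, b6, jf1, snps, "control"), peaks)
    left_join(s_tab, c_tab, by = "peak_id") |>
      mutate(cell_line = line, .after = "peak_id")
  }) |>
    bind_rows() |>
    left_join(peaks |> select("peak_id", "chrom"), by = "peak_id") |>
    select("peak_id", "cell_line", "chrom", dplyr::everything())
}
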