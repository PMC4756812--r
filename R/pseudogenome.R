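#' Haplotype genome container
#'
#' A haplotype genome is a named set of chromosome sequences belonging to one
#' parental haplotype of an F1 hybrid (conventionally `"B6"`, the assembly
#' reference, or `"JF1"`, the pseudogenome built by SNV substitution). The two
#' haplotypes of a hybrid differ only at single-nucleotide positions, so both
#' carry identical chromosome names and lengths.
#'
#' @param sequences named character vector, chromosome name -> sequence.
#'   Lowercase (soft-masked) bases are uppercased on construction so motif
#'   scanning never misses masked sequence.
#' @param label haplotype label, e.g. `"B6"` or `"JF1"`.
#' @return an object of class `haplotype_genome` (a named character vector
#'   with a `label` attribute).
#' @examples
#' haplotype_genome(c(chr1 = "ACGTACGT"), label = "B6")
#' @export
haplotype_genome <- function(sequences, label = "B6") {
  if (is.null(names(sequences)) || any(!nzchar(names(sequences))))
    abort("`sequences` must be a named character vector (chromosome names).")
  if (any(nchar(sequences) == 0L))
    abort("chromosome sequences must be non-empty.")
  sequences <- toupper(sequences)
  bad <- grepl("[^ACGTN]", sequences)
  if (any(bad))
    abort(paste0("non-ACGTN characters in chromosome(s): ",
                 paste(names(sequences)[bad], collapse = ", ")))
  structure(sequences, label = label, class = "haplotype_genome")
}

#' @export
#' @method print haplotype_genome
print.haplotype_genome <- function(x, ...) {
  cat("<haplotype_genome> label:", attr(x, "label"), "\n")
  for (nm in names(x))
    cat(sprintf("  %s  %s bp\n", nm, format(nchar(x[[nm]]), big.mark = ",")))
  invisible(x)
}

#' @export
`[.haplotype_genome` <- function(x, i) {
  haplotype_genome(unclass(x)[i], label = attr(x, "label"))
}

genome_label <- function(genome) attr(genome, "label")

#' Load biallelic SNVs from a VCF file
#'
#' Reads a VCF and keeps only biallelic single-nucleotide variants: records
#' whose REF and ALT are both single bases in A/C/G/T. Indels and
#' multi-allelic records are skipped (their count is reported with a message
#' and attached as the `n_skipped` attribute), because reads overlapping
#' insertions or deletions are excluded from the allelic analysis and the
#' haplotype model is SNV-only. REF is taken as the reference-haplotype (B6)
#' allele and ALT as the alternate-haplotype (JF1) allele; pass
#' `ref_haplotype = "JF1"` to flip that convention.
#'
#' @param path VCF file (plain text).
#' @param ref_haplotype which haplotype the VCF REF column represents.
#' @return a tibble with columns `chrom`, `pos` (1-based), `id`, `allele_b6`,
#'   `allele_jf1`, sorted by (chrom, pos).
#' @export
read_snp_vcf <- function(path, ref_haplotype = c("B6", "JF1")) {
  ref_haplotype <- match.arg(ref_haplotype)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0L) {
    snps <- tibble(chrom = character(), pos = integer(), id = character(),
                   allele_b6 = character(), allele_jf1 = character())
    attr(snps, "n_skipped") <- 0L
    return(snps)
  }
  ref <- toupper(fix$REF)
  alt <- toupper(fix$ALT)
  pos <- suppressWarnings(as.integer(fix$POS))
  if (anyNA(pos))
    abort(paste0("malformed POS in VCF record(s): ",
                 paste(which(is.na(pos)), collapse = ", ")))
  keep <- !is.na(ref) & !is.na(alt) &
    ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T")
  n_skipped <- sum(!keep)
  if (n_skipped > 0)
    inform(sprintf("read_snp_vcf: skipped %d non-SNV/multi-allelic record(s).",
                   n_skipped))
  snps <- tibble(
    chrom = fix$CHROM[keep],
    pos = pos[keep],
    id = ifelse(is.na(fix$ID[keep]) | fix$ID[keep] == ".",
                paste0("snp", seq_len(sum(keep))), fix$ID[keep]),
    allele_b6 = if (ref_haplotype == "B6") ref[keep] else alt[keep],
    allele_jf1 = if (ref_haplotype == "B6") alt[keep] else ref[keep]
  ) |>
    arrange(.data$chrom, .data$pos)
  attr(snps, "n_skipped") <- n_skipped
  snps
}

#' Write a SNP table as a minimal VCF
#'
#' REF is the B6 allele, ALT the JF1 allele (the reference assembly is B6).
#'
#' @param snps tibble with `chrom`, `pos`, `id`, `allele_b6`, `allele_jf1`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_snp_vcf <- function(snps, path) {
  header <- c("##fileformat=VCFv4.2",
              "##source=allelome",
              "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  body <- sprintf("%s\t%d\t%s\t%s\t%s\t.\t.\t.",
                  snps$chrom, snps$pos, snps$id,
                  snps$allele_b6, snps$allele_jf1)
  readr::write_lines(c(header, body), path)
  invisible(path)
}

#' Substitute SNP alleles into a haplotype genome
#'
#' Builds the alternate haplotype (pseudogenome) by replacing, at every SNP
#' position, the source haplotype's allele with the target haplotype's allele.
#' The source base is checked against the SNP table first: a mismatch means
#' the SNP set is inconsistent with the genome and is an error, never a silent
#' substitution. Applying the swap twice (B6 -> JF1 -> B6) restores the input
#' byte-for-byte.
#'
#' @param genome a [haplotype_genome()].
#' @param snps SNP tibble as from [read_snp_vcf()].
#' @param target_label label of the haplotype being built (`"JF1"` when
#'   `genome` is B6, `"B6"` when it is JF1).
#' @return a new `haplotype_genome` with `target_label`.
#' @examples
#' b6 <- haplotype_genome(c(chr1 = "ACGTACGT"), "B6")
#' snps <- tibble::tibble(chrom = "chr1", pos = 3L, id = "s1",
#'                        allele_b6 = "G", allele_jf1 = "C")
#' apply_snps(b6, snps, "JF1")
#' @export
apply_snps <- function(genome, snps, target_label = "JF1") {
  if (nrow(snps) == 0L)
    return(haplotype_genome(unclass(genome), label = target_label))
  from_col <- if (genome_label(genome) == "JF1") "allele_jf1" else "allele_b6"
  to_col <- if (target_label == "JF1") "allele_jf1" else "allele_b6"
  if (from_col == to_col)
    abort("source and target haplotype labels must differ.")
  seqs <- unclass(genome)
  missing_chrom <- setdiff(unique(snps$chrom), names(seqs))
  if (length(missing_chrom) > 0)
    abort(paste0("SNP chromosome(s) absent from genome: ",
                 paste(missing_chrom, collapse = ", ")))
  for (chrom in unique(snps$chrom)) {
    s <- snps[snps$chrom == chrom, ]
    chrom_seq <- seqs[[chrom]]
    if (any(s$pos < 1L | s$pos > nchar(chrom_seq)))
      abort(sprintf("SNP position beyond end of %s (length %d).",
                    chrom, nchar(chrom_seq)))
    have <- substring(chrom_seq, s$pos, s$pos)
    bad <- have != s[[from_col]]
    if (any(bad))
      abort(paste0("reference base mismatch (SNP table inconsistent with ",
                   "genome) at: ",
                   paste(sprintf("%s:%d expected %s found %s", chrom,
                                 s$pos[bad], s[[from_col]][bad], have[bad]),
                         collapse = "; ")))
    ch <- strsplit(chrom_seq, "", fixed = TRUE)[[1]]
    ch[s$pos] <- s[[to_col]]
    seqs[[chrom]] <- paste(ch, collapse = "")
  }
  haplotype_genome(seqs, label = target_label)
}

#' Read a genome FASTA into a haplotype genome
#'
#' @param path FASTA file.
#' @param label haplotype label to attach.
#' @return a [haplotype_genome()].
#' @export
read_genome_fasta <- function(path, label = "B6") {
  ss <- Biostrings::readDNAStringSet(path)
  seqs <- as.character(ss)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  haplotype_genome(seqs, label = label)
}

#' Write a haplotype genome to FASTA (60-column wrapped)
#'
#' @param genome a [haplotype_genome()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(genome, path) {
  ss <- Biostrings::DNAStringSet(unclass(genome))
  Biostrings::writeXStringSet(ss, path, width = 60L)
  invisible(path)
}

#' Read peak intervals from a BED file
#'
#' BED is 0-based half-open on disk; coordinates are converted to the 1-based
#' inclusive convention used throughout the package at this boundary.
#'
#' @param path BED file.
#' @return tibble with `peak_id`, `chrom`, `start`, `end` (1-based inclusive).
#' @export
read_peaks_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  ids <- if (!is.null(gr$name) && !anyNA(gr$name)) as.character(gr$name)
         else paste0("peak", seq_along(gr))
  tibble(
    peak_id = ids,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),   # rtracklayer already yields 1-based
    end = GenomicRanges::end(gr)
  )
}

#' Write peak intervals to a BED file
#'
#' @param peaks tibble with `peak_id`, `chrom`, `start`, `end` (1-based
#'   inclusive); written 0-based half-open.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_peaks_bed <- function(peaks, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = peaks$chrom,
    ranges = IRanges::IRanges(start = peaks$start, end = peaks$end),
    name = peaks$peak_id
  )
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}
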