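#' Strand-aware motif scan of a DNA sequence
#'
#' Finds every occurrence of each hexamer motif on both strands of the given
#' sequence: a plus-strand hit where the forward sequence contains the motif,
#' a minus-strand hit where it contains the motif's reverse complement.
#' Overlapping hits are all reported (two overlapping occurrences in inverted
#' orientation count as two motifs), and `N` never matches.
#'
#' @param sequence a single DNA string over A/C/G/T/N.
#' @param motifs character vector of hexamer motifs (e.g. `c("TGCCGC",
#'   "GGCCGC")`).
#' @param seq_id identifier attached to the hits.
#' @return a tibble of hits: `seq_id, start, end, strand, motif_id`, 1-based
#'   inclusive on the forward strand, sorted by start then strand.
#' @examples
#' scan_motifs("GCGGCCGC", "GGCCGC") # two overlapping hits, one per strand
#' @export
scan_motifs <- function(sequence, motifs, seq_id = "seq") {
  if (length(sequence) != 1L) abort("`sequence` must be a single string.")
  if (any(nchar(motifs) != 6L)) abort("motifs must be hexamers (length 6).")
  sequence <- toupper(sequence)
  hits <- purrr::map(motifs, function(m) {
    bind_rows(
      tibble(start = overlap_match_starts(sequence, m), strand = "+"),
      tibble(start = overlap_match_starts(sequence, revcomp(m)), strand = "-")
    ) |> mutate(motif_id = m)
  }) |> bind_rows()
  if (nrow(hits) == 0L)
    return(tibble(seq_id = character(), start = integer(), end = integer(),
                  strand = character(), motif_id = character()))
  hits |>
    mutate(seq_id = seq_id, end = .data$start + 5L) |>
    select("seq_id", "start", "end", "strand", "motif_id") |>
    arrange(.data$start, .data$strand)
}

# All (overlapping) match start positions of a fixed pattern.
overlap_match_starts <- function(sequence, pattern) {
  m <- gregexpr(paste0("(?=", pattern, ")"), sequence, perl = TRUE)[[1]]
  if (m[1] == -1L) integer(0) else as.integer(m)
}

#' Intervening gap between two motif hits
#'
#' The number of bases strictly between the two occurrences:
#' `gap = start2 - end1 - 1`. Adjacent hits have gap 0; overlapping hits have
#' a negative gap.
#'
#' @param hit1,hit2 one-row hit tibbles (or lists) with `seq_id, start, end`;
#'   `hit1` must not start after `hit2`.
#' @return integer gap.
#' @export
pair_gap <- function(hit1, hit2) {
  if (hit1$seq_id != hit2$seq_id)
    abort("hits lie on different sequences.")
  if (hit1$start > hit2$start)
    abort("`hit1` must not start after `hit2`.")
  as.integer(hit2$start - hit1$end - 1L)
}

#' Relative orientation of two motif hits
#'
#' @param hit1,hit2 one-row hit tibbles with `seq_id` and `strand`.
#' @return `"direct"` when the strands are equal, `"inverted"` otherwise.
#' @export
pair_orientation <- function(hit1, hit2) {
  if (hit1$seq_id != hit2$seq_id)
    abort("hits lie on different sequences.")
  if (hit1$strand == hit2$strand) "direct" else "inverted"
}

#' Motif clusters by single-linkage gap chaining
#'
#' Hits on the same sequence are chained when the intervening gap between
#' consecutive occurrences (sorted by start) is strictly below
#' `gap_threshold`; maximal chains with at least two members are returned.
#' With `method = "start"` the start-to-start distance is used instead of the
#' intervening gap.
#'
#' @param hits hit tibble from [scan_motifs()] (any mix of motifs; multiple
#'   `seq_id`s allowed).
#' @param gap_threshold clustering threshold in bp (default 38, strict `<`).
#' @param method distance convention: `"gap"` (intervening bases, default) or
#'   `"start"` (start-to-start).
#' @return tibble of clusters: `cluster_id, seq_id, start, end, n_hits,
#'   members` (list-column of member hit tibbles).
#' @export
find_clusters <- function(hits, gap_threshold = 38, method = c("gap", "start")) {
  method <- match.arg(method)
  empty <- tibble(cluster_id = character(), seq_id = character(),
                  start = integer(), end = integer(), n_hits = integer(),
                  members = list())
  if (nrow(hits) < 2L) return(empty)
  out <- purrr::map(split(hits, hits$seq_id), function(h) {
    h <- h |> arrange(.data$start, .data$strand)
    if (nrow(h) < 2L) return(NULL)
    d <- if (method == "gap") h$start[-1] - h$end[-nrow(h)] - 1L
         else h$start[-1] - h$start[-nrow(h)]
    grp <- cumsum(c(1L, as.integer(!(d < gap_threshold))))
    purrr::map(split(h, grp), function(g) {
      if (nrow(g) < 2L) return(NULL)
      tibble(seq_id = g$seq_id[1], start = min(g$start), end = max(g$end),
             n_hits = nrow(g), members = list(as_tibble(g)))
    }) |> bind_rows()
  }) |> bind_rows()
  if (nrow(out) == 0L) return(empty)
  out |>
    arrange(.data$seq_id, .data$start) |>
    mutate(cluster_id = sprintf("cluster%03d", row_number()), .before = 1)
}

#' Scan motifs across peak intervals of a genome
#'
#' @param peaks peak tibble (`peak_id, chrom, start, end`, 1-based inclusive).
#' @param genome a [haplotype_genome()] (scan the B6 reference by default, or
#'   pass the JF1 pseudogenome for allele-aware scanning).
#' @param motifs hexamer motif set.
#' @return hit tibble with `seq_id = peak_id` and *genomic* coordinates.
#' @export
scan_peak_motifs <- function(peaks, genome, motifs) {
  seqs <- unclass(genome)
  purrr::pmap(peaks |> select("peak_id", "chrom", "start", "end"),
              function(peak_id, chrom, start, end) {
    offset <- as.integer(start) - 1L
    scan_motifs(substring(seqs[[chrom]], start, end), motifs,
                seq_id = peak_id) |>
      mutate(start = .data$start + offset, end = .data$end + offset)
  }) |> bind_rows()
}

#' Per-peak motif content and clustering summary
#'
#' For a peak cohort: per-peak motif counts, the cohort mean and sample SD of
#' motifs per peak, the fraction of peaks with at least two motifs that
#' contain a couple closer than `gap_threshold`, and peak counts by motif
#' content (first motif only / second only / both / neither, for a two-motif
#' set).
#'
#' @param peaks peak tibble.
#' @param genome a [haplotype_genome()].
#' @param motifs hexamer motif set.
#' @param gap_threshold clustering threshold (bp, strict `<`).
#' @return an object of class `motif_summary`: list with `per_peak` (tibble
#'   `peak_id, n_motifs, content, has_close_pair`), `hits`, `clusters`, and
#'   `stats` (one-row tibble: `n_peaks, mean_motifs_per_peak,
#'   sd_motifs_per_peak, n_multi_motif, pct_close_pair_of_multi`, plus one
#'   `n_<content>` column per content bucket).
#' @export
peak_motif_summary <- function(peaks, genome, motifs = c("TGCCGC", "GGCCGC"),
                               gap_threshold = 38) {
  hits <- scan_peak_motifs(peaks, genome, motifs)
  clusters <- find_clusters(hits, gap_threshold = gap_threshold)
  per_peak <- peaks |>
    select("peak_id") |>
    left_join(hits |> group_by(peak_id = .data$seq_id) |>
                summarise(n_motifs = n(),
                          content = motif_content(.data$motif_id, motifs),
                          .groups = "drop"),
              by = "peak_id") |>
    mutate(n_motifs = if_else(is.na(.data$n_motifs), 0L, .data$n_motifs),
           content = if_else(is.na(.data$content), "neither", .data$content),
           has_close_pair = .data$peak_id %in% clusters$seq_id)
  multi <- per_peak |> filter(.data$n_motifs >= 2L)
  content_counts <- table(per_peak$content)
  stats <- tibble(
    n_peaks = nrow(per_peak),
    mean_motifs_per_peak = mean(per_peak$n_motifs),
    sd_motifs_per_peak = sd(per_peak$n_motifs),
    n_multi_motif = nrow(multi),
    pct_close_pair_of_multi =
      if (nrow(multi) > 0) mean(multi$has_close_pair) * 100 else NA_real_
  )
  for (nm in names(content_counts))
    stats[[paste0("n_", nm)]] <- as.integer(content_counts[[nm]])
  structure(list(per_peak = per_peak, hits = hits, clusters = clusters,
                 stats = stats, motifs = motifs,
                 gap_threshold = gap_threshold),
            class = "motif_summary")
}

motif_content <- function(motif_ids, motifs) {
  present <- motifs[motifs %in% motif_ids]
  if (length(present) == 0L) "neither"
  else if (length(present) == length(motifs) && length(motifs) > 1L) "both"
  else paste(present, collapse = "+")
}

#' @export
#' @method print motif_summary
print.motif_summary <- function(x, ...) {
  s <- x$stats
  cat(sprintf(
    paste0("<motif_summary> %d peaks; %.2f +/- %.2f motifs/peak; %.1f%% of ",
           ">=2-motif peaks have a couple < %d bp apart\n"),
    s$n_peaks, s$mean_motifs_per_peak, s$sd_motifs_per_peak,
    s$pct_close_pair_of_multi, x$gap_threshold))
  invisible(x)
}

#' @export
glance.motif_summary <- function(x, ...) x$stats

#' @export
tidy.motif_summary <- function(x, ...) x$per_peak

#' Fold enrichment of motif-cluster density
#'
#' Compares cluster density inside a region set with the genome-wide density,
#' both expressed as bp of sequence per cluster: `fold =
#' bp_per_cluster_genome / bp_per_cluster_regions`. The raw fold is returned
#' together with the half-up-rounded integer used for reporting.
#'
#' @param bp_per_cluster_regions bp of region sequence per cluster (regions).
#' @param bp_per_cluster_genome bp of genome sequence per cluster
#'   (genome-wide).
#' @return one-row tibble: `fold` (raw) and `fold_reported` (integer).
#' @examples
#' cluster_enrichment(2276, 161914) # ~71-fold
#' @export
cluster_enrichment <- function(bp_per_cluster_regions, bp_per_cluster_genome) {
  if (bp_per_cluster_regions <= 0 || bp_per_cluster_genome <= 0)
    abort("bp-per-cluster densities must be positive.")
  fold <- bp_per_cluster_genome / bp_per_cluster_regions
  tibble(fold = fold, fold_reported = as.integer(floor(fold + 0.5)))
}

#' Cluster density of a genome or a region set
#'
#' Counts motif clusters and returns bp of scanned sequence per cluster. With
#' `regions = NULL` the whole genome is scanned and the denominator is the
#' total non-N length; otherwise each region is scanned separately and the
#' denominator is the summed region widths.
#'
#' @param genome a [haplotype_genome()].
#' @param motifs hexamer motif set.
#' @param gap_threshold clustering threshold (bp).
#' @param regions optional region tibble (`peak_id, chrom, start, end`).
#' @return one-row tibble: `n_clusters, bp_scanned, bp_per_cluster`.
#' @export
cluster_density <- function(genome, motifs = c("TGCCGC", "GGCCGC"),
                            gap_threshold = 38, regions = NULL) {
  if (is.null(regions)) {
    hits <- purrr::imap(unclass(genome), function(s, nm)
      scan_motifs(s, motifs, seq_id = nm)) |> bind_rows()
    bp <- sum(nchar(gsub("N", "", unclass(genome), fixed = TRUE)))
  } else {
    hits <- scan_peak_motifs(regions, genome, motifs)
    bp <- sum(interval_length(regions$start, regions$end))
  }
  n_cl <- nrow(find_clusters(hits, gap_threshold = gap_threshold))
  tibble(n_clusters = n_cl, bp_scanned = bp,
         bp_per_cluster = if (n_cl > 0) bp / n_cl else NA_real_)
}

#' Call SNP-driven motif disruptions from allele strings
#'
#' For each SNP, the strings surrounding it (+/- `flank` bp) are extracted
#' from both haplotypes and scanned for the motif set on both strands. When
#' one allele carries a motif occurrence covering the SNP that the other
#' allele lacks, a disruption is called with `lost_in` set to the haplotype
#' lacking the motif and the affected 1-6 position within the motif. When
#' both alleles carry a covering occurrence (e.g. a SNP converting one
#' recognised variant into another) or neither does, no call is made.
#' Windows truncated by a contig edge are shrunk with a warning.
#'
#' @param snps SNP tibble (`chrom, pos, allele_b6, allele_jf1`, optional
#'   `id`).
#' @param b6,jf1 the two [haplotype_genome()]s.
#' @param motifs hexamer motif set.
#' @param flank half-width of the allele string (default 5; must be >= 5 so
#'   every hexamer covering the SNP fits in the window).
#' @return tibble of calls: `snp_id, chrom, pos, lost_in, motif_id,
#'   motif_position_affected, permissive_hits, nonpermissive_hits`
#'   (list-columns of window-coordinate hit tibbles).
#' @export
snp_disruption <- function(snps, b6, jf1, motifs = c("TGCCGC", "GGCCGC"),
                           flank = 5) {
  if (flank < 5) abort("`flank` must be >= 5 to cover all hexamer frames.")
  if (nrow(snps) == 0L)
    return(tibble(snp_id = character(), chrom = character(), pos = integer(),
                  lost_in = character(), motif_id = character(),
                  motif_position_affected = integer(),
                  permissive_hits = list(), nonpermissive_hits = list()))
  ids <- if ("id" %in% names(snps)) snps$id
         else paste0("snp", seq_len(nrow(snps)))
  seqs_b6 <- unclass(b6)
  seqs_jf1 <- unclass(jf1)
  calls <- purrr::pmap(
    list(ids, snps$chrom, snps$pos),
    function(snp_id, chrom, pos) {
      clen <- nchar(seqs_b6[[chrom]])
      wstart <- max(1L, pos - as.integer(flank))
      wend <- min(clen, pos + as.integer(flank))
      if (wstart > pos - flank || wend < pos + flank)
        warn(sprintf("snp_disruption: window for %s truncated by contig edge.",
                     snp_id))
      centre <- pos - wstart + 1L
      h_b6 <- scan_motifs(substring(seqs_b6[[chrom]], wstart, wend), motifs,
                          seq_id = "B6")
      h_jf1 <- scan_motifs(substring(seqs_jf1[[chrom]], wstart, wend), motifs,
                           seq_id = "JF1")
      cov_b6 <- h_b6 |> filter(.data$start <= centre, .data$end >= centre)
      cov_jf1 <- h_jf1 |> filter(.data$start <= centre, .data$end >= centre)
      has_b6 <- nrow(cov_b6) > 0L
      has_jf1 <- nrow(cov_jf1) > 0L
      if (has_b6 == has_jf1) return(NULL)
      hit <- if (has_b6) cov_b6[1, ] else cov_jf1[1, ]
      tibble(
        snp_id = snp_id, chrom = chrom, pos = pos,
        lost_in = if (has_b6) "JF1" else "B6",
        motif_id = hit$motif_id,
        motif_position_affected = if (hit$strand == "+")
          as.integer(centre - hit$start + 1L)
        else as.integer(hit$end - centre + 1L),
        permissive_hits = list(if (has_b6) cov_b6 else cov_jf1),
        nonpermissive_hits = list(if (has_b6) cov_jf1 else cov_b6)
      )
    })
  bind_rows(purrr::compact(calls))
}
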