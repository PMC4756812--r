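test_that("scan_motifs finds hits on both strands with overlaps", {
  h <- scan_motifs("TGCCGC", "TGCCGC")
  expect_equal(nrow(h), 1L)
  expect_equal(h$start, 1L)
  expect_equal(h$strand, "+")

  # GCGGCA is the reverse complement of TGCCGC
  h2 <- scan_motifs("GCGGCA", "TGCCGC")
  expect_equal(nrow(h2), 1L)
  expect_equal(h2$strand, "-")
  expect_equal(h2$start, 1L)

  # two overlapping GGCCGC occurrences in inverted orientation
  h3 <- scan_motifs("GCGGCCGC", "GGCCGC")
  expect_equal(nrow(h3), 2L)
  expect_setequal(h3$start, c(1L, 3L))
  expect_setequal(h3$strand, c("-", "+"))
  expect_equal(pair_orientation(h3[1, ], h3[2, ]), "inverted")

  # N never matches
  expect_equal(nrow(scan_motifs("TGCNGC", "TGCCGC")), 0L)
  expect_error(scan_motifs("ACGT", "TGCCG"), "hexamer")
})

test_that("scan_motifs equals the brute-force sliding-window oracle", {
  set.seed(61)
  for (i in 1:40) {
    s <- random_dna(2000)
    got <- scan_motifs(s, c("TGCCGC", "GGCCGC"))
    want <- oracle_scan(s, c("TGCCGC", "GGCCGC"))
    expect_equal(nrow(got), nrow(want))
    if (nrow(got) > 0) {
      expect_equal(got$start, want$start)
      expect_equal(got$strand, want$strand)
      expect_equal(got$motif_id, want$motif_id)
    }
  }
})

test_that("hit count is invariant under reverse complementing the sequence", {
  set.seed(71)
  for (i in 1:10) {
    s <- random_dna(1000)
    fw <- scan_motifs(s, c("TGCCGC", "GGCCGC"))
    rv <- scan_motifs(revcomp(s), c("TGCCGC", "GGCCGC"))
    expect_equal(nrow(fw), nrow(rv))
    if (nrow(fw) > 0) {
      # positions mirror and strands swap
      mirrored <- sort(1000 - fw$end + 1)
      expect_equal(sort(rv$start), mirrored)
      expect_equal(sum(fw$strand == "+"), sum(rv$strand == "-"))
    }
  }
})

test_that("pair_gap uses the intervening-base convention", {
  mk <- function(start, end, strand = "+", id = "s")
    tibble::tibble(seq_id = id, start = start, end = end, strand = strand,
                   motif_id = "TGCCGC")
  expect_equal(pair_gap(mk(1, 6), mk(10, 15)), 3L)
  expect_equal(pair_gap(mk(1, 6), mk(7, 12)), 0L)
  expect_equal(pair_gap(mk(1, 6), mk(3, 8)), -4L)
  expect_error(pair_gap(mk(1, 6, id = "a"), mk(10, 15, id = "b")),
               "different sequences")
  expect_equal(pair_orientation(mk(1, 6, "+"), mk(10, 15, "+")), "direct")
  expect_equal(pair_orientation(mk(1, 6, "-"), mk(10, 15, "-")), "direct")
  expect_equal(pair_orientation(mk(1, 6, "+"), mk(10, 15, "-")), "inverted")
})

test_that("find_clusters chains consecutive hits under the gap threshold", {
  mk_hits <- function(starts, id = "s")
    tibble::tibble(seq_id = id, start = starts, end = starts + 5L,
                   strand = "+", motif_id = "TGCCGC")
  # gap between starts 100 and 120 is 13 for hexamers -> one cluster
  c1 <- find_clusters(mk_hits(c(100L, 120L)))
  expect_equal(nrow(c1), 1L)
  expect_equal(c1$n_hits, 2L)
  expect_equal(c(c1$start, c1$end), c(100L, 125L))
  # far apart -> none
  expect_equal(nrow(find_clusters(mk_hits(c(100L, 200L)))), 0L)
  # two clusters
  c2 <- find_clusters(mk_hits(c(100L, 130L, 160L, 300L, 330L)))
  expect_equal(nrow(c2), 2L)
  expect_equal(c2$n_hits, c(3L, 2L))
  # start-to-start convention shifts the boundary
  c3 <- find_clusters(mk_hits(c(100L, 138L)), method = "start")
  expect_equal(nrow(c3), 0L)   # start distance 38 is not < 38
  c4 <- find_clusters(mk_hits(c(100L, 137L)), method = "start")
  expect_equal(nrow(c4), 1L)
})

test_that("find_clusters equals the transitive-closure oracle on random hit sets", {
  set.seed(81)
  for (i in 1:30) {
    n <- sample(2:50, 1)
    starts <- sort(sample(1:2000, n))
    hits <- tibble::tibble(seq_id = "s", start = starts, end = starts + 5L,
                           strand = "+", motif_id = "TGCCGC")
    got <- find_clusters(hits, gap_threshold = 38)
    want <- oracle_clusters(hits$start, hits$end, 38)
    expect_equal(nrow(got), length(want))
    if (length(want) > 0) {
      want_sizes <- unname(sort(vapply(want, length, integer(1))))
      expect_equal(sort(got$n_hits), want_sizes)
    }
  }
})

test_that("peak_motif_summary aggregates per-peak content", {
  g <- haplotype_genome(c(chr1 = paste0(
    strrep("A", 99), "TGCCGC",                       # p1: 1 motif
    strrep("A", 95),
    # p2 at 201..400: motifs at 201, 217 (gap 10), 263 (gap 40)
    "TGCCGC", strrep("T", 10), "GGCCGC", strrep("T", 40), "TGCCGC",
    strrep("A", 132),
    strrep("C", 100)                                  # p3: none ("neither")
  )), "B6")
  peaks <- tibble::tibble(peak_id = c("p1", "p2", "p3"),
                          chrom = "chr1",
                          start = c(1L, 201L, 401L),
                          end = c(200L, 400L, 500L))
  ms <- peak_motif_summary(peaks, g)
  pp <- ms$per_peak
  expect_equal(pp$n_motifs, c(1L, 3L, 0L))
  expect_equal(pp$content, c("TGCCGC", "both", "neither"))
  expect_equal(pp$has_close_pair, c(FALSE, TRUE, FALSE))
  s <- ms$stats
  expect_equal(s$mean_motifs_per_peak, mean(c(1, 3, 0)))
  expect_equal(s$sd_motifs_per_peak, oracle_sd(c(1, 3, 0)))
  # one >=2-motif peak, and it has a couple closer than 38 bp
  expect_equal(s$pct_close_pair_of_multi, 100)
  expect_equal(s$n_neither, 1L)
  # two peaks with 1 and 3 hits -> mean 2, sample SD 1.4142
  ms2 <- peak_motif_summary(peaks[1:2, ], g)
  expect_equal(ms2$stats$mean_motifs_per_peak, 2)
  expect_equal(ms2$stats$sd_motifs_per_peak, 1.4142, tolerance = 1e-4)
})

test_that("cluster_enrichment reports raw and rounded folds", {
  ce <- cluster_enrichment(2276, 161914)
  expect_equal(ce$fold, 161914 / 2276)
  expect_equal(ce$fold_reported, 71L)
  expect_equal(cluster_enrichment(1234, 1234)$fold, 1)
  expect_error(cluster_enrichment(0, 10), "positive")
})

test_that("cluster_density matches a brute-force density computation", {
  cfg <- sim_config(n_chromosomes = 2, chrom_length = 16000,
                    n_peaks_per_category = 3, seed = 15)
  arch <- sim_architecture(sim_reference(cfg), cfg)
  g <- arch$reference
  dens_g <- cluster_density(g)
  dens_r <- cluster_density(g, regions = arch$peaks)
  # brute force: oracle scan + oracle clusters per chromosome
  brute_count <- function(seqs) {
    sum(vapply(seqs, function(s) {
      h <- oracle_scan(s, c("TGCCGC", "GGCCGC"))
      length(oracle_clusters(h$start, h$start + 5, 38))
    }, numeric(1)))
  }
  expect_equal(dens_g$n_clusters, brute_count(unclass(g)))
  expect_equal(dens_g$bp_scanned, 32000)
  peak_seqs <- substring(unclass(g)[arch$peaks$chrom], arch$peaks$start,
                         arch$peaks$end)
  expect_equal(dens_r$n_clusters, brute_count(peak_seqs))
  expect_equal(dens_r$bp_scanned, sum(arch$peaks$end - arch$peaks$start + 1))
  # fold from densities equals the brute-force density ratio
  fold <- cluster_enrichment(dens_r$bp_per_cluster, dens_g$bp_per_cluster)
  expect_equal(fold$fold,
               (dens_r$n_clusters / dens_r$bp_scanned) /
                 (dens_g$n_clusters / dens_g$bp_scanned))
})

test_that("snp_disruption calls motif losses from +/-5 bp allele strings", {
  # B6 window AATGCCGCTTT carries TGCCGC; the JF1 C>A at motif position 4
  # destroys it
  b6 <- haplotype_genome(c(chr1 = paste0(strrep("G", 20), "AATGCCGCTTT",
                                         strrep("G", 20))), "B6")
  snps <- tibble::tibble(chrom = "chr1", pos = 26L, id = "s1",
                         allele_b6 = "C", allele_jf1 = "A")
  jf1 <- apply_snps(b6, snps, "JF1")
  call <- snp_disruption(snps, b6, jf1, motifs = "TGCCGC")
  expect_equal(nrow(call), 1L)
  expect_equal(call$lost_in, "JF1")
  expect_equal(call$motif_position_affected, 4L)
  expect_equal(call$motif_id, "TGCCGC")

  # SNP far from any motif: no call
  snps_far <- tibble::tibble(chrom = "chr1", pos = 10L, id = "s2",
                             allele_b6 = "G", allele_jf1 = "T")
  jf1_far <- apply_snps(b6, snps_far, "JF1")
  expect_equal(nrow(snp_disruption(snps_far, b6, jf1_far,
                                   motifs = "TGCCGC")), 0L)
  expect_error(snp_disruption(snps, b6, jf1, flank = 3), "flank")
})

test_that("variant-aware scanning rescues motif-to-motif substitutions", {
  # T>G at motif position 1 converts TGCCGC into GGCCGC: a loss under the
  # canonical motif alone, no loss once the variant is recognised
  b6 <- haplotype_genome(c(chr1 = paste0(strrep("A", 20), "TGCCGC",
                                         strrep("A", 20))), "B6")
  snps <- tibble::tibble(chrom = "chr1", pos = 21L, id = "s1",
                         allele_b6 = "T", allele_jf1 = "G")
  jf1 <- apply_snps(b6, snps, "JF1")
  only_canonical <- snp_disruption(snps, b6, jf1, motifs = "TGCCGC")
  expect_equal(nrow(only_canonical), 1L)
  expect_equal(only_canonical$lost_in, "JF1")
  with_variant <- snp_disruption(snps, b6, jf1,
                                 motifs = c("TGCCGC", "GGCCGC"))
  expect_equal(nrow(with_variant), 0L)
})

test_that("disruption calls on simulated strain-specific peaks are reversible", {
  cfg <- sim_config(n_chromosomes = 2, chrom_length = 16000,
                    n_peaks_per_category = 4, seed = 19)
  arch <- sim_architecture(sim_reference(cfg), cfg)
  jf1 <- apply_snps(arch$reference, arch$snps, "JF1")
  strain <- arch$truth[!is.na(arch$truth$disrupting_pos), ]
  dsnp <- arch$snps[arch$snps$pos %in% strain$disrupting_pos, ]
  calls <- snp_disruption(dsnp, arch$reference, jf1)
  expect_equal(nrow(calls), nrow(strain))
  expect_equal(calls$lost_in[order(calls$pos)],
               strain$lost_in[order(strain$disrupting_pos)])
  # reversibility: relabelling the haplotypes (and the allele columns) swaps
  # each call's lost_in side, i.e. applying the other allele restores the
  # motif on the reconstructed window
  flipped <- dsnp
  flipped$allele_b6 <- dsnp$allele_jf1
  flipped$allele_jf1 <- dsnp$allele_b6
  b6_swapped <- haplotype_genome(unclass(jf1), "B6")
  jf1_swapped <- haplotype_genome(unclass(arch$reference), "JF1")
  calls2 <- snp_disruption(flipped, b6_swapped, jf1_swapped)
  expect_equal(nrow(calls2), nrow(calls))
  expect_true(all(calls2$lost_in[order(calls2$pos)] !=
                    calls$lost_in[order(calls$pos)]))
})
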