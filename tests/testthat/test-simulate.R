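test_that("sim_config validates its invariants", {
  expect_s3_class(sim_config(), "sim_config")
  expect_error(sim_config(read_length = 400, peak_width = 300), "read_length")
  expect_error(sim_config(allelic_fraction_mono = 0.3), "0.5")
  expect_error(sim_config(error_rate = 1.5), "proportions")
  expect_error(sim_config(snp_density = 1e-9, chrom_length = 1000), ">= 1")
})

test_that("sim_reference is deterministic and has requested dimensions", {
  cfg <- sim_config(n_chromosomes = 2, chrom_length = 10000, seed = 1)
  g1 <- sim_reference(cfg)
  g2 <- sim_reference(cfg)
  expect_identical(unclass(g1), unclass(g2))
  expect_equal(length(g1), 2L)
  expect_equal(unname(nchar(unclass(g1))), c(10000L, 10000L))
  expect_false(any(grepl("[^ACGT]", unclass(g1))))
})

test_that("GC fraction of a 1 Mb uniform chromosome is near 0.5", {
  cfg <- sim_config(n_chromosomes = 1, chrom_length = 1000000,
                    snp_density = 0, ensure_peak_snp = FALSE, seed = 9)
  g <- sim_reference(cfg)
  gc <- sum(strsplit(unclass(g)[[1]], "")[[1]] %in% c("G", "C")) / 1000000
  # +/- 0.01 is ~20 binomial SDs at n = 1e6
  expect_gt(gc, 0.49)
  expect_lt(gc, 0.51)
})

test_that("sim_architecture plants one peak and truth row per category", {
  cfg <- sim_config(n_chromosomes = 1, chrom_length = 6000,
                    n_peaks_per_category = 1, seed = 4)
  arch <- sim_architecture(sim_reference(cfg), cfg)
  expect_equal(nrow(arch$peaks), 5L)
  expect_equal(nrow(arch$truth), 5L)
  expect_setequal(arch$truth$category,
                  c("biallelic", "maternal", "paternal",
                    "B6_specific", "JF1_specific"))
  # peaks non-overlapping and within bounds
  p <- arch$peaks[order(arch$peaks$start), ]
  expect_true(all(p$start[-1] > p$end[-nrow(p)]))
  expect_true(all(p$end <= cfg$chrom_length))
  # every peak overlaps at least one SNP
  for (i in seq_len(nrow(p))) {
    expect_true(any(arch$snps$chrom == p$chrom[i] &
                      arch$snps$pos >= p$start[i] &
                      arch$snps$pos <= p$end[i]))
  }
  # truth fractions consistent with category definitions
  bi <- arch$truth[arch$truth$category == "biallelic", ]
  expect_equal(c(bi$b6_frac_jb1, bi$b6_frac_bj1), c(0.5, 0.5))
  mat <- arch$truth[arch$truth$category == "maternal", ]
  expect_equal(c(mat$b6_frac_jb1, mat$b6_frac_bj1), c(0.05, 0.95))
})

test_that("genome too small for the requested peaks errors", {
  cfg <- sim_config(n_chromosomes = 1, chrom_length = 2500,
                    n_peaks_per_category = 4, seed = 1)
  expect_error(sim_architecture(sim_reference(cfg), cfg), "too small")
})

test_that("strain-specific disrupting SNPs break the motif on the right haplotype", {
  cfg <- sim_config(n_chromosomes = 2, chrom_length = 30000,
                    n_peaks_per_category = 5, seed = 21)
  arch <- sim_architecture(sim_reference(cfg), cfg)
  jf1 <- apply_snps(arch$reference, arch$snps, "JF1")
  strain <- arch$truth[arch$truth$category %in% c("B6_specific",
                                                  "JF1_specific"), ]
  expect_true(all(!is.na(strain$disrupting_pos)))
  for (i in seq_len(nrow(strain))) {
    tr <- strain[i, ]
    m1 <- tr$motifs[[1]][1, ]  # disrupted occurrence is the first planted
    win_b6 <- substring(unclass(arch$reference)[[tr$chrom]], m1$start,
                        m1$start + 5)
    win_jf1 <- substring(unclass(jf1)[[tr$chrom]], m1$start, m1$start + 5)
    motif_fwd <- if (m1$strand == "+") m1$motif else revcomp(m1$motif)
    if (tr$category == "B6_specific") {
      expect_equal(unname(win_b6), motif_fwd)
      expect_false(win_jf1 == motif_fwd)
      expect_equal(tr$lost_in, "JF1")
    } else {
      expect_equal(unname(win_jf1), motif_fwd)
      expect_false(win_b6 == motif_fwd)
      expect_equal(tr$lost_in, "B6")
    }
  }
})

test_that("error-free reads match their source haplotype exactly", {
  cfg <- sim_config(n_chromosomes = 1, chrom_length = 11000,
                    n_peaks_per_category = 2, reads_per_peak_per_line = 30,
                    error_rate = 0, duplicate_fraction = 0, seed = 6)
  ds <- sim_dataset(cfg)
  for (hap in c("B6", "JF1")) {
    sub <- ds$reads[ds$reads$true_hap == hap, ]
    mm <- count_mismatches(sub, if (hap == "B6") ds$b6 else ds$jf1)
    expect_true(all(mm == 0L))
  }
  # strand use is symmetric-ish
  expect_gt(mean(ds$reads$strand == "-"), 0.35)
  expect_lt(mean(ds$reads$strand == "-"), 0.65)
})

test_that("haplotype sampling follows the category fraction", {
  # biallelic peak, 1000 error-free reads: B6 count within central 99%
  # binomial band around 500
  cfg <- sim_config(n_chromosomes = 1, chrom_length = 6000,
                    n_peaks_per_category = 1, reads_per_peak_per_line = 1000,
                    error_rate = 0, duplicate_fraction = 0, seed = 17)
  ds <- sim_dataset(cfg)
  bi_id <- ds$truth$peak_id[ds$truth$category == "biallelic"]
  bi <- ds$reads[ds$reads$peak_id == bi_id & ds$reads$cell_line == "JB1", ]
  n_b6 <- sum(bi$true_hap == "B6")
  expect_gte(n_b6, qbinom(0.005, 1000, 0.5))
  expect_lte(n_b6, qbinom(0.995, 1000, 0.5))
  # maternal peak in JB1: ~95% of reads are JF1-origin
  mat_id <- ds$truth$peak_id[ds$truth$category == "maternal"]
  mat <- ds$reads[ds$reads$peak_id == mat_id & ds$reads$cell_line == "JB1", ]
  expect_gt(mean(mat$true_hap == "JF1"), 0.9)
})

test_that("duplicate_fraction adds exact positional copies", {
  cfg <- sim_config(n_chromosomes = 1, chrom_length = 6000,
                    n_peaks_per_category = 1, reads_per_peak_per_line = 20,
                    error_rate = 0, duplicate_fraction = 0.5, seed = 8)
  ds <- sim_dataset(cfg)
  jb1 <- ds$reads[ds$reads$cell_line == "JB1", ]
  expect_equal(nrow(jb1), 150L)  # 5 peaks x 20 reads x 1.5
  expect_equal(sum(jb1$is_duplicate), 50L)
  dup <- jb1[jb1$is_duplicate, ][1, ]
  src <- jb1[!jb1$is_duplicate & jb1$start == dup$start &
               jb1$strand == dup$strand & jb1$chrom == dup$chrom, ]
  expect_true(any(src$seq == dup$seq))
})

test_that("a whole dataset is bit-identical across runs with one seed", {
  cfg <- sim_config(n_chromosomes = 1, chrom_length = 11000,
                    n_peaks_per_category = 2, reads_per_peak_per_line = 15,
                    seed = 33)
  d1 <- sim_dataset(cfg)
  d2 <- sim_dataset(cfg)
  expect_identical(unclass(d1$b6), unclass(d2$b6))
  expect_identical(unclass(d1$jf1), unclass(d2$jf1))
  expect_equal(as.data.frame(d1$reads), as.data.frame(d2$reads))
  expect_equal(as.data.frame(d1$snps), as.data.frame(d2$snps))
})

test_that("without SNPs no read is informative downstream", {
  cfg <- sim_config(n_chromosomes = 1, chrom_length = 11000,
                    n_peaks_per_category = 2, reads_per_peak_per_line = 10,
                    snp_density = 0, ensure_peak_snp = FALSE, seed = 2)
  ds <- sim_dataset(cfg)
  expect_equal(nrow(ds$snps), 0L)
  counts <- peak_allelic_counts(ds$reads, ds$b6, ds$jf1, ds$snps, ds$peaks)
  expect_true(all(counts$IR == 0L))
  expect_true(all(counts$IR_C == 0L))
})

test_that("write_sim_dataset writes the standard formats coherently", {
  cfg <- sim_config(n_chromosomes = 1, chrom_length = 6000,
                    n_peaks_per_category = 1, reads_per_peak_per_line = 10,
                    seed = 12)
  ds <- sim_dataset(cfg)
  dir <- tempfile()
  write_sim_dataset(ds, dir)
  expect_true(all(file.exists(file.path(
    dir, c("b6.fa", "jf1.fa", "snps.vcf", "peaks.bed",
           "reads_JB1.sam", "reads_BJ1.sam", "placements.tsv", "truth.tsv")))))
  expect_equal(unclass(read_genome_fasta(file.path(dir, "jf1.fa"), "JF1")),
               unclass(ds$jf1))
  expect_equal(as.data.frame(read_peaks_bed(file.path(dir, "peaks.bed"))),
               as.data.frame(ds$peaks))
  back <- read_reads_sam(file.path(dir, "reads_JB1.sam"))
  orig <- ds$reads[ds$reads$cell_line == "JB1",
                   c("read_id", "chrom", "start", "strand", "seq")]
  back <- back[match(orig$read_id, back$read_id), ]
  expect_equal(as.data.frame(back), as.data.frame(orig), ignore_attr = TRUE)
})
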