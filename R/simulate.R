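#' Configuration for the synthetic hybrid-genome ChIP simulator
#'
#' Collects every knob of the simulated study design. Defaults reflect the
#' hybrid ESC setting the package targets: two haplotypes diverging by point
#' SNPs at roughly one per 250 bp, 50 bp single-end reads, 300 bp peaks, a
#' 95% allelic fraction at mono-allelically bound peaks, a 0.1% per-base
#' sequencing error rate and a 5% duplicate rate.
#'
#' @param n_chromosomes number of autosomes to simulate.
#' @param chrom_length length of each chromosome (bp).
#' @param snp_density expected SNPs per bp between the haplotypes (default
#'   1/250). `0` disables background SNPs.
#' @param n_peaks_per_category peaks simulated for each of the five truth
#'   categories (`biallelic`, `maternal`, `paternal`, `B6_specific`,
#'   `JF1_specific`).
#' @param peak_width peak width in bp.
#' @param reads_per_peak_per_line unique reads simulated per peak per cell
#'   line (before duplication).
#' @param allelic_fraction_mono fraction of reads drawn from the favoured
#'   haplotype at mono-allelic peaks, in `[0.5, 1]`.
#' @param read_length read length in bp (single-end).
#' @param error_rate per-base substitution error probability.
#' @param duplicate_fraction fraction of reads re-emitted as exact duplicates.
#' @param ensure_peak_snp plant one neutral SNP inside every peak so each peak
#'   can yield informative reads (default `TRUE`).
#' @param seed integer seed; one seed drives all stages through deterministic
#'   per-stage substreams.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(n_chromosomes = 2L,
                       chrom_length = 100000L,
                       snp_density = 1 / 250,
                       n_peaks_per_category = 4L,
                       peak_width = 300L,
                       reads_per_peak_per_line = 50L,
                       allelic_fraction_mono = 0.95,
                       read_length = 50L,
                       error_rate = 0.001,
                       duplicate_fraction = 0.05,
                       ensure_peak_snp = TRUE,
                       seed = 1L) {
  cfg <- list(
    n_chromosomes = as.integer(n_chromosomes),
    chrom_length = as.integer(chrom_length),
    snp_density = snp_density,
    n_peaks_per_category = as.integer(n_peaks_per_category),
    peak_width = as.integer(peak_width),
    reads_per_peak_per_line = as.integer(reads_per_peak_per_line),
    allelic_fraction_mono = allelic_fraction_mono,
    read_length = as.integer(read_length),
    error_rate = error_rate,
    duplicate_fraction = duplicate_fraction,
    ensure_peak_snp = isTRUE(ensure_peak_snp),
    seed = as.integer(seed)
  )
  if (cfg$n_chromosomes < 1L || cfg$chrom_length < 1L)
    abort("`n_chromosomes` and `chrom_length` must be positive.")
  props <- c(cfg$allelic_fraction_mono, cfg$error_rate, cfg$duplicate_fraction)
  if (any(props < 0) || any(props > 1))
    abort("proportions must lie in [0, 1].")
  if (cfg$allelic_fraction_mono < 0.5)
    abort("`allelic_fraction_mono` must be in [0.5, 1].")
  if (cfg$read_length > cfg$peak_width)
    abort("`read_length` must not exceed `peak_width`.")
  if (cfg$snp_density < 0)
    abort("`snp_density` must be non-negative.")
  if (cfg$snp_density > 0 && cfg$snp_density * cfg$chrom_length < 1)
    abort("`snp_density` * `chrom_length` must be >= 1 (or snp_density = 0).")
  structure(cfg, class = "sim_config")
}

sim_categories <- c("biallelic", "maternal", "paternal",
                    "B6_specific", "JF1_specific")

# True B6-read fraction per category and cell line. JF1 is the mother of the
# JB1 line (JF1 x B6 cross) and B6 the mother of BJ1, so a maternally bound
# peak is JF1-biased in JB1 and B6-biased in BJ1; strain-specific peaks favour
# the same haplotype in both lines.
category_b6_fraction <- function(category, cell_line, f) {
  stopifnot(cell_line %in% c("JB1", "BJ1"))
  unname(vapply(category, function(cat) {
    switch(cat,
      biallelic = 0.5,
      maternal = if (cell_line == "JB1") 1 - f else f,
      paternal = if (cell_line == "JB1") f else 1 - f,
      B6_specific = f,
      JF1_specific = 1 - f,
      abort(paste0("unknown truth category: ", cat))
    )
  }, numeric(1)))
}

#' Simulate a reference (B6) genome
#'
#' Uniform-base random chromosomes, uppercase A/C/G/T, deterministic for a
#' fixed config seed.
#'
#' @param config a [sim_config()].
#' @return a [haplotype_genome()] labelled `"B6"`.
#' @export
sim_reference <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(stage_seed(config$seed, "reference"))
  seqs <- vapply(seq_len(config$n_chromosomes), function(i) {
    paste(sample(c("A", "C", "G", "T"), config$chrom_length, replace = TRUE),
          collapse = "")
  }, character(1))
  names(seqs) <- paste0("chr", seq_len(config$n_chromosomes))
  haplotype_genome(seqs, label = "B6")
}

# Edit a motif occurrence into a chromosome string. For minus-strand
# occurrences the reverse complement of the motif is written on the forward
# strand.
insert_motif <- function(chrom_seq, start, motif, strand) {
  written <- if (strand == "+") motif else revcomp(motif)
  paste0(substring(chrom_seq, 1, start - 1), written,
         substring(chrom_seq, start + nchar(motif)))
}

#' Plant peaks, motif architectures and SNPs into a reference genome
#'
#' Lays out non-overlapping peaks for the five truth categories, writes 1-4
#' hexamer motif occurrences into each peak (mixing gaps below and above the
#' 38 bp clustering threshold, both strands, both motif variants), places one
#' neutral SNP inside every peak plus background SNPs at `snp_density`
#' elsewhere, and -- for strain-specific peaks -- one disrupting SNP in the
#' CpG of a planted motif so that the non-permissive haplotype loses the
#' motif. The reference sequence is edited in place (for JF1-specific peaks
#' the broken base is written into the reference, since the reference carries
#' the B6 allele at every SNP).
#'
#' @param reference a [haplotype_genome()] labelled `"B6"`.
#' @param config a [sim_config()].
#' @param motifs character vector of hexamer motifs to plant.
#' @return a list with elements `reference` (edited genome), `peaks` (tibble
#'   `peak_id, chrom, start, end`), `snps` (SNP tibble) and `truth` (tibble
#'   `peak_id, category, b6_frac_jb1, b6_frac_bj1, motifs` (list-column of
#'   per-peak motif tibbles), `disrupting_pos`, `lost_in`).
#' @export
sim_architecture <- function(reference, config,
                             motifs = c("TGCCGC", "GGCCGC")) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(stage_seed(config$seed, "architecture"))
  n_peaks <- 5L * config$n_peaks_per_category
  chroms <- names(reference)
  slot <- config$peak_width + 700L   # spacing keeps peaks well separated
  per_chrom <- (config$chrom_length - 200L) %/% slot
  if (per_chrom * length(chroms) < n_peaks)
    abort(sprintf(paste0("genome too small: %d peak slot(s) available for ",
                         "%d requested peaks."),
                  per_chrom * length(chroms), n_peaks))

  slots <- tibble(
    chrom = rep(chroms, each = per_chrom),
    start = rep(100L + (seq_len(per_chrom) - 1L) * slot, length(chroms))
  )
  slots <- slots[seq_len(n_peaks), ]
  categories <- sample(rep(sim_categories, config$n_peaks_per_category))

  peaks <- tibble(
    peak_id = sprintf("peak%03d", seq_len(n_peaks)),
    chrom = slots$chrom,
    start = slots$start,
    end = slots$start + config$peak_width - 1L
  )

  seqs <- unclass(reference)
  truth_rows <- vector("list", n_peaks)
  snp_rows <- vector("list", n_peaks)

  for (i in seq_len(n_peaks)) {
    pk <- peaks[i, ]
    cat_i <- categories[i]
    width <- config$peak_width

    # motif layout: 1-4 occurrences, first offset early in the peak, then a
    # mix of sub-threshold (< 38 bp) and supra-threshold gaps
    n_mot <- sample(1:4, 1)
    offs <- integer(0)
    cur <- sample(15:50, 1)
    for (k in seq_len(n_mot)) {
      if (cur + 6L > width - 10L) break
      offs <- c(offs, cur)
      gap <- if (stats::runif(1) < 0.6) sample(2:30, 1) else sample(45:70, 1)
      cur <- cur + 6L + gap
    }
    n_mot <- length(offs)
    mot_seq <- sample(motifs, n_mot, replace = TRUE, prob = c(0.75, 0.25)[
      seq_along(motifs)] / sum(c(0.75, 0.25)[seq_along(motifs)]))
    mot_strand <- sample(c("+", "-"), n_mot, replace = TRUE)
    mot_start <- pk$start + offs - 1L
    for (k in seq_len(n_mot))
      seqs[[pk$chrom]] <- insert_motif(seqs[[pk$chrom]], mot_start[k],
                                       mot_seq[k], mot_strand[k])

    # disrupting SNP at the CpG C of the first planted motif, for
    # strain-specific categories only
    # with snp_density = 0 and ensure_peak_snp = FALSE the generator plants
    # no SNPs at all (haplotypes identical, no informative reads), so even
    # strain-specific peaks receive no disrupting SNP in that degenerate mode
    plant_snps <- config$ensure_peak_snp || config$snp_density > 0
    disrupting_pos <- NA_integer_
    lost_in <- NA_character_
    snp_list <- list()
    if (plant_snps && cat_i %in% c("B6_specific", "JF1_specific")) {
      cpg_off <- as.integer(regexpr("CG", mot_seq[1], fixed = TRUE))
      gpos <- if (mot_strand[1] == "+") mot_start[1] + cpg_off - 1L
              else mot_start[1] + (6L - cpg_off)
      intact <- substring(seqs[[pk$chrom]], gpos, gpos)
      # C -> A on the motif strand kills the CpG; on the forward strand that
      # is C -> A (+) or G -> T (-)
      broken <- if (mot_strand[1] == "+") "A" else "T"
      if (cat_i == "B6_specific") {
        lost_in <- "JF1"
        snp_list[[length(snp_list) + 1L]] <- tibble(
          chrom = pk$chrom, pos = gpos, allele_b6 = intact, allele_jf1 = broken)
      } else {
        lost_in <- "B6"
        # reference must carry the broken (B6) allele
        seqs[[pk$chrom]] <- paste0(substring(seqs[[pk$chrom]], 1, gpos - 1L),
                                   broken,
                                   substring(seqs[[pk$chrom]], gpos + 1L))
        snp_list[[length(snp_list) + 1L]] <- tibble(
          chrom = pk$chrom, pos = gpos, allele_b6 = broken, allele_jf1 = intact)
      }
      disrupting_pos <- gpos
    }

    # one neutral SNP per peak, outside motif footprints, so every peak can
    # produce informative reads; placed in the centre band of the peak where
    # reads starting inside the peak can actually cover it
    if (config$ensure_peak_snp) {
      motif_bp <- unlist(lapply(mot_start, function(s) s:(s + 5L)))
      inset <- min(config$read_length - 1L, (width - 2L) %/% 2L)
      cand <- setdiff((pk$start + inset):(pk$end - inset),
                      c(motif_bp, disrupting_pos))
      if (length(cand) == 0L)
        cand <- setdiff(pk$start:pk$end, c(motif_bp, disrupting_pos))
      npos <- sample(cand, 1)
      ref_base <- substring(seqs[[pk$chrom]], npos, npos)
      alt_base <- sample(setdiff(c("A", "C", "G", "T"), ref_base), 1)
      snp_list[[length(snp_list) + 1L]] <- tibble(
        chrom = pk$chrom, pos = npos, allele_b6 = ref_base,
        allele_jf1 = alt_base)
    }

    truth_rows[[i]] <- tibble(
      peak_id = pk$peak_id, chrom = pk$chrom, start = pk$start, end = pk$end,
      category = cat_i,
      b6_frac_jb1 = category_b6_fraction(cat_i, "JB1",
                                         config$allelic_fraction_mono),
      b6_frac_bj1 = category_b6_fraction(cat_i, "BJ1",
                                         config$allelic_fraction_mono),
      motifs = list(tibble(offset = offs, start = mot_start,
                           strand = mot_strand, motif = mot_seq)),
      disrupting_pos = disrupting_pos,
      lost_in = lost_in
    )
    snp_rows[[i]] <- if (length(snp_list)) bind_rows(snp_list) else NULL
  }

  truth <- bind_rows(truth_rows)
  snps <- bind_rows(snp_rows)
  if (nrow(snps) == 0L)
    snps <- tibble(chrom = character(), pos = integer(),
                   allele_b6 = character(), allele_jf1 = character())

  # background SNPs at snp_density, away from motif footprints and peak SNPs
  if (config$snp_density > 0) {
    motif_bp <- unlist(purrr::map2(truth$motifs, truth$chrom, function(m, ch) {
      paste0(ch, ":", unlist(lapply(m$start, function(s) s:(s + 5L))))
    }))
    used <- c(motif_bp, paste0(snps$chrom, ":", snps$pos))
    n_bg <- round(config$snp_density * config$chrom_length *
                    config$n_chromosomes)
    bg <- tibble(
      chrom = sample(names(seqs), n_bg, replace = TRUE),
      pos = sample.int(config$chrom_length, n_bg, replace = TRUE)
    ) |>
      distinct(.data$chrom, .data$pos) |>
      filter(!paste0(.data$chrom, ":", .data$pos) %in% used)
    if (nrow(bg) > 0) {
      bg$allele_b6 <- substring(seqs[bg$chrom], bg$pos, bg$pos)
      bg$allele_jf1 <- vapply(bg$allele_b6, function(b)
        sample(setdiff(c("A", "C", "G", "T"), b), 1), character(1),
        USE.NAMES = FALSE)
      snps <- bind_rows(snps, bg)
    }
  }

  snps <- snps |>
    arrange(.data$chrom, .data$pos) |>
    mutate(id = sprintf("snp%04d", row_number()), .before = "allele_b6")

  list(reference = haplotype_genome(seqs, label = "B6"),
       peaks = peaks, snps = snps, truth = truth)
}

#' Simulate ChIP-seq reads for one hybrid cell line
#'
#' For each peak, `reads_per_peak_per_line` unique reads are drawn with start
#' uniform over the peak, haplotype chosen by the line- and
#' category-dependent B6 fraction from the truth table, strand symmetric
#' (minus-strand reads are stored reverse-complemented, as sequenced),
#' per-base substitution errors at `error_rate`, and a `duplicate_fraction`
#' of reads re-emitted as exact positional copies.
#'
#' @param b6,jf1 the two [haplotype_genome()]s.
#' @param truth truth tibble from [sim_architecture()].
#' @param config a [sim_config()].
#' @param cell_line `"JB1"` (JF1 mother) or `"BJ1"` (B6 mother).
#' @return a placement tibble: `read_id, chrom, start, strand, seq,
#'   cell_line, peak_id, true_hap, is_duplicate`.
#' @export
sim_reads <- function(b6, jf1, truth, config, cell_line = c("JB1", "BJ1")) {
  cell_line <- match.arg(cell_line)
  stopifnot(inherits(config, "sim_config"))
  set.seed(stage_seed(config$seed,
                      if (cell_line == "JB1") "reads_jb1" else "reads_bj1"))
  L <- config$read_length
  n <- config$reads_per_peak_per_line
  frac_col <- if (cell_line == "JB1") "b6_frac_jb1" else "b6_frac_bj1"

  per_peak <- purrr::pmap(
    list(truth$peak_id, truth$chrom, truth$start, truth$end, truth[[frac_col]]),
    function(peak_id, chrom, start, end, b6_frac) {
      starts <- sample(start:(end - L + 1L), n, replace = TRUE)
      hap <- ifelse(rbinom(n, 1L, b6_frac) == 1L, "B6", "JF1")
      strand <- ifelse(rbinom(n, 1L, 0.5) == 1L, "+", "-")
      tibble(chrom = chrom, start = starts, strand = strand,
             true_hap = hap, peak_id = peak_id)
    }) |> bind_rows()

  seq_b6 <- substring(unclass(b6)[per_peak$chrom], per_peak$start,
                      per_peak$start + L - 1L)
  seq_jf1 <- substring(unclass(jf1)[per_peak$chrom], per_peak$start,
                       per_peak$start + L - 1L)
  fwd <- ifelse(per_peak$true_hap == "B6", seq_b6, seq_jf1)

  # sequencing errors: substitute a uniformly chosen different base
  n_err <- rbinom(nrow(per_peak), L, config$error_rate)
  for (i in which(n_err > 0L)) {
    ch <- strsplit(fwd[i], "", fixed = TRUE)[[1]]
    at <- sample.int(L, n_err[i])
    ch[at] <- vapply(ch[at], function(b)
      sample(setdiff(c("A", "C", "G", "T"), b), 1), character(1))
    fwd[i] <- paste(ch, collapse = "")
  }

  reads <- per_peak |>
    mutate(seq = ifelse(.data$strand == "-", revcomp(fwd), fwd),
           cell_line = cell_line, is_duplicate = FALSE)

  n_dup <- round(nrow(reads) * config$duplicate_fraction)
  if (n_dup > 0) {
    dup <- reads[sample.int(nrow(reads), n_dup, replace = TRUE), ] |>
      mutate(is_duplicate = TRUE)
    reads <- bind_rows(reads, dup)
  }
  reads |>
    mutate(read_id = sprintf("%s_r%05d", cell_line, row_number())) |>
    select("read_id", "chrom", "start", "strand", "seq", "cell_line",
           "peak_id", "true_hap", "is_duplicate")
}

#' Simulate a complete two-line hybrid ChIP dataset
#'
#' Runs reference simulation, peak/SNP/motif planting, pseudogenome
#' construction and read simulation for both reciprocal cell lines. Fully
#' deterministic for a fixed `config$seed`.
#'
#' @param config a [sim_config()].
#' @param motifs hexamer motifs to plant.
#' @return a list with `config`, `b6`, `jf1`, `peaks`, `snps`, `truth`, and
#'   `reads` (one placement tibble combining both cell lines).
#' @export
sim_dataset <- function(config = sim_config(), motifs = c("TGCCGC", "GGCCGC")) {
  ref0 <- sim_reference(config)
  arch <- sim_architecture(ref0, config, motifs = motifs)
  jf1 <- apply_snps(arch$reference, arch$snps, target_label = "JF1")
  reads <- bind_rows(
    sim_reads(arch$reference, jf1, arch$truth, config, "JB1"),
    sim_reads(arch$reference, jf1, arch$truth, config, "BJ1")
  )
  list(config = config, b6 = arch$reference, jf1 = jf1, peaks = arch$peaks,
       snps = arch$snps, truth = arch$truth, reads = reads)
}

#' Write a simulated dataset to standard file formats
#'
#' Genomes as FASTA (one per haplotype), SNPs as VCF (REF = B6 allele), peaks
#' as BED (0-based half-open on disk), reads as SAM (one per cell line) plus a
#' placements TSV, truth as TSV.
#'
#' @param dataset list from [sim_dataset()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_sim_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_genome_fasta(dataset$b6, file.path(dir, "b6.fa"))
  write_genome_fasta(dataset$jf1, file.path(dir, "jf1.fa"))
  write_snp_vcf(dataset$snps, file.path(dir, "snps.vcf"))
  write_peaks_bed(dataset$peaks, file.path(dir, "peaks.bed"))
  for (line in unique(dataset$reads$cell_line)) {
    write_reads_sam(dataset$reads[dataset$reads$cell_line == line, ],
                    dataset$b6, file.path(dir, paste0("reads_", line, ".sam")))
  }
  readr::write_tsv(dataset$reads, file.path(dir, "placements.tsv"))
  readr::write_tsv(dataset$truth |> select(-"motifs"),
                   file.path(dir, "truth.tsv"))
  invisible(dir)
}
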