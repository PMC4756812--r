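# Independent brute-force oracles used to cross-check the implementation.
# These deliberately share no code with the package internals.

# position-by-position scan of one motif on both strands
oracle_scan <- function(sequence, motifs) {
  sequence <- toupper(sequence)
  n <- nchar(sequence)
  rows <- list()
  for (m in motifs) {
    rc <- oracle_revcomp(m)
    for (i in seq_len(max(0, n - 5))) {
      w <- substr(sequence, i, i + 5)
      if (w == m)
        rows[[length(rows) + 1]] <- data.frame(start = i, strand = "+",
                                               motif_id = m)
      if (w == rc)
        rows[[length(rows) + 1]] <- data.frame(start = i, strand = "-",
                                               motif_id = m)
    }
  }
  if (length(rows) == 0)
    return(data.frame(start = integer(), strand = character(),
                      motif_id = character()))
  out <- do.call(rbind, rows)
  out[order(out$start, out$strand), , drop = FALSE]
}

oracle_revcomp <- function(x) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(comp[strsplit(toupper(x), "")[[1]]]), collapse = "")
}

# transitive closure of the pairwise gap < threshold relation
oracle_clusters <- function(starts, ends, threshold) {
  n <- length(starts)
  if (n < 2) return(list())
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    for (k in seq_len(n)) {
      if (i == k) next
      lo <- if (starts[i] <= starts[k]) i else k
      hi <- if (starts[i] <= starts[k]) k else i
      gap <- starts[hi] - ends[lo] - 1
      if (gap < threshold) adj[i, k] <- TRUE
    }
  }
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) for (k in seq_len(n)) {
      if (adj[i, k] && comp[k] != comp[i]) {
        comp[comp == comp[k]] <- comp[i]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  comps <- split(seq_len(n), comp)
  Filter(function(m) length(m) >= 2, comps)
}

oracle_hamming <- function(a, b) {
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

# two-pass standard deviation (n-1)
oracle_sd <- function(x) {
  m <- sum(x) / length(x)
  sqrt(sum((x - m)^2) / (length(x) - 1))
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")

# small two-haplotype fixture used across read-assignment tests:
# chr1 of 2000 bp with SNPs at fixed positions
make_fixture <- function(seed = 42, n_snps = 8, len = 2000) {
  set.seed(seed)
  b6 <- haplotype_genome(c(chr1 = random_dna(len)), "B6")
  pos <- sort(sample(seq(60, len - 60), n_snps))
  ref <- substring(unclass(b6)[["chr1"]], pos, pos)
  alt <- vapply(ref, function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1),
                character(1), USE.NAMES = FALSE)
  snps <- tibble::tibble(chrom = "chr1", pos = pos,
                         id = paste0("s", seq_along(pos)),
                         allele_b6 = ref, allele_jf1 = alt)
  jf1 <- apply_snps(b6, snps, "JF1")
  list(b6 = b6, jf1 = jf1, snps = snps)
}

# read copied verbatim from a haplotype at a placement
perfect_read <- function(genome, chrom, start, len = 50, strand = "+",
                         id = "r1") {
  s <- substring(unclass(genome)[[chrom]], start, start + len - 1)
  tibble::tibble(read_id = id, chrom = chrom, start = start, strand = strand,
                 seq = if (strand == "-") revcomp(s) else s)
}

substitute_base <- function(seq, at, base) {
  paste0(substring(seq, 1, at - 1), base, substring(seq, at + 1))
}
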