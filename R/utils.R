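#' Reverse complement of DNA strings
#'
#' Vectorised reverse complement over plain character DNA. Only A/C/G/T/N are
#' handled; case is preserved by uppercasing first (all allelome sequences are
#' uppercase by contract).
#'
#' @param x character vector of DNA sequences.
#' @return character vector of the same length.
#' @examples
#' revcomp("TGCCGC")
#' @export
revcomp <- function(x) {
  flipped <- chartr("ACGTN", "TGCAN", toupper(x))
  vapply(strsplit(flipped, "", fixed = TRUE),
         function(ch) paste(rev(ch), collapse = ""), character(1))
}

#' Length of a 1-based inclusive genomic interval
#'
#' @param start,end 1-based inclusive coordinates, `end >= start`.
#' @return integer vector `end - start + 1`.
#' @examples
#' interval_length(67149603, 67150079) # 477
#' @export
interval_length <- function(start, end) {
  if (any(end < start)) abort("`end` must be >= `start` for every interval.")
  as.integer(end - start + 1)
}

#' Hamming distance between equal-length string vectors
#'
#' Used as the placement-level mismatch counter: all reads in one call share a
#' read length, so the pair of vectors is folded into two byte matrices and
#' compared column-wise.
#'
#' @param a,b character vectors of equal-length strings (`nchar(a) == nchar(b)`
#'   elementwise).
#' @return integer vector of per-pair mismatch counts.
#' @keywords internal
hamming <- function(a, b) {
  if (length(a) != length(b)) abort("`a` and `b` must have the same length.")
  if (length(a) == 0L) return(integer(0))
  na <- nchar(a); nb <- nchar(b)
  if (any(na != nb)) abort("paired strings must have equal lengths.")
  if (length(unique(na)) == 1L) {
    L <- na[1]
    ma <- matrix(utf8ToInt(paste(a, collapse = "")), nrow = L)
    mb <- matrix(utf8ToInt(paste(b, collapse = "")), nrow = L)
    as.integer(colSums(ma != mb))
  } else {
    mapply(function(x, y) sum(charToRaw(x) != charToRaw(y)), a, b,
           USE.NAMES = FALSE)
  }
}

# Deterministic per-stage seed derived from one user seed, so every simulation
# stage has its own reproducible stream and stages can be re-run independently.
# Kept below 2^31 - 1.
stage_seed <- function(seed, stage) {
  offsets <- c(reference = 101L, architecture = 211L, reads_jb1 = 307L,
               reads_bj1 = 401L, generic = 503L)
  off <- offsets[[stage]] %||% offsets[["generic"]]
  as.integer((as.numeric(seed) * 7919 + off) %% 2147483629)
}

# 1-based closed-interval overlap of (s1,e1) with (s2,e2), vectorised.
intervals_overlap <- function(s1, e1, s2, e2) s1 <= e2 & s2 <= e1
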