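#' Consensus peaks across peak sets
#'
#' Keeps the peaks of the first set that intersect (closed intervals, >= 1 bp)
#' at least one peak in *every* other set -- e.g. factor peaks that coincide
#' with co-factor binding sites and are present in both reciprocal cell
#' lines.
#'
#' @param peak_sets list of >= 2 peak tibbles (`peak_id, chrom, start, end`).
#' @return the filtered first peak set.
#' @export
consensus_peaks <- function(peak_sets) {
  if (!is.list(peak_sets) || length(peak_sets) < 2L)
    abort("`peak_sets` must be a list of at least two peak tables.")
  first <- peak_sets[[1]]
  gr1 <- GenomicRanges::GRanges(first$chrom,
                                IRanges::IRanges(first$start, first$end))
  keep <- rep(TRUE, nrow(first))
  for (other in peak_sets[-1]) {
    gro <- GenomicRanges::GRanges(other$chrom,
                                  IRanges::IRanges(other$start, other$end))
    keep <- keep & (GenomicRanges::countOverlaps(gr1, gro) > 0L)
  }
  first[keep, ]
}

#' Run the full allele-specific binding pipeline on a simulated dataset
#'
#' Composes the stages end to end: simulate the hybrid dataset (two
#' haplotypes, peaks with planted motif architectures, reads for both
#' reciprocal lines), tally per-peak allelic counts under the stringent and
#' control contracts, score and classify peaks, summarise motif content, and
#' -- because the simulation carries ground truth -- build a truth-vs-called
#' confusion table. Deterministic for a fixed `config$seed`.
#'
#' @param config a [sim_config()].
#' @param motifs hexamer motif set used for planting and scanning.
#' @param min_ir,sigma_mult,s_bi,s_mono,s_strong scoring thresholds, see
#'   [score_peaks()].
#' @param gap_threshold motif clustering threshold (bp).
#' @param outdir optional directory; when given, all stage outputs (FASTA,
#'   VCF, BED, SAM, TSV tables) and a JSON run summary are written there.
#' @return an object of class `allelome_report`: list with `config`,
#'   `dataset`, `counts`, `calls`, `calibrations`, `motif_summary`,
#'   `confusion` (truth x called matrix), `class_counts` and `recovery`
#'   (class/category agreement rates).
#' @export
run_pipeline <- function(config = sim_config(),
                         motifs = c("TGCCGC", "GGCCGC"),
                         min_ir = 5, sigma_mult = 3,
                         s_bi = 26, s_mono = 27, s_strong = 42.5,
                         gap_threshold = 38,
                         outdir = NULL) {
  ds <- sim_dataset(config, motifs = motifs)
  counts <- peak_allelic_counts(ds$reads, ds$b6, ds$jf1, ds$snps, ds$peaks)
  calls <- score_peaks(counts, min_ir = min_ir, sigma_mult = sigma_mult,
                       s_bi = s_bi, s_mono = s_mono, s_strong = s_strong)
  msum <- peak_motif_summary(ds$peaks, ds$b6, motifs = motifs,
                             gap_threshold = gap_threshold)

  truth_called <- ds$truth |>
    select("peak_id", "category") |>
    rename(truth = "category") |>
    left_join(calls |> select("peak_id", "score_class", "category"),
              by = "peak_id") |>
    mutate(called = case_when(
      is.na(.data$score_class) | .data$score_class == "uninformative" ~
        "uninformative",
      .data$score_class == "biallelic" ~ "biallelic",
      .data$score_class == "monoallelic" ~ .data$category,
      TRUE ~ "indeterminate"
    ))
  lvls <- union(sim_categories, unique(truth_called$called))
  confusion <- table(truth = factor(truth_called$truth, levels = lvls),
                     called = factor(truth_called$called, levels = lvls))

  informative <- truth_called |> filter(.data$called != "uninformative")
  class_of <- function(x) if_else(x == "biallelic", "biallelic", "monoallelic")
  mono <- informative |>
    filter(class_of(.data$truth) == "monoallelic",
           .data$called %in% sim_categories,
           class_of(.data$called) == "monoallelic")
  recovery <- tibble(
    n_informative = nrow(informative),
    class_recovery = mean(class_of(informative$truth) ==
                            if_else(informative$called == "biallelic",
                                    "biallelic", "monoallelic")),
    category_recovery = if (nrow(mono) > 0)
      mean(mono$truth == mono$called) else NA_real_
  )

  report <- structure(
    list(config = config, dataset = ds, counts = counts, calls = calls,
         calibrations = attr(calls, "calibrations"),
         motif_summary = msum, confusion = confusion,
         class_counts = glance(calls), recovery = recovery),
    class = "allelome_report")

  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    write_sim_dataset(ds, outdir)
    readr::write_tsv(counts, file.path(outdir, "allelic_counts.tsv"))
    readr::write_tsv(as_tibble(calls), file.path(outdir, "allelic_calls.tsv"))
    jsonlite::write_json(
      list(seed = config$seed,
           class_counts = as.list(glance(calls)),
           recovery = as.list(recovery),
           calibration = purrr::map(report$calibrations,
                                    ~ as.list(glance(.x))),
           motif_stats = as.list(msum$stats)),
      file.path(outdir, "report.json"), auto_unbox = TRUE, digits = NA)
  }
  report
}

#' @export
#' @method print allelome_report
print.allelome_report <- function(x, ...) {
  cat("<allelome_report>\n")
  cat(sprintf("  peaks simulated: %d; informative: %d\n",
              nrow(x$dataset$peaks), x$recovery$n_informative))
  cat(sprintf("  class recovery: %.1f%%; category recovery: %.1f%%\n",
              100 * x$recovery$class_recovery,
              100 * x$recovery$category_recovery))
  cat("  confusion (truth x called):\n")
  print(x$confusion)
  invisible(x)
}

#' @export
glance.allelome_report <- function(x, ...) {
  bind_cols(x$class_counts, x$recovery |> select(-"n_informative"))
}
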