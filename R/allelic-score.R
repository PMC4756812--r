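#' Percentage of B6-assigned reads
#'
#' `x = ASR_B6 / (ASR_B6 + ASR_JF1) * 100`. A zero denominator marks the peak
#' uninformative and yields `NA` rather than a number.
#'
#' @param asr_b6,asr_jf1 non-negative counts (vectorised).
#' @return numeric vector in `[0, 100]`, `NA` where the denominator is zero.
#' @examples
#' percent_b6(3, 1) # 75
#' @export
percent_b6 <- function(asr_b6, asr_jf1) {
  denom <- asr_b6 + asr_jf1
  if_else(denom > 0, asr_b6 / denom * 100, NA_real_)
}

#' Filter peaks to the informative autosomal set
#'
#' Drops peaks on sex chromosomes (the hybrid ESC lines are male, so the
#' X and Y carry no biallelic information) and keeps a peak only when both
#' `IR >= min_ir` and `IR_C >= min_ir` in *every* cell line present.
#'
#' @param counts tibble from [peak_allelic_counts()] (long, one row per
#'   peak x cell line, with a `chrom` column).
#' @param min_ir minimum informative reads, inclusive (default 5).
#' @param sex_chroms chromosome names to exclude.
#' @return the filtered counts tibble (all lines of the surviving peaks).
#' @export
filter_informative <- function(counts, min_ir = 5,
                               sex_chroms = c("chrX", "chrY", "X", "Y")) {
  counts <- counts |> filter(!.data$chrom %in% sex_chroms)
  ok <- counts |>
    group_by(.data$peak_id) |>
    summarise(keep = all(.data$IR >= min_ir & .data$IR_C >= min_ir),
              .groups = "drop") |>
    filter(.data$keep)
  counts |> filter(.data$peak_id %in% ok$peak_id)
}

#' Calibrate the bi-allelicity range from control percentages
#'
#' For one cell line, the control percentage `j = ASR_C_B6 / (ASR_C_B6 +
#' ASR_C_JF1) * 100` is computed per informative peak. The mean and sample
#' standard deviation (n-1 denominator) of the `j` distribution across peaks
#' define the bi-allelicity range `Y = j_bar +/- sigma_mult * sigma`: under a
#' lenient dual-genome mapping contract most reads map to both haplotypes, so
#' `j` concentrates near 50 and its spread measures residual mapping bias,
#' not true allelic imbalance.
#'
#' Peaks with a zero control denominator are dropped before calibration.
#'
#' @param counts counts tibble (typically after [filter_informative()]).
#' @param cell_line which line to calibrate.
#' @param sigma_mult half-width of Y in standard deviations (default 3).
#' @return an object of class `line_calibration` with fields `cell_line`,
#'   `j_bar`, `sigma`, `y_low`, `y_high`, `sigma_mult`, `n_peaks` and the
#'   per-peak `j` tibble.
#' @examples
#' # j = {40, 60}: j_bar 50, sample SD 14.14, Y = [7.57, 92.43]
#' @export
calibrate <- function(counts, cell_line, sigma_mult = 3) {
  cc <- counts |>
    filter(.data$cell_line == !!cell_line) |>
    mutate(j = percent_b6(.data$ASR_C_B6, .data$ASR_C_JF1)) |>
    filter(!is.na(.data$j))
  if (nrow(cc) < 2L)
    abort("calibration needs >= 2 informative peaks (sigma is undefined).")
  j_bar <- mean(cc$j)
  sigma <- sd(cc$j)
  structure(
    list(cell_line = cell_line, j_bar = j_bar, sigma = sigma,
         sigma_mult = sigma_mult,
         y_low = j_bar - sigma_mult * sigma,
         y_high = j_bar + sigma_mult * sigma,
         n_peaks = nrow(cc),
         j_values = cc |> select("peak_id", "j")),
    class = "line_calibration")
}

#' @export
#' @method print line_calibration
print.line_calibration <- function(x, ...) {
  cat(sprintf(
    "<line_calibration> %s: j_bar = %.2f, sigma = %.2f, Y = [%.2f, %.2f] (n = %d)\n",
    x$cell_line, x$j_bar, x$sigma, x$y_low, x$y_high, x$n_peaks))
  invisible(x)
}

#' @export
tidy.line_calibration <- function(x, ...) x$j_values

#' @export
glance.line_calibration <- function(x, ...) {
  tibble(cell_line = x$cell_line, j_bar = x$j_bar, sigma = x$sigma,
         y_low = x$y_low, y_high = x$y_high, n_peaks = x$n_peaks)
}

#' Combined two-line allelic score
#'
#' `S = (|j_bar_JB1 - x_JB1| + |j_bar_BJ1 - x_BJ1|) / 2`: the mean deviation
#' of the stringent allelic percentage from the control mean across the two
#' reciprocal lines. A parental-origin peak (x near 95 in one line, 5 in the
#' other) and a strain-specific peak (near 95 in both) score equally -- the
#' score measures strength of bias, direction is read separately.
#'
#' @param x_jb1,x_bj1 stringent percentages per line, in `[0, 100]`.
#' @param jbar_jb1,jbar_bj1 control means per line.
#' @return numeric vector `S >= 0`.
#' @examples
#' combined_score(95, 5, 50, 50) # 45
#' @export
combined_score <- function(x_jb1, x_bj1, jbar_jb1, jbar_bj1) {
  (abs(jbar_jb1 - x_jb1) + abs(jbar_bj1 - x_bj1)) / 2
}

#' Classify a peak by the bi-allelicity ranges
#'
#' Inside the calibrated range `Y` in both lines: bi-allelic. Outside in
#' both: mono-allelic. One in, one out: discordant (discarded downstream).
#' Range membership is inclusive at the bounds.
#'
#' @param x_jb1,x_bj1 stringent percentages (vectorised).
#' @param cal_jb1,cal_bj1 [calibrate()] objects for the two lines.
#' @return character vector: `"biallelic"`, `"monoallelic"`, `"discordant"`,
#'   or `NA` where an x is missing.
#' @export
classify_range <- function(x_jb1, x_bj1, cal_jb1, cal_bj1) {
  in1 <- x_jb1 >= cal_jb1$y_low & x_jb1 <= cal_jb1$y_high
  in2 <- x_bj1 >= cal_bj1$y_low & x_bj1 <= cal_bj1$y_high
  case_when(
    is.na(in1) | is.na(in2) ~ NA_character_,
    in1 & in2 ~ "biallelic",
    !in1 & !in2 ~ "monoallelic",
    TRUE ~ "discordant"
  )
}

#' Direction category of a mono-allelic peak
#'
#' Uses the control mean (not 50) as the neutral point per line so that
#' residual mapping bias cannot flip a category. Below the control mean in
#' both lines means the JF1 haplotype is favoured in both: JF1-specific.
#' Above in both: B6-specific. Below in JB1 (JF1 mother) and above in BJ1
#' (B6 mother): the maternal haplotype is favoured in both crosses, so the
#' peak is maternal; the mirror pattern is paternal.
#'
#' @param x_jb1,x_bj1 stringent percentages (vectorised).
#' @param jbar_jb1,jbar_bj1 control means per line.
#' @return character vector: `"maternal"`, `"paternal"`, `"B6_specific"`,
#'   `"JF1_specific"`.
#' @export
categorize_mono <- function(x_jb1, x_bj1, jbar_jb1, jbar_bj1) {
  above1 <- x_jb1 >= jbar_jb1
  above2 <- x_bj1 >= jbar_bj1
  case_when(
    is.na(above1) | is.na(above2) ~ NA_character_,
    above1 & above2 ~ "B6_specific",
    !above1 & !above2 ~ "JF1_specific",
    !above1 & above2 ~ "maternal",
    TRUE ~ "paternal"
  )
}

#' Attach score-threshold labels and the strong-bias flag
#'
#' Alongside the calibrated Y-range class, peaks are labelled by the combined
#' score: `S <= s_bi` bi-allelic, `S >= s_mono` mono-allelic (scores strictly
#' between the two published cut-offs are `"indeterminate"`); `S > s_strong`
#' flags the most strongly biased peaks. Both classifications are reported,
#' never merged.
#'
#' @param calls calls tibble containing an `S` column.
#' @param s_bi,s_mono,s_strong score thresholds (defaults 26, 27, 42.5).
#' @return `calls` with added `score_class` and `strong_bias` columns.
#' @export
annotate_thresholds <- function(calls, s_bi = 26, s_mono = 27,
                                s_strong = 42.5) {
  if (s_bi >= s_mono) abort("`s_bi` must be < `s_mono`.")
  calls |>
    mutate(
      score_class = case_when(
        is.na(.data$S) ~ NA_character_,
        .data$S <= s_bi ~ "biallelic",
        .data$S >= s_mono ~ "monoallelic",
        TRUE ~ "indeterminate"
      ),
      strong_bias = .data$S > s_strong
    )
}

#' Score and classify peaks from per-peak allelic counts
#'
#' The complete allelic-scoring stage: sex-chromosome and minimum-IR
#' filtering, per-line control calibration, stringent percentages, Y-range
#' classification, combined score S, score-threshold labels, strong-bias
#' flag and mono-allelic direction categories. Peaks removed by the filter
#' are reported with class `uninformative`.
#'
#' The direction `category` is filled for peaks that are mono-allelic under
#' the score thresholds (the cohort classification rule); the Y-range class
#' is carried alongside in `range_class`.
#'
#' @param counts tibble from [peak_allelic_counts()] covering cell lines
#'   `"JB1"` and `"BJ1"`.
#' @param min_ir minimum `IR` and `IR_C` per line (default 5).
#' @param sigma_mult Y-range half-width in control SDs (default 3).
#' @param sex_chroms chromosome names excluded from the analysis.
#' @param s_bi,s_mono,s_strong combined-score thresholds.
#' @return an `allelic_calls` tibble: `peak_id, chrom, x_jb1, x_bj1, j_jb1,
#'   j_bj1, S, range_class, score_class, strong_bias, category`, with the two
#'   `line_calibration` objects in the `calibrations` attribute. Uninformative
#'   peaks appear with `NA` scores and class `"uninformative"`.
#' @export
score_peaks <- function(counts, min_ir = 5, sigma_mult = 3,
                        sex_chroms = c("chrX", "chrY", "X", "Y"),
                        s_bi = 26, s_mono = 27, s_strong = 42.5) {
  needed <- c("peak_id", "cell_line", "chrom", "IR", "ASR_B6", "ASR_JF1",
              "IR_C", "ASR_C_B6", "ASR_C_JF1")
  missing_cols <- setdiff(needed, names(counts))
  if (length(missing_cols) > 0)
    abort(paste0("`counts` lacks column(s): ",
                 paste(missing_cols, collapse = ", ")))
  if (!all(c("JB1", "BJ1") %in% counts$cell_line))
    abort("`counts` must contain both cell lines JB1 and BJ1.")

  informative <- filter_informative(counts, min_ir = min_ir,
                                    sex_chroms = sex_chroms)
  cal_jb1 <- calibrate(informative, "JB1", sigma_mult = sigma_mult)
  cal_bj1 <- calibrate(informative, "BJ1", sigma_mult = sigma_mult)

  wide <- informative |>
    mutate(x = percent_b6(.data$ASR_B6, .data$ASR_JF1),
           j = percent_b6(.data$ASR_C_B6, .data$ASR_C_JF1)) |>
    select("peak_id", "chrom", "cell_line", "x", "j") |>
    tidyr::pivot_wider(names_from = "cell_line", values_from = c("x", "j"),
                       names_glue = "{.value}_{tolower(cell_line)}")

  calls <- wide |>
    mutate(
      S = combined_score(.data$x_jb1, .data$x_bj1,
                         cal_jb1$j_bar, cal_bj1$j_bar),
      range_class = classify_range(.data$x_jb1, .data$x_bj1,
                                   cal_jb1, cal_bj1)
    ) |>
    annotate_thresholds(s_bi = s_bi, s_mono = s_mono, s_strong = s_strong) |>
    mutate(
      category = if_else(
        !is.na(.data$score_class) & .data$score_class == "monoallelic",
        categorize_mono(.data$x_jb1, .data$x_bj1,
                        cal_jb1$j_bar, cal_bj1$j_bar),
        "not_applicable")
    )

  dropped <- counts |>
    distinct(.data$peak_id, .data$chrom) |>
    filter(!.data$peak_id %in% calls$peak_id) |>
    mutate(x_jb1 = NA_real_, x_bj1 = NA_real_, j_jb1 = NA_real_,
           j_bj1 = NA_real_, S = NA_real_,
           range_class = "uninformative", score_class = "uninformative",
           strong_bias = NA, category = "not_applicable")

  out <- bind_rows(calls, dropped) |> arrange(.data$peak_id)
  attr(out, "calibrations") <- list(JB1 = cal_jb1, BJ1 = cal_bj1)
  attr(out, "thresholds") <- list(min_ir = min_ir, sigma_mult = sigma_mult,
                                  s_bi = s_bi, s_mono = s_mono,
                                  s_strong = s_strong)
  class(out) <- c("allelic_calls", class(out))
  out
}

#' @export
glance.allelic_calls <- function(x, ...) {
  informative <- x |> filter(.data$score_class != "uninformative")
  tibble(
    n_peaks = nrow(x),
    n_informative = nrow(informative),
    n_biallelic = sum(informative$score_class == "biallelic", na.rm = TRUE),
    n_monoallelic = sum(informative$score_class == "monoallelic",
                        na.rm = TRUE),
    n_maternal = sum(informative$category == "maternal", na.rm = TRUE),
    n_paternal = sum(informative$category == "paternal", na.rm = TRUE),
    n_b6_specific = sum(informative$category == "B6_specific", na.rm = TRUE),
    n_jf1_specific = sum(informative$category == "JF1_specific",
                         na.rm = TRUE),
    n_strong_bias = sum(informative$strong_bias, na.rm = TRUE)
  )
}
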