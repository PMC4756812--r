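#' Plot allelic calls in the two-line percentage plane
#'
#' Scatter of the stringent B6 percentage in JB1 against BJ1, coloured by the
#' score-threshold class. Bi-allelic peaks sit near the centre, parental-
#' origin peaks in the off-diagonal corners, strain-specific peaks in the
#' diagonal corners; the dashed lines mark the control means.
#'
#' @param object an `allelic_calls` tibble from [score_peaks()].
#' @param ... ignored.
#' @return a ggplot object.
#' @export
autoplot.allelic_calls <- function(object, ...) {
  cal <- attr(object, "calibrations")
  df <- as_tibble(object) |> filter(!is.na(.data$x_jb1))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x_jb1, y = .data$x_bj1)) +
    ggplot2::geom_hline(yintercept = cal$BJ1$j_bar, linetype = "dashed",
                        colour = "grey60") +
    ggplot2::geom_vline(xintercept = cal$JB1$j_bar, linetype = "dashed",
                        colour = "grey60") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$score_class,
                                     shape = .data$category), alpha = 0.8) +
    ggplot2::coord_fixed(xlim = c(0, 100), ylim = c(0, 100)) +
    ggplot2::labs(x = "% B6 reads (JB1, stringent)",
                  y = "% B6 reads (BJ1, stringent)",
                  colour = "class", shape = "category") +
    ggplot2::theme_minimal()
}

#' Plot the control-percentage distribution of a line calibration
#'
#' Histogram of per-peak control percentages `j` with the mean and the
#' bi-allelicity range `Y` overlaid.
#'
#' @param object a [calibrate()] result.
#' @param ... ignored.
#' @return a ggplot object.
#' @export
autoplot.line_calibration <- function(object, ...) {
  ggplot2::ggplot(object$j_values, ggplot2::aes(x = .data$j)) +
    ggplot2::geom_histogram(binwidth = 1, fill = "steelblue",
                            colour = "white") +
    ggplot2::geom_vline(xintercept = object$j_bar, colour = "black") +
    ggplot2::geom_vline(xintercept = c(object$y_low, object$y_high),
                        linetype = "dashed", colour = "firebrick") +
    ggplot2::labs(x = sprintf("%% B6 control reads (j), %s",
                              object$cell_line),
                  y = "peaks",
                  title = sprintf("Y = [%.1f, %.1f]",
                                  object$y_low, object$y_high)) +
    ggplot2::theme_minimal()
}

#' Map motif hits and clusters along a peak
#'
#' Strand-aware motif map: one horizontal track per peak, plus-strand hits
#' drawn above the axis and minus-strand hits below, cluster spans shaded.
#'
#' @param summary a [peak_motif_summary()] result.
#' @param peak_ids optional subset of peaks to draw (default: all peaks with
#'   at least one hit, capped at 20).
#' @return a ggplot object.
#' @export
plot_motif_map <- function(summary, peak_ids = NULL) {
  hits <- summary$hits
  if (is.null(peak_ids)) {
    peak_ids <- head(unique(hits$seq_id), 20)
  }
  hits <- hits |> filter(.data$seq_id %in% peak_ids)
  clusters <- summary$clusters |> filter(.data$seq_id %in% peak_ids)
  p <- ggplot2::ggplot(hits)
  if (nrow(clusters) > 0) {
    p <- p + ggplot2::geom_rect(
      data = clusters,
      ggplot2::aes(xmin = .data$start, xmax = .data$end,
                   ymin = -0.6, ymax = 0.6),
      fill = "grey85")
  }
  p +
    ggplot2::geom_segment(
      ggplot2::aes(x = .data$start, xend = .data$end,
                   y = ifelse(.data$strand == "+", 0.3, -0.3),
                   yend = ifelse(.data$strand == "+", 0.3, -0.3),
                   colour = .data$motif_id),
      linewidth = 2) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey50") +
    ggplot2::facet_wrap(~seq_id, scales = "free_x", ncol = 1,
                        strip.position = "right") +
    ggplot2::scale_y_continuous(breaks = c(-0.3, 0.3),
                                labels = c("-", "+"), limits = c(-1, 1)) +
    ggplot2::labs(x = "position (bp)", y = "strand", colour = "motif") +
    ggplot2::theme_minimal()
}
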