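# ggplot2 views of the main result types.

#' Genome-wide copy-number plot of a pipeline report
#'
#' Per-bin corrected read counts along the genome with the decoded segments
#' overlaid as horizontal lines at their expected per-state count
#' (`somy * mu`), the usual genome-wide view for reviewing a single-cell
#' CNV call.
#'
#' @param object an `ont_report`.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.ont_report <- function(object, ...) {
  bins <- dplyr::mutate(object$bins,
                        chrom = factor(.data$chrom, levels = unique(.data$chrom)))
  segs <- dplyr::mutate(object$segments,
                        chrom = factor(.data$chrom, levels = levels(bins$chrom)),
                        expected = .data$somy * object$model$mu)
  ggplot2::ggplot(bins[!bins$masked, ], ggplot2::aes(x = (.data$start + .data$end) / 2e6)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$corrected), size = 0.4, alpha = 0.6) +
    ggplot2::geom_segment(
      data = segs,
      ggplot2::aes(x = .data$start / 1e6, xend = .data$end / 1e6,
                   y = .data$expected, yend = .data$expected,
                   colour = factor(.data$somy)),
      linewidth = 1
    ) +
    ggplot2::facet_grid(. ~ chrom, scales = "free_x", space = "free_x") +
    ggplot2::labs(x = "position (Mb)", y = "corrected read count",
                  colour = "somy") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank(),
                   panel.spacing.x = ggplot2::unit(0.1, "lines"))
}

#' Probe-level view of an aCGH profile
#'
#' Probe log2 ratios along the genome for one control channel, with the
#' trisomic-baseline gain/loss thresholds drawn as horizontal lines.
#'
#' @param object an `acgh_profile`.
#' @param channel `"female"` or `"male"` control channel.
#' @param baseline baseline chromatid count for the threshold lines.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.acgh_profile <- function(object, channel = c("female", "male"),
                                  baseline = 3L, ...) {
  channel <- match.arg(channel)
  thr <- acgh_thresholds(baseline)
  col <- paste0("log2_vs_", channel)
  df <- dplyr::mutate(tibble::as_tibble(object),
                      chrom = factor(.data$chrom, levels = unique(.data$chrom)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$position / 1e6, y = .data[[col]])) +
    ggplot2::geom_point(size = 0.3, alpha = 0.4) +
    ggplot2::geom_hline(yintercept = c(thr$gain, thr$loss),
                        colour = c("orange", "blue"), linetype = "dashed") +
    ggplot2::facet_grid(. ~ chrom, scales = "free_x", space = "free_x") +
    ggplot2::labs(x = "position (Mb)",
                  y = sprintf("log2 ratio vs %s control", channel)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank(),
                   panel.spacing.x = ggplot2::unit(0.1, "lines"))
}

#' Tile view of a concordance cross table
#'
#' Counts per class pair, concordant diagonal highlighted.
#'
#' @param object a `concordance_table`.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.concordance_table <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$method_b, y = .data$method_a)) +
    ggplot2::geom_tile(ggplot2::aes(fill = .data$concordant), colour = "white") +
    ggplot2::geom_text(ggplot2::aes(label = .data$n)) +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "#9ecae1", `FALSE` = "#fcae91"),
                               guide = "none") +
    ggplot2::labs(x = "method B (nanopore)", y = "method A (aCGH)",
                  title = sprintf("%s-level concordance", object$level)) +
    ggplot2::theme_minimal()
}
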