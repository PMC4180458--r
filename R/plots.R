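#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot spike-in RPKM against reference concentration
#'
#' One panel per sample, both axes log10, with the fitted Pearson r in the
#' panel strip data.
#'
#' @param object An [spikein_correlation()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method
autoplot.nsr_spikein_cor <- function(object, ...) {
  d <- object$spike_data
  d <- d[d$rpkm > 0, , drop = FALSE]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$concentration, y = .data$rpkm)) +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         linewidth = 0.4, colour = "red") +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::facet_wrap(~sample) +
    ggplot2::labs(x = "reference concentration", y = "observed RPKM",
                  title = "Spike-in ladder vs observed expression")
}

#' Plot differential calls
#'
#' Mean expression against fold change (log scales), coloured by call
#' direction, with the fold-change thresholds marked.
#'
#' @param object A [call_differential()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method
autoplot.nsr_diff_calls <- function(object, ...) {
  p <- attr(object, "params")
  d <- tibble::as_tibble(object)
  d$mean_rpkm <- (d$rpkm_a + d$rpkm_b) / 2 + p$pseudocount
  ggplot2::ggplot(d, ggplot2::aes(x = .data$mean_rpkm,
                                  y = .data$fold_change,
                                  colour = .data$direction)) +
    ggplot2::geom_point(alpha = 0.7, size = 1) +
    ggplot2::geom_hline(yintercept = c(p$fc_min, 1 / p$fc_min),
                        linetype = "dashed") +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "mean RPKM", y = "fold change (b/a)",
                  colour = "direction")
}

#' Plot a genomic read category breakdown
#'
#' Stacked per-sample bars of the classified read fractions.
#'
#' @param object A [classify_alignments()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method
autoplot.nsr_classification <- function(object, ...) {
  ggplot2::ggplot(object$breakdown,
                  ggplot2::aes(x = .data$sample, y = .data$fraction,
                               fill = .data$category)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "fraction of mapped reads",
                  title = "Genomic distribution of mapped reads")
}

#' Histogram of per-transcript k-mer coverage
#'
#' @param coverage An [hexamer_coverage()] result.
#' @param bins Number of bins.
#' @return A ggplot object.
#' @export
plot_coverage <- function(coverage, bins = 30) {
  per <- coverage$per_transcript
  ggplot2::ggplot(per, ggplot2::aes(x = .data$n_hexamers)) +
    ggplot2::geom_histogram(bins = bins) +
    ggplot2::geom_vline(xintercept = mean(per$n_hexamers), colour = "red") +
    ggplot2::labs(x = "distinct matching k-mers per transcript",
                  y = "transcripts",
                  title = sprintf("mean %.1f matching k-mers",
                                  mean(per$n_hexamers)))
}
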