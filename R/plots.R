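#' Trans-count histogram with the fitted interactability threshold
#'
#' Diagnostic for the failed-bait filter: the bimodal distribution of
#' per-fragment trans-ligation totals on the log1p scale, with the fitted
#' 5% threshold marked.
#'
#' @param object A `chic_truncnb` fit.
#' @param n_trans The trans counts the fit was selected from.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.chic_truncnb <- function(object, n_trans, ...) {
  df <- tibble::tibble(n_trans = n_trans)
  ggplot2::ggplot(df, ggplot2::aes(x = log1p(.data$n_trans))) +
    ggplot2::geom_histogram(binwidth = 0.25, fill = "grey70",
                            colour = "grey30") +
    ggplot2::geom_vline(xintercept = log1p(object$threshold),
                        colour = "red", linetype = 2) +
    ggplot2::geom_vline(xintercept = log1p(object$truncation_point),
                        colour = "blue", linetype = 3) +
    ggplot2::labs(
      x = "log1p(trans di-tags per captured fragment)", y = "fragments",
      title = sprintf("Interactability filter: t = %d, threshold q = %d",
                      object$truncation_point, object$threshold)
    )
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Peak distance distributions by cell line
#'
#' @param peaks Significant-peak tibble (multiple cell lines).
#' @return A ggplot object.
#' @export
plot_peak_distances <- function(peaks) {
  ggplot2::ggplot(peaks,
                  ggplot2::aes(x = .data$distance / 1e3,
                               colour = .data$cell_line)) +
    ggplot2::stat_ecdf() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "distance between interacting fragments (kb)",
                  y = "cumulative fraction of peaks",
                  colour = "cell line")
}

#' Peaks per locus by cell line
#'
#' @param locus_summary Output of [summarize_loci()].
#' @return A ggplot object.
#' @export
plot_locus_summary <- function(locus_summary) {
  ggplot2::ggplot(locus_summary,
                  ggplot2::aes(x = .data$locus_id, y = .data$n_peaks,
                               fill = .data$cell_line)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "locus", y = "interaction peaks",
                  fill = "cell line") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}
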