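#' Dosage plot of relative read coverage
#'
#' One point per bin, faceted by chromosome (and line when several are
#' plotted), with guide lines at the expected levels for copy states 1, 2
#' and 3.
#'
#' @param relcov Output of [relative_coverage()].
#' @param lines Lines to show (default all).
#' @param max_state Highest copy-state guide line.
#' @return A ggplot object.
#' @export
plot_dosage <- function(relcov, lines = NULL, max_state = 3) {
  df <- relcov
  if (!is.null(lines)) df <- df %>% filter(.data$line %in% lines)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$start / 1e6,
                                   y = .data$relcov)) +
    ggplot2::geom_hline(yintercept = seq_len(max_state), colour = "grey75",
                        linetype = "dashed", linewidth = 0.3) +
    ggplot2::geom_point(size = 0.3, alpha = 0.6) +
    ggplot2::facet_grid(line ~ chrom, scales = "free_x", space = "free_x") +
    ggplot2::labs(x = "position (Mb)", y = "relative read coverage") +
    ggplot2::theme_bw()
}

#' Paternal allele frequency plot
#'
#' Binned paternal SNP frequency with guide lines at the expected levels
#' for paternal copy numbers 0..3 (0, 1/2, 2/3, 3/4).
#'
#' @param baf Output of [bin_paternal_fraction()].
#' @param lines Lines to show (default all).
#' @return A ggplot object.
#' @export
plot_allele_frequency <- function(baf, lines = NULL) {
  df <- baf %>% filter(!is.na(.data$frequency))
  if (!is.null(lines)) df <- df %>% filter(.data$line %in% lines)
  guides <- expected_paternal_fraction(0:3)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$start / 1e6,
                                   y = .data$frequency)) +
    ggplot2::geom_hline(yintercept = guides, colour = "grey75",
                        linetype = "dashed", linewidth = 0.3) +
    ggplot2::geom_point(size = 0.3, alpha = 0.6, colour = "steelblue") +
    ggplot2::facet_grid(line ~ chrom, scales = "free_x", space = "free_x") +
    ggplot2::labs(x = "position (Mb)", y = "paternal allele frequency") +
    ggplot2::theme_bw()
}

#' @method autoplot enrichment_result
#' @export
#' @importFrom ggplot2 autoplot
autoplot.enrichment_result <- function(object, ...) {
  df <- tibble(mean_density = object$rand_means)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mean_density)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey25") +
    ggplot2::geom_vline(xintercept = object$observed_mean, colour = "red",
                        linewidth = 0.8) +
    ggplot2::labs(
      x = sprintf("mean %s density (%s bp windows)", object$feature,
                  format(object$window, big.mark = ",")),
      y = "randomized datasets",
      title = sprintf("enrichment ratio %.2f, empirical p %.3g",
                      object$enrichment_ratio, object$p_emp)) +
    ggplot2::theme_bw()
}
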