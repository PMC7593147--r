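#' Plot deviation summaries against the deletion fraction
#'
#' Line plot of the mean grand-mean deviation (solid) and half the
#' confidence-interval-width deviation (dashed; halved for display only)
#' against the fraction of deleted values, faceted by treatment option and
#' effect size x deleted-data type, colored by scenario. A deviation of zero
#' means the treatment reproduced the fully informed weighted analysis.
#'
#' @param summary Output of [summarize_deviation()].
#' @return A ggplot object.
#' @export
plot_deviation <- function(summary) {
  summary$panel <- paste(summary$measure, summary$deleted, sep = " / ")
  ggplot2::ggplot(summary, ggplot2::aes(x = fraction)) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3, colour = "grey40") +
    ggplot2::geom_line(ggplot2::aes(y = dev_mu, colour = scenario)) +
    ggplot2::geom_line(ggplot2::aes(y = dev_ci_width / 2, colour = scenario),
                       linetype = "dashed") +
    ggplot2::facet_grid(ggplot2::vars(option), ggplot2::vars(panel)) +
    ggplot2::labs(x = "fraction of deleted values",
                  y = "deviation from fully informed analysis",
                  colour = "scenario") +
    ggplot2::theme_minimal(base_size = 9)
}
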