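utils::globalVariables(c("rank", "cumulative_fraction"))

#' Plot the cumulative cluster-coverage curve
#'
#' Log-x cumulative frequency of family contributions, the standard view
#' of how few families dominate an LTR-RT complement. Requires ggplot2.
#'
#' @param curve Output of [cumulative_cluster_curve()].
#' @return A ggplot object.
#' @export
plot_cumulative_curve <- function(curve) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting", call. = FALSE)
  }
  ggplot2::ggplot(curve, ggplot2::aes(x = rank, y = cumulative_fraction)) +
    ggplot2::geom_step() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "cluster rank (log scale)",
                  y = "cumulative fraction",
                  title = "Cumulative contribution of LTR-RT families") +
    ggplot2::theme_minimal()
}
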