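#' Stage-wise box plots of a delta table
#'
#' Box plots of baseline-subtracted stiffness / IEMG per stage and leg, in
#' the style of the congestion study's figures (quartile boxes, 1.5 IQR
#' whiskers, outlier dots). Requires ggplot2.
#'
#' @param delta_table A delta table (see [compare_all()]).
#' @param feature Feature to plot (`"delta_stiffness"` or `"delta_iemg"`).
#' @param vibration Vibration condition to plot.
#' @return A ggplot object.
#' @export
plot_deltas <- function(delta_table, feature = "delta_stiffness",
                        vibration = "on") {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop_myovib("missing_dependency", "plot_deltas requires ggplot2")
  d <- delta_table[delta_table$feature == feature &
                     delta_table$vibration == vibration, ]
  if (nrow(d) == 0L) stop_myovib("empty_input", "no rows for that feature/vibration")
  d$stage <- factor(d$stage, levels = vc_stages())
  ylab <- if (feature == "delta_stiffness")
    expression(Delta * " muscle stiffness (N/m)") else
      expression(Delta * " IEMG (a.u.)")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$stage, y = .data$value,
                                  fill = .data$leg)) +
    ggplot2::geom_boxplot(outlier.shape = 16, position = "dodge") +
    ggplot2::labs(x = "Congestion stage", y = ylab, fill = "Leg") +
    ggplot2::theme_minimal()
}
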