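#' Fold-change-plane scatter plot
#'
#' Female T1->T2 log2FC on the X axis, male on the Y axis; MEGs blue, FEGs
#' red, shared stage-regulated genes grey (non-significant points are
#' dropped). Requires ggplot2.
#'
#' @param points a `DynamicsTable`.
#' @param title plot title.
#' @return a ggplot object.
#' @export
fc_plane_plot <- function(points, title = NULL) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("fc_plane_plot requires the ggplot2 package")
  }
  df <- points[points$class != "NONSIG", , drop = FALSE]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$fc_female, y = .data$fc_male,
                                   colour = .data$class)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey70") +
    ggplot2::geom_vline(xintercept = 0, colour = "grey70") +
    ggplot2::geom_point(alpha = 0.6, size = 0.8) +
    ggplot2::scale_colour_manual(values = c(MEG = "#2166ac", FEG = "#b2182b",
                                            SHARED = "grey50")) +
    ggplot2::labs(x = expression(log[2] ~ FC ~ (ovary)),
                  y = expression(log[2] ~ FC ~ (testis)), title = title) +
    ggplot2::theme_minimal()
}

#' Activation/repression percentage bar plot
#'
#' Percent of MEGs (blue) and FEGs (red) achieved by upregulation in the
#' enriched sex vs downregulation in the opposite sex.
#'
#' @param summary a `MechanismSummary`.
#' @param title plot title.
#' @return a ggplot object.
#' @export
mechanism_barplot <- function(summary, title = NULL) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("mechanism_barplot requires the ggplot2 package")
  }
  pct <- mechanism_percentages(summary)
  df <- data.frame(group = rep(c("MEG", "FEG"), each = 2),
                   direction = rep(c("up", "down"), 2),
                   pct = as.numeric(pct))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$direction, y = .data$pct,
                                   fill = .data$group)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::scale_fill_manual(values = c(MEG = "#2166ac", FEG = "#b2182b")) +
    ggplot2::labs(x = NULL, y = "% of sex-enriched genes", title = title) +
    ggplot2::theme_minimal()
}
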