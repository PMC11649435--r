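# ggplot2 views of proportion tables and DPA results.

#' Plot a cluster-proportion table
#'
#' Stacked per-group composition bars: each bar is one group, segments are
#' clusters, heights are the pooled proportions.
#'
#' @param object A [cluster_proportions()] table.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot proportion_table
#' @export
autoplot.proportion_table <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$group, y = .data$proportion,
                                       fill = .data$cluster)) +
    ggplot2::geom_col(width = 0.7) +
    ggplot2::labs(x = NULL, y = "Proportion of cells", fill = "Cluster") +
    ggplot2::theme_minimal()
}

#' Plot a DPA result
#'
#' One bar per cluster showing the proportion-difference statistic
#' (test minus reference), filled by Bonferroni significance, annotated with
#' the adjusted p-value for significant clusters.
#'
#' @param object A [dpa_test()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot dpa_result
#' @export
autoplot.dpa_result <- function(object, ...) {
  d <- tidy(object)
  d$label <- ifelse(d$significant, sprintf("p = %.3g", d$p_bonferroni), "")
  ggplot2::ggplot(d, ggplot2::aes(x = stats::reorder(.data$cluster,
                                                     .data$statistic),
                                  y = .data$statistic,
                                  fill = .data$significant)) +
    ggplot2::geom_col() +
    ggplot2::geom_text(ggplot2::aes(label = .data$label), size = 3,
                       vjust = -0.4) +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey70",
                                          `TRUE` = "#c0392b")) +
    ggplot2::labs(
      x = "Cluster",
      y = sprintf("Proportion difference (%s - %s)",
                  object$groups["test"], object$groups["reference"]),
      fill = sprintf("Bonferroni p < %g", object$alpha)
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}
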