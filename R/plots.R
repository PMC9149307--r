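#' Rank-ordered intercellular score plot
#'
#' Instances are ranked by final intercellular normZ; significant
#' instances (FDR below the threshold) are highlighted. The classic
#' waterfall view for a screen: CTL-activating candidates rise on the
#' left, CTL-suppressive ones sink on the right.
#'
#' @param scores A significance-annotated score table.
#' @param fdr_threshold Highlight cutoff; default 0.05.
#' @return A ggplot object.
#' @export
plot_rank_scores <- function(scores, fdr_threshold = 0.05) {
  df <- scores |>
    dplyr::arrange(dplyr::desc(.data$z_final)) |>
    dplyr::mutate(rank = dplyr::row_number(),
                  significant = .data$fdr < fdr_threshold)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rank, y = .data$z_final,
                                   colour = .data$significant)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(x = "rank", y = "intercellular normZ",
                  colour = paste0("FDR < ", fdr_threshold)) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.ic_run <- function(object, ...) {
  plot_rank_scores(object$scores, object$config$fdr_threshold)
}

#' Confusion-matrix heatmap for an evaluation report
#'
#' @param object An `ic_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ic_report <- function(object, ...) {
  df <- as.data.frame(object$confusion)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$prediction, y = .data$truth,
                                   fill = .data$Freq)) +
    ggplot2::geom_tile(colour = "white") +
    ggplot2::geom_text(ggplot2::aes(label = .data$Freq)) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue") +
    ggplot2::labs(x = "prediction", y = "truth", fill = "count") +
    ggplot2::theme_minimal()
}
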