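# ggplot2 views of the result objects.

#' Ranked composite-score bar plot for a signature evaluation
#'
#' Samples ordered by composite score, colored by class — the standard
#' view of how cleanly the signature separates cases from controls.
#'
#' @param object A `signature_eval`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot signature_eval
#' @export
autoplot.signature_eval <- function(object, ...) {
  d <- object$scores |>
    mutate(ord = seq_len(dplyr::n()),
           class = factor(ifelse(.data$label == 1L, "case", "control"),
                          levels = c("control", "case")))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$ord, y = .data$score,
                                  fill = .data$class)) +
    ggplot2::geom_col(width = 1) +
    ggplot2::scale_fill_manual(values = c(control = "#2ca05a", case = "#e0b000")) +
    ggplot2::labs(x = "samples (ranked by composite score)",
                  y = "composite score",
                  subtitle = sprintf("AUC = %.3f, p = %.2g", object$auc, object$p)) +
    ggplot2::theme_minimal()
}

#' Violin plot of composite scores by class
#'
#' @param eval A `signature_eval`.
#' @return A ggplot object.
#' @export
plot_score_violin <- function(eval) {
  d <- tidy(eval) |>
    mutate(class = factor(ifelse(.data$label == 1L, "case", "control"),
                          levels = c("control", "case")))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$class, y = .data$score,
                                  fill = .data$class)) +
    ggplot2::geom_violin(alpha = 0.6) +
    ggplot2::geom_jitter(width = 0.12, size = 0.7) +
    ggplot2::scale_fill_manual(values = c(control = "#2ca05a", case = "#e0b000"),
                               guide = "none") +
    ggplot2::labs(x = NULL, y = "composite score") +
    ggplot2::theme_minimal()
}

#' Cluster-size distribution on log-log axes
#'
#' The scale-free diagnostic: sizes of the equivalence clusters against
#' their frequency, both on log10 scales.
#'
#' @param clusters Cluster tibble from [extract_clusters()].
#' @return A ggplot object.
#' @export
plot_cluster_sizes <- function(clusters) {
  d <- cluster_size_distribution(clusters)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$size, y = .data$n_clusters)) +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "cluster size", y = "number of clusters") +
    ggplot2::theme_minimal()
}
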