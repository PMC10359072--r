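#' Plot recovery trajectories coloured by cluster
#'
#' One line per subject across the four timepoints, coloured and facetted by
#' the selected clusters — the standard visual for recovery phenotypes.
#'
#' @param object A [cluster_trajectories()] solution.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot cluster_solution
#' @export
autoplot.cluster_solution <- function(object, ...) {
  tp <- timepoint_labels()
  df <- dplyr::left_join(object$features, tidy(object), by = "subject_id") |>
    tidyr::pivot_longer(dplyr::all_of(tp), names_to = "timepoint",
                        values_to = "value")
  df$timepoint <- factor(df$timepoint, levels = tp)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$timepoint, y = .data$value,
                                   group = .data$subject_id,
                                   colour = factor(.data$cluster))) +
    ggplot2::geom_line(alpha = 0.8) +
    ggplot2::geom_point(size = 1) +
    ggplot2::facet_wrap(~cluster, labeller = ggplot2::label_both) +
    ggplot2::labs(x = NULL, y = paste(object$scale, "score"), colour = "cluster",
                  title = sprintf("%s recovery trajectories (K = %d)",
                                  object$scale, object$k_selected)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none")
}

#' Plot the silhouette-by-K selection curve
#'
#' @param solution A [cluster_trajectories()] solution.
#' @return A ggplot object.
#' @export
plot_silhouette_curve <- function(solution) {
  stopifnot(inherits(solution, "cluster_solution"))
  ggplot2::ggplot(solution$silhouette_by_k,
                  ggplot2::aes(x = .data$k, y = .data$mean_silhouette)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = solution$k_selected, linetype = 2) +
    ggplot2::labs(x = "number of clusters K", y = "mean silhouette",
                  title = paste(solution$scale, "silhouette curve")) +
    ggplot2::theme_minimal()
}

#' Heatmap of per-cluster mean anomaly counts
#'
#' Tile map of [render_heatmap_table()] output: regions (split by laterality)
#' on the y-axis, clusters on the x-axis; hypoconnections plotted as negative
#' intensity (blue), hyperconnections positive (red).
#'
#' @param heatmap_table Output of [render_heatmap_table()].
#' @param direction `"hypo"`, `"hyper"` or `"both"` (hyper minus hypo).
#' @return A ggplot object.
#' @export
plot_anomaly_heatmap <- function(heatmap_table,
                                 direction = c("both", "hypo", "hyper")) {
  direction <- match.arg(direction)
  df <- heatmap_table
  df$value <- switch(direction,
    both = df$mean_hyper - df$mean_hypo,
    hypo = -df$mean_hypo,
    hyper = df$mean_hyper
  )
  df$row <- paste(df$laterality, df$region)
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$cluster), y = .data$row,
                                   fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "white", high = "red",
                                  midpoint = 0) +
    ggplot2::labs(x = "cluster", y = NULL, fill = "mean count\n(hyper - hypo)") +
    ggplot2::theme_minimal()
}
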