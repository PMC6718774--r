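#' Plot brightness traces
#'
#' One facet per ROI, brightness against frame; detected spike frames can be
#' overlaid as vertical marks.
#'
#' @param object A `trace_set` tibble.
#' @param spikes Optional `spike_set` tibble; spike frames are drawn as rug
#'   marks.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot trace_set
#' @export
autoplot.trace_set <- function(object, spikes = NULL, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$frame, y = .data$brightness)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~roi_id, scales = "free_y") +
    ggplot2::labs(x = "frame", y = "mean ROI brightness")
  if (!is.null(spikes)) {
    hits <- spikes[spikes$spike == 1L, ]
    if (nrow(hits)) {
      p <- p + ggplot2::geom_vline(data = hits,
                                   ggplot2::aes(xintercept = .data$frame),
                                   color = "red", alpha = 0.5, linewidth = 0.2)
    }
  }
  p
}

#' Plot a correlation matrix
#'
#' Tile plot of the pairwise cross-correlations at one lag, diverging from
#' -1 (blue) through 0 to +1 (red).
#'
#' @param object A `correlation_table` tibble.
#' @param lag Which lag to show (default 0).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot correlation_table
#' @export
autoplot.correlation_table <- function(object, lag = 0L, ...) {
  sub <- object[object$lag == lag, ]
  ggplot2::ggplot(sub, ggplot2::aes(x = factor(.data$roi_a),
                                    y = factor(.data$roi_b),
                                    fill = .data$correlation)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "white", high = "red",
                                  limits = c(-1, 1)) +
    ggplot2::labs(x = "ROI", y = "ROI",
                  title = sprintf("cross-correlation, lag %d", lag))
}

#' Plot the reconstructed communication network
#'
#' ROIs at their centroids; directed edges as arrows from leader to
#' follower, colored by correlation. Plotted in image coordinates (row axis
#' reversed so the origin is top-left, as in the footage).
#'
#' @param object A `calcium_network`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot calcium_network
#' @export
autoplot.calcium_network <- function(object, ...) {
  nodes <- object$nodes
  p <- ggplot2::ggplot(nodes, ggplot2::aes(x = .data$centroid_col,
                                           y = .data$centroid_row)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "col (px)", y = "row (px)")
  if (nrow(object$edges)) {
    seg <- dplyr::left_join(object$edges, nodes,
                            by = c(source_roi = "id")) |>
      dplyr::rename(x = "centroid_col", y = "centroid_row") |>
      dplyr::left_join(nodes, by = c(target_roi = "id")) |>
      dplyr::rename(xend = "centroid_col", yend = "centroid_row")
    p <- p + ggplot2::geom_segment(
      data = seg,
      ggplot2::aes(x = .data$x, y = .data$y, xend = .data$xend,
                   yend = .data$yend, color = .data$correlation),
      arrow = ggplot2::arrow(length = ggplot2::unit(2, "mm")),
      linewidth = 0.5)
  }
  p
}

#' Spatiotemporal activity map
#'
#' Each spiking ROI drawn as a circle at its centroid, sized by spike count
#' and colored by the average spike frame (red = early, blue = late).
#'
#' @param map_data Output of [spatiotemporal_map_data()].
#' @return A ggplot object.
#' @export
plot_spatiotemporal_map <- function(map_data) {
  ggplot2::ggplot(map_data, ggplot2::aes(x = .data$centroid_col,
                                         y = .data$centroid_row,
                                         size = .data$spike_count,
                                         color = .data$n_avg)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::scale_color_gradient(low = "red", high = "blue") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "col (px)", y = "row (px)",
                  size = "spikes", color = "avg frame")
}

#' Activity heat map over the culture
#'
#' ROI centroids colored by the normalized activity value from
#' [heatmap_values()].
#'
#' @param values Tibble `(roi_id, value)` from [heatmap_values()].
#' @param rois The matching [roi_set()].
#' @return A ggplot object.
#' @export
plot_activity_map <- function(values, rois) {
  df <- dplyr::inner_join(tibble::as_tibble(rois), values,
                          by = c(id = "roi_id"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$centroid_col,
                                   y = .data$centroid_row,
                                   color = .data$value)) +
    ggplot2::geom_point(size = 3) +
    ggplot2::scale_color_viridis_c(limits = c(0, 1)) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "col (px)", y = "row (px)", color = "activity")
}
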