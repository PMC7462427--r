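# ggplot2 figures for the main result types. Figures are advisory; the
# numeric tables are the contract.

#' Plot a resolution-parameter sweep surface
#'
#' Tile map of `Qdiff = Qobs - Qnull` over the (gamma, omega) grid, with
#' the selected scale marked.
#'
#' @param object A `q_surface`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.q_surface <- function(object, ...) {
  sel <- select_scale(object, quiet = TRUE)
  ggplot2::ggplot(object$table,
                  ggplot2::aes(x = factor(.data$gamma),
                               y = factor(.data$omega),
                               fill = .data$q_diff)) +
    ggplot2::geom_tile() +
    ggplot2::geom_point(data = sel,
                        ggplot2::aes(x = factor(.data$gamma),
                                     y = factor(.data$omega)),
                        inherit.aes = FALSE, shape = 4, size = 3) +
    ggplot2::scale_fill_viridis_c(name = "Q - Qnull") +
    ggplot2::labs(x = "structural resolution gamma",
                  y = "temporal resolution omega",
                  title = "Null-calibrated modularity surface")
}

#' Plot community labels over time
#'
#' Layer-by-node tile map of a multilayer partition, one color per
#' community.
#'
#' @param object A `multilayer_partition`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.multilayer_partition <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(x = .data$layer, y = .data$node,
                               fill = factor(.data$community))) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_brewer(palette = "Set2", name = "community") +
    ggplot2::labs(x = "layer (time window)", y = "node",
                  title = "Dynamic community structure")
}

#' Plot mean connectivity over the peri-stimulus epoch
#'
#' Mean off-diagonal dwPLI per window, with the pulse marked.
#'
#' @param object A `connectivity_series`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.connectivity_series <- function(object, ...) {
  n <- dim(object$layers)[1]
  means <- vapply(seq_len(dim(object$layers)[3]), function(l) {
    A <- object$layers[, , l]
    mean(A[upper.tri(A)])
  }, numeric(1))
  df <- tibble::tibble(center_s = object$manifest$center_s, mean_dwpli = means)
  ggplot2::ggplot(df, ggplot2::aes(.data$center_s, .data$mean_dwpli)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed") +
    ggplot2::labs(x = "time from pulse (s)", y = "mean dwPLI",
                  title = object$label %||% "connectivity")
}

#' Node allegiance change versus distance from the stimulation site
#'
#' Scatter of each node's mean absolute allegiance change against its
#' distance from the site, with the percentile selection threshold as a
#' horizontal dotted line.
#'
#' @param object A `reconfig_report`.
#' @param band Band label to plot (default: first).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.reconfig_report <- function(object, band = NULL, ...) {
  nm <- object$node_metrics
  band <- band %||% nm$band[1]
  df <- nm |>
    dplyr::filter(.data$band == !!band) |>
    dplyr::group_by(.data$node) |>
    dplyr::summarise(dist_m = mean(.data$dist_m),
                     score = mean(.data$abs_d_alleg),
                     community = .data$community[1], .groups = "drop")
  ggplot2::ggplot(df, ggplot2::aes(.data$dist_m, .data$score,
                                   color = factor(.data$community))) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = object$percentile_threshold,
                        linetype = "dotted") +
    ggplot2::scale_color_brewer(palette = "Set2", name = "community") +
    ggplot2::labs(x = "distance from stimulation site (m)",
                  y = "mean |d allegiance|",
                  title = sprintf("Node reconfiguration vs distance (%s)", band))
}

#' Edge-change heatmap
#'
#' Matrix heatmap of the subject-mean per-edge connectivity change
#' (post minus pre) for one band.
#'
#' @param report A `reconfig_report`.
#' @param band Band label (default: first).
#' @return A ggplot.
#' @export
plot_edge_change <- function(report, band = NULL) {
  ec <- report$edge_changes
  band <- band %||% ec$band[1]
  df <- ec |>
    dplyr::filter(.data$band == !!band) |>
    dplyr::group_by(.data$node_a, .data$node_b) |>
    dplyr::summarise(change = mean(.data$change), .groups = "drop")
  df <- dplyr::bind_rows(df,
                         dplyr::rename(df, node_a = "node_b",
                                       node_b = "node_a"))
  ggplot2::ggplot(df, ggplot2::aes(.data$node_a, .data$node_b,
                                   fill = .data$change)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(name = "d dwPLI") +
    ggplot2::labs(x = "node", y = "node",
                  title = sprintf("Mean edge change (%s)", band))
}
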