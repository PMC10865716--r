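#' Plot priority access score trajectories
#'
#' One line per mouse; territorial trajectories climb, non-territorial
#' ones sink, and the zero line separates final statuses.
#'
#' @param object An `rfid_pas` tibble from [priority_access()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot rfid_pas
#' @export
autoplot.rfid_pas <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$day, y = .data$pas,
                               group = .data$mouse_id,
                               colour = .data$mouse_id)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Trial day", y = "Priority access score",
                  colour = "Mouse") +
    ggplot2::theme_minimal()
}

#' Plot a daily social network
#'
#' Circular layout; edge width encodes the Simple Ratio Index, point
#' size the node strength.
#'
#' @param object An `rfid_network` from [build_daily_network()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot rfid_network
#' @export
autoplot.rfid_network <- function(object, ...) {
  n <- length(object$nodes)
  theta <- 2 * pi * (seq_len(n) - 1) / max(n, 1)
  layout <- tibble::tibble(mouse_id = object$nodes,
                           x = cos(theta), y = sin(theta))
  edges <- tidy(object)
  if (nrow(edges) > 0L) {
    edges <- edges |>
      dplyr::left_join(layout, by = c(mouse_a = "mouse_id")) |>
      dplyr::rename(xa = "x", ya = "y") |>
      dplyr::left_join(layout, by = c(mouse_b = "mouse_id")) |>
      dplyr::rename(xb = "x", yb = "y")
  }
  nodes <- dplyr::left_join(layout, object$node_metrics, by = "mouse_id")
  p <- ggplot2::ggplot()
  if (nrow(edges) > 0L) {
    p <- p + ggplot2::geom_segment(
      data = edges,
      ggplot2::aes(x = .data$xa, y = .data$ya, xend = .data$xb,
                   yend = .data$yb, linewidth = .data$sri),
      colour = "grey60", alpha = 0.7)
  }
  p +
    ggplot2::geom_point(data = nodes,
                        ggplot2::aes(x = .data$x, y = .data$y,
                                     size = .data$strength)) +
    ggplot2::geom_text(data = nodes,
                       ggplot2::aes(x = 1.12 * .data$x, y = 1.12 * .data$y,
                                    label = .data$mouse_id), size = 3) +
    ggplot2::scale_linewidth(range = c(0.2, 2)) +
    ggplot2::coord_equal() +
    ggplot2::labs(title = paste("Day", object$day),
                  size = "Strength", linewidth = "SRI") +
    ggplot2::theme_void()
}

#' Zone-use heatmap of read counts
#'
#' Mice by day, faceted over zones, with fill showing each mouse's read
#' concentration — warm cells reveal zone monopolization.
#'
#' @param reads Read tibble.
#' @param config An [enclosure_config()].
#' @return A ggplot.
#' @export
plot_zone_use <- function(reads, config = enclosure_config()) {
  counts <- reads |>
    dplyr::mutate(day = assign_day(.data$t, config)) |>
    dplyr::count(.data$mouse_id, .data$zone_id, .data$day)
  ggplot2::ggplot(counts,
                  ggplot2::aes(x = .data$day, y = .data$mouse_id,
                               fill = .data$n)) +
    ggplot2::geom_tile() +
    ggplot2::facet_wrap(ggplot2::vars(.data$zone_id), nrow = 2) +
    ggplot2::scale_fill_viridis_c(option = "inferno", trans = "log10") +
    ggplot2::labs(x = "Trial day", y = NULL, fill = "Reads") +
    ggplot2::theme_minimal()
}
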