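# Diagnostic ggplot2 views of the two network types. These are quick
# looks for interactive work; publication-grade layouts are delegated to
# Cytoscape via the GraphML/SIF exports.

network_layout <- function(graph, seed = 42L) {
  xy <- withr::with_seed(seed, igraph::layout_with_fr(graph))
  tibble::tibble(
    name = igraph::V(graph)$name,
    x = xy[, 1L],
    y = xy[, 2L]
  )
}

#' Plot an AC network
#'
#' Nodes are AC compounds colored by role (highly potent partner in all
#' cliffs, weakly potent in all, or mixed), edges are MMP-cliffs.
#'
#' @param object An `ac_network`.
#' @param seed Layout seed (default 42).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ac_network <- function(object, seed = 42L, ...) {
  lay <- network_layout(object$graph, seed)
  nodes <- dplyr::left_join(object$nodes, lay, by = c(compound_id = "name"))
  edges <- object$edges |>
    dplyr::left_join(lay, by = c(high_id = "name")) |>
    dplyr::rename(x_from = "x", y_from = "y") |>
    dplyr::left_join(lay, by = c(low_id = "name")) |>
    dplyr::rename(x_to = "x", y_to = "y")
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = edges,
      ggplot2::aes(x = .data$x_from, y = .data$y_from, xend = .data$x_to, yend = .data$y_to),
      color = "grey60", linewidth = 0.3
    ) +
    ggplot2::geom_point(
      data = nodes,
      ggplot2::aes(x = .data$x, y = .data$y, color = .data$role),
      size = 2
    ) +
    ggplot2::scale_color_manual(
      values = c(high = "#2e7d32", low = "#c62828", mixed = "#f9a825")
    ) +
    ggplot2::theme_void() +
    ggplot2::labs(color = "AC role", title = "Activity cliff network")
}

#' Plot a reduced MMS network
#'
#' Nodes are matching molecular series, sized by member count, filled by
#' the largest member potency, with border thickness proportional to the
#' series' AC propensity; edges are MMSP relationships.
#'
#' @param object A `reduced_network`.
#' @param seed Layout seed (default 42).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.reduced_network <- function(object, seed = 42L, ...) {
  lay <- network_layout(object$graph, seed)
  nodes <- dplyr::left_join(
    tidy.reduced_network(object, "nodes"), lay,
    by = c(mms_id = "name")
  )
  p <- ggplot2::ggplot()
  if (nrow(object$edges)) {
    edges <- object$edges |>
      dplyr::left_join(lay, by = c(mms_a = "name")) |>
      dplyr::rename(x_from = "x", y_from = "y") |>
      dplyr::left_join(lay, by = c(mms_b = "name")) |>
      dplyr::rename(x_to = "x", y_to = "y")
    p <- p + ggplot2::geom_segment(
      data = edges,
      ggplot2::aes(x = .data$x_from, y = .data$y_from, xend = .data$x_to, yend = .data$y_to),
      color = "grey60", linewidth = 0.4
    )
  }
  p +
    ggplot2::geom_point(
      data = nodes,
      ggplot2::aes(
        x = .data$x, y = .data$y, size = .data$n_members,
        fill = .data$max_pki, stroke = 0.5 + .data$ac_propensity / 25
      ),
      shape = 21, color = "black"
    ) +
    ggplot2::scale_fill_gradient(low = "#fff3e0", high = "#b71c1c") +
    ggplot2::theme_void() +
    ggplot2::labs(
      size = "Members", fill = "Max pKi",
      title = "Reduced AC network (MMS nodes, MMSP edges)"
    )
}
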