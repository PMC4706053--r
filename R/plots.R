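#' Plot the per-kind composition of a hetnet
#'
#' @param object A [hetnet()].
#' @param ... Unused.
#' @return A ggplot: node and edge counts per kind.
#' @method autoplot hetnet
#' @export
autoplot.hetnet <- function(object, ...) {
  cnt <- hetnet_counts(object) |> filter(n > 0)
  ggplot2::ggplot(cnt, ggplot2::aes(x = kind, y = n, fill = element)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_wrap(~element, scales = "free") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "count", fill = NULL,
                  title = "Hetnet composition") +
    ggplot2::theme_minimal()
}

#' Plot a topology report
#'
#' Degree distribution, neighborhood connectivity and the shortest-path
#' length distribution of the largest component, as the usual three panels.
#'
#' @param object A [topology_report()].
#' @param ... Unused.
#' @return A ggplot (facetted across the three statistics).
#' @method autoplot topology_report
#' @export
autoplot.topology_report <- function(object, ...) {
  panels <- bind_rows(
    object$degree_distribution |>
      transmute(x = degree, y = as.double(n_nodes),
                panel = "degree distribution"),
    object$neighborhood_connectivity |>
      transmute(x = degree, y = mean_neighbor_degree,
                panel = "neighborhood connectivity"),
    object$path_length_distribution |>
      transmute(x = distance, y = n_pairs, panel = "shortest path lengths")
  )
  ggplot2::ggplot(panels, ggplot2::aes(x = x, y = y)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(alpha = 0.4) +
    ggplot2::facet_wrap(~panel, scales = "free") +
    ggplot2::labs(x = NULL, y = NULL, title = "Network topology") +
    ggplot2::theme_minimal()
}

#' Plot a similarity network's weight spectrum
#'
#' @param object A [similarity_projection()] result.
#' @param ... Unused.
#' @return A ggplot: histogram of shared-neighbor edge weights.
#' @method autoplot similarity_network
#' @export
autoplot.similarity_network <- function(object, ...) {
  w <- tibble(weight = object$edges$weight %||% integer())
  ggplot2::ggplot(w, ggplot2::aes(x = weight)) +
    ggplot2::geom_bar() +
    ggplot2::labs(x = "shared neighbors", y = "edges",
                  title = "Similarity-edge weights") +
    ggplot2::theme_minimal()
}

#' Plot degree-proportional opacity for one node kind
#'
#' Mirrors the darker-squares-for-shared-drugs display: each node of the
#' kind is a tile whose alpha is its degree over the kind's maximum degree.
#'
#' @param net A [hetnet()].
#' @param kind Node kind to display (e.g. `"drug"`).
#' @return A ggplot.
#' @export
plot_degree_opacity <- function(net, kind) {
  op <- degree_opacity(net, kind)
  ggplot2::ggplot(op, ggplot2::aes(x = stats::reorder(id, -degree),
                                   y = 1, alpha = opacity)) +
    ggplot2::geom_tile(fill = "steelblue") +
    ggplot2::scale_alpha_identity() +
    ggplot2::labs(x = kind, y = NULL,
                  title = "Degree-proportional opacity") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5),
                   axis.text.y = ggplot2::element_blank())
}
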