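# ggplot2 views of the result objects. These are thin visual layers over
# the exported tables; all numbers come from the corresponding tidy()
# output.

#' Plot a weighted network
#'
#' Nodes on a circle (grouped by community when available), edges drawn
#' with width proportional to `|weight|`, positive edges solid and
#' negative edges dashed.
#'
#' @param object A `weighted_network`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.weighted_network <- function(object, ...) {
  nodes <- object$nodes
  comm <- object$communities %||% setNames(rep("all", length(nodes)), nodes)
  ord <- order(comm[nodes])
  theta <- seq(0, 2 * pi, length.out = length(nodes) + 1)[seq_along(nodes)]
  pos <- tibble::tibble(node = nodes[ord], x = cos(theta), y = sin(theta),
                        community = unname(comm[nodes[ord]]))
  edges <- tidy(object) |>
    dplyr::left_join(pos, by = c(node_i = "node")) |>
    dplyr::left_join(pos, by = c(node_j = "node"), suffix = c("", "_j"))
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = edges,
      ggplot2::aes(x = .data$x, y = .data$y, xend = .data$x_j,
                   yend = .data$y_j, linewidth = abs(.data$weight),
                   linetype = .data$weight < 0),
      colour = "grey40", show.legend = FALSE) +
    ggplot2::geom_point(data = pos,
                        ggplot2::aes(.data$x, .data$y,
                                     colour = .data$community), size = 6) +
    ggplot2::geom_text(data = pos,
                       ggplot2::aes(.data$x * 1.12, .data$y * 1.12,
                                    label = .data$node), size = 2.8) +
    ggplot2::scale_linewidth(range = c(0.2, 2)) +
    ggplot2::coord_equal(clip = "off") +
    ggplot2::theme_void()
}

#' Plot a centrality table
#'
#' Dot chart of z-scored centrality indices, ordered by expected
#' influence.
#'
#' @param cent A tibble from [centrality()].
#' @param indices Index columns to show.
#' @return A ggplot object.
#' @export
plot_centrality <- function(cent, indices = c("z_expected_influence",
                                              "z_strength",
                                              "z_bridge_expected_influence")) {
  indices <- intersect(indices, names(cent))
  long <- tidyr::pivot_longer(cent[c("node", indices)],
                              dplyr::all_of(indices),
                              names_to = "index", values_to = "z")
  long$node <- factor(long$node,
                      levels = cent$node[order(cent$expected_influence)])
  ggplot2::ggplot(long, ggplot2::aes(.data$z, .data$node)) +
    ggplot2::geom_point() +
    ggplot2::geom_path(ggplot2::aes(group = .data$index)) +
    ggplot2::facet_wrap(~index, nrow = 1) +
    ggplot2::labs(x = "z-score", y = NULL)
}

#' Plot bootstrap edge-weight intervals
#'
#' Sample edge weights (points) with their bootstrap 95% quantile
#' intervals (segments), ordered by sample weight.
#'
#' @param object A `network_bootstrap`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.network_bootstrap <- function(object, ...) {
  edges <- dplyr::filter(object$summary, .data$type == "edge")
  edges$statistic <- factor(edges$statistic,
                            levels = edges$statistic[order(edges$sample)])
  ggplot2::ggplot(edges, ggplot2::aes(y = .data$statistic)) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$ci_lower,
                                       xend = .data$ci_upper,
                                       yend = .data$statistic),
                          colour = "grey60") +
    ggplot2::geom_point(ggplot2::aes(x = .data$sample), size = 0.8) +
    ggplot2::labs(x = "edge weight", y = NULL) +
    ggplot2::theme(axis.text.y = ggplot2::element_blank())
}

#' Plot case-dropping stability curves
#'
#' Mean subset-vs-full centrality correlation against the dropped
#' proportion, with a 2.5-97.5% quantile ribbon, one line per index. The
#' conventional 0.7 correlation threshold is marked.
#'
#' @param object A `case_drop` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.case_drop <- function(object, ...) {
  curves <- tidy(object)
  ggplot2::ggplot(curves, ggplot2::aes(.data$proportion,
                                       .data$mean_correlation,
                                       colour = .data$index,
                                       fill = .data$index)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$q025, ymax = .data$q975),
                         alpha = 0.15, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 0.7, linetype = 2) +
    ggplot2::labs(x = "proportion of cases dropped",
                  y = "correlation with full sample")
}

#' Plot a predictive-betweenness bootstrap
#'
#' Full-sample values as white dots over the bootstrap 2.5-97.5% interval
#' as black lines, one row per node.
#'
#' @param object A `pb_bootstrap`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pb_bootstrap <- function(object, ...) {
  s <- object$summary
  s$node <- factor(s$node, levels = s$node[order(s$boot_median)])
  ggplot2::ggplot(s, ggplot2::aes(y = .data$node)) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$ci_lower,
                                       xend = .data$ci_upper,
                                       yend = .data$node), colour = "black") +
    ggplot2::geom_point(ggplot2::aes(x = .data$sample), shape = 21,
                        fill = "white", size = 2) +
    ggplot2::labs(x = paste0("predictive betweenness (focal = ",
                             object$focal, ")"), y = NULL)
}

#' Plot a flow view
#'
#' Direct neighbours of the focal node ordered by absolute weight, signed
#' weights as bars; indirect nodes listed separately.
#'
#' @param object A `flow_view`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.flow_view <- function(object, ...) {
  direct <- dplyr::filter(tibble::as_tibble(object),
                          .data$relation == "direct")
  direct$node <- factor(direct$node,
                        levels = rev(direct$node))
  ggplot2::ggplot(direct, ggplot2::aes(.data$weight, .data$node,
                                       fill = .data$weight > 0)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::labs(x = paste0("edge weight with ", attr(object, "focal")),
                  y = NULL)
}
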