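# Node-importance measures for weighted partial-correlation networks:
# strength, (one-step) expected influence, bridge expected influence across
# supplied communities, weighted shortest-path betweenness on distances
# 1/|w|, focal-node predictive betweenness, the focal "flow" view, and
# ranked edge lists.

net_weights <- function(net) {
  if (inherits(net, "weighted_network")) return(net$weights)
  stopifnot(isSymmetric(unname(net), tol = 1e-8))
  if (is.null(colnames(net))) {
    dimnames(net) <- rep(list(paste0("V", seq_len(ncol(net)))), 2)
  }
  net
}

net_igraph <- function(W) {
  g <- igraph::graph_from_adjacency_matrix(abs(W), mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  # shortest-path distance convention: d_ij = 1 / |w_ij|
  igraph::E(g)$weight <- 1 / igraph::E(g)$weight
  g
}

#' Expected influence and strength
#'
#' One-step expected influence is the signed sum of a node's edge weights;
#' strength is the absolute sum. The two coincide on all-positive networks.
#'
#' @param net A `weighted_network` or symmetric weight matrix.
#' @return Tibble with `node`, `expected_influence`, `strength`.
#' @export
expected_influence <- function(net) {
  W <- net_weights(net)
  tibble::tibble(node = colnames(W),
                 expected_influence = unname(rowSums(W)),
                 strength = unname(rowSums(abs(W))))
}

#' Bridge expected influence
#'
#' Signed sum of each node's edge weights to nodes outside its own
#' community.
#'
#' @param net A `weighted_network` or weight matrix.
#' @param communities Named community labels; taken from the network when
#'   omitted.
#' @return Tibble with `node`, `community`, `bridge_expected_influence`.
#' @export
bridge_expected_influence <- function(net, communities = NULL) {
  W <- net_weights(net)
  communities <- communities %||%
    (if (inherits(net, "weighted_network")) net$communities)
  nodes <- colnames(W)
  missing_c <- nodes[!nodes %in% names(communities)]
  if (length(missing_c)) {
    abort(paste0("No community label for node(s): ",
                 paste(missing_c, collapse = ", ")))
  }
  cross <- outer(communities[nodes], communities[nodes], `!=`)
  tibble::tibble(node = nodes,
                 community = unname(communities[nodes]),
                 bridge_expected_influence = unname(rowSums(W * cross)))
}

#' Weighted shortest-path betweenness
#'
#' Shortest paths are computed on distances `d_ij = 1/|w_ij|` over non-zero
#' edges. A node's betweenness is the number of unordered node pairs whose
#' shortest path passes through it, with ties in path length split
#' fractionally across equal-length paths. Disconnected pairs contribute
#' nothing.
#'
#' @param net A `weighted_network` or weight matrix.
#' @return Tibble with `node`, `betweenness`.
#' @export
node_betweenness <- function(net) {
  W <- net_weights(net)
  g <- net_igraph(W)
  b <- igraph::betweenness(g, directed = FALSE)
  tibble::tibble(node = colnames(W), betweenness = unname(b))
}

#' Focal-node predictive betweenness
#'
#' For a designated focal node, counts for every other node `v` how often
#' `v` lies on the shortest paths between the focal node and each remaining
#' node (same `1/|w|` distances and fractional tie handling as
#' [node_betweenness()]).
#'
#' @param net A `weighted_network` or weight matrix.
#' @param focal Name of the focal node.
#' @return Tibble with `node`, `predictive_betweenness` (NA for the focal
#'   node itself).
#' @export
predictive_betweenness <- function(net, focal) {
  W <- net_weights(net)
  nodes <- colnames(W)
  if (!focal %in% nodes) abort(paste0("Focal node not found: ", focal))
  g <- net_igraph(W)
  score <- setNames(numeric(length(nodes)), nodes)
  targets <- setdiff(nodes, focal)
  for (t in targets) {
    # unreachable targets contribute nothing (igraph warns; we document)
    sp <- suppressWarnings(
      igraph::all_shortest_paths(g, from = focal, to = t)$res)
    if (!length(sp)) next
    share <- 1 / length(sp)
    for (pth in sp) {
      inner <- setdiff(names(pth), c(focal, t))
      if (length(inner)) score[inner] <- score[inner] + share
    }
  }
  score[focal] <- NA_real_
  tibble::tibble(node = nodes, predictive_betweenness = unname(score))
}

#' Full centrality table
#'
#' Combines strength, expected influence, bridge expected influence (when
#' community labels are available) and betweenness, with z-scored variants
#' of each (columns prefixed `z_`).
#'
#' @param net A `weighted_network` or weight matrix.
#' @param communities Optional named community labels.
#' @return A tibble, one row per node.
#' @examples
#' W <- matrix(0, 3, 3, dimnames = rep(list(c("A", "B", "C")), 2))
#' W["A", "B"] <- W["B", "A"] <- 0.3
#' W["B", "C"] <- W["C", "B"] <- -0.2
#' centrality(W)
#' @export
centrality <- function(net, communities = NULL) {
  communities <- communities %||%
    (if (inherits(net, "weighted_network")) net$communities)
  out <- dplyr::left_join(expected_influence(net), node_betweenness(net),
                          by = "node")
  if (!is.null(communities)) {
    out <- dplyr::left_join(bridge_expected_influence(net, communities), out,
                            by = "node")
  }
  zs <- function(x) if (sd(x) == 0) rep(0, length(x)) else
    (x - mean(x)) / sd(x)
  numcols <- names(out)[vapply(out, is.numeric, logical(1))]
  for (cl in numcols) out[[paste0("z_", cl)]] <- zs(out[[cl]])
  out
}

#' Flow view of a focal node
#'
#' Splits the network relative to a focal node: its direct neighbours with
#' signed weights, ordered by `|weight|` descending, plus the nodes
#' reachable only indirectly and the unreachable ones.
#'
#' @param net A `weighted_network` or weight matrix.
#' @param focal Focal node name.
#' @return Object of class `flow_view`: tibble with `node`, `relation`
#'   (`direct` / `indirect` / `unreachable`), `weight` (NA unless direct),
#'   plus attribute `focal`.
#' @export
flow_edges <- function(net, focal) {
  W <- net_weights(net)
  nodes <- colnames(W)
  if (!focal %in% nodes) abort(paste0("Focal node not found: ", focal))
  w <- W[focal, setdiff(nodes, focal)]
  direct <- names(w)[w != 0]
  direct <- direct[order(-abs(w[direct]), direct)]
  g <- net_igraph(W)
  d <- igraph::distances(g, v = focal)[1, ]
  reach <- names(d)[is.finite(d) & d > 0]
  indirect <- setdiff(reach, direct)
  unreachable <- setdiff(nodes, c(focal, direct, indirect))
  out <- tibble::tibble(
    node = c(direct, indirect, unreachable),
    relation = c(rep("direct", length(direct)),
                 rep("indirect", length(indirect)),
                 rep("unreachable", length(unreachable))),
    weight = c(unname(w[direct]), rep(NA_real_, length(indirect) +
                                        length(unreachable)))
  )
  structure(out, focal = focal, class = c("flow_view", class(out)))
}

#' Strongest edges
#'
#' Top-`k` edges by absolute weight; ties broken by the lexicographic
#' (node_i, node_j) pair. Returns all edges when `k` exceeds the edge count.
#'
#' @param net A `weighted_network` or weight matrix.
#' @param k Number of edges (default all).
#' @return Tibble with `node_i`, `node_j`, `weight`, ordered by `|weight|`
#'   descending.
#' @export
strongest_edges <- function(net, k = Inf) {
  W <- net_weights(net)
  nodes <- colnames(W)
  idx <- which(upper.tri(W) & W != 0, arr.ind = TRUE)
  out <- tibble::tibble(
    node_i = nodes[idx[, 1]], node_j = nodes[idx[, 2]],
    weight = W[idx]
  )
  out <- dplyr::arrange(out, dplyr::desc(abs(.data$weight)),
                        .data$node_i, .data$node_j)
  head(out, n = min(k, nrow(out)))
}
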