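# Independent oracles and fixture builders shared across the suite.

# random sparse symmetric weight matrix with named nodes
random_weights <- function(p, seed, density = 0.5, allow_negative = TRUE) {
  set.seed(seed)
  W <- matrix(0, p, p, dimnames = rep(list(LETTERS[seq_len(p)]), 2))
  idx <- which(upper.tri(W), arr.ind = TRUE)
  on <- runif(nrow(idx)) < density
  w <- runif(sum(on), 0.05, 0.6)
  if (allow_negative) w <- w * sample(c(-1, 1), sum(on), replace = TRUE)
  W[idx[on, , drop = FALSE]] <- w
  W[lower.tri(W)] <- t(W)[lower.tri(W)]
  W
}

# all simple paths between two nodes, by depth-first enumeration
enumerate_paths <- function(W, from, to) {
  nodes <- colnames(W)
  out <- list()
  walk <- function(path) {
    last <- path[length(path)]
    if (last == to) {
      out[[length(out) + 1]] <<- path
      return(invisible())
    }
    nb <- nodes[W[last, ] != 0]
    for (v in setdiff(nb, path)) walk(c(path, v))
  }
  walk(from)
  out
}

path_length <- function(W, path) {
  if (length(path) < 2) return(0)
  sum(1 / abs(W[cbind(path[-length(path)], path[-1])]))
}

# brute-force weighted betweenness with fractional credit for tied
# shortest paths; distances are 1/|w|
brute_betweenness <- function(W) {
  nodes <- colnames(W)
  score <- setNames(numeric(length(nodes)), nodes)
  prs <- utils::combn(nodes, 2)
  for (k in seq_len(ncol(prs))) {
    paths <- enumerate_paths(W, prs[1, k], prs[2, k])
    if (!length(paths)) next
    lens <- vapply(paths, function(p) path_length(W, p), numeric(1))
    best <- which(lens <= min(lens) + 1e-12)
    for (b in best) {
      inner <- setdiff(paths[[b]], prs[, k])
      if (length(inner)) score[inner] <- score[inner] + 1 / length(best)
    }
  }
  score
}

# brute-force focal-anchored predictive betweenness
brute_predictive <- function(W, focal) {
  nodes <- colnames(W)
  score <- setNames(numeric(length(nodes)), nodes)
  for (t in setdiff(nodes, focal)) {
    paths <- enumerate_paths(W, focal, t)
    if (!length(paths)) next
    lens <- vapply(paths, function(p) path_length(W, p), numeric(1))
    best <- which(lens <= min(lens) + 1e-12)
    for (b in best) {
      inner <- setdiff(paths[[b]], c(focal, t))
      if (length(inner)) score[inner] <- score[inner] + 1 / length(best)
    }
  }
  score[focal] <- NA_real_
  score
}

# toy weight matrix from an edge list: edges as list(c("A","B",w), ...)
toy_net <- function(..., nodes = NULL) {
  edges <- list(...)
  nodes <- nodes %||% unique(unlist(lapply(edges, function(e) e[1:2])))
  W <- matrix(0, length(nodes), length(nodes),
              dimnames = list(nodes, nodes))
  for (e in edges) {
    W[e[[1]], e[[2]]] <- as.numeric(e[[3]])
    W[e[[2]], e[[1]]] <- as.numeric(e[[3]])
  }
  W
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# latent-Gaussian ordinal sample with given correlation and thresholds
ordinal_pair <- function(n, rho, cuts_x, cuts_y, seed) {
  set.seed(seed)
  z1 <- rnorm(n)
  z2 <- rho * z1 + sqrt(1 - rho^2) * rnorm(n)
  list(x = findInterval(z1, cuts_x), y = findInterval(z2, cuts_y))
}
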