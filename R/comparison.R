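# Permutation network comparison test between two subgroups: invariance of
# the network structure (maximum absolute edge-weight difference, M) and of
# global strength (S), plus per-edge permutation tests with multiplicity
# adjustment. Group labels are permuted over the pooled rows, preserving
# group sizes, and both networks are re-estimated per permutation.

#' Global strength of a network
#'
#' Sum of absolute edge weights over unordered node pairs.
#'
#' @param net A `weighted_network` or symmetric weight matrix.
#' @return Numeric scalar.
#' @export
global_strength <- function(net) {
  W <- net_weights(net)
  sum(abs(W[upper.tri(W)]))
}

nct_stats <- function(net1, net2) {
  d <- abs(net1$weights - net2$weights)
  list(M = max(d[upper.tri(d)]),
       S = abs(global_strength(net1) - global_strength(net2)),
       edge_diff = abs(net1$weights - net2$weights))
}

#' Permutation network comparison test
#'
#' Estimates a network per group, then compares them with permutation
#' tests: `M`, the maximum absolute edge-weight difference (network
#' structure invariance), and `S`, the absolute global-strength difference.
#' P-values use the add-one estimator `(1 + #{perm >= obs}) / (1 + n_perm)`.
#' Per-edge differences are tested for every edge non-zero in at least one
#' observed network, with `p.adjust` multiplicity correction.
#'
#' @param data Cohort data frame containing the grouping column.
#' @param group Name of a two-level grouping column (e.g. `"gender"`).
#' @param n_perm Number of permutations (default 1000).
#' @param seed Master seed.
#' @param adjust Multiplicity adjustment for per-edge tests
#'   (see [stats::p.adjust()]; default `"holm"`).
#' @param estimator Function `data -> weighted_network`; defaults to the
#'   standard pipeline ([mixed_cor()] + [ebic_glasso()]).
#' @param ... Passed to the default estimator.
#' @return Object of class `nct_result`: observed `M` and `S`, per-group
#'   global strengths, `p_structure`, `p_strength`, `edge_tests` tibble,
#'   permutation null vectors, `n_perm`, `seed`.
#' @export
nct <- function(data, group, n_perm = 1000, seed = 1, adjust = "holm",
                estimator = NULL, ...) {
  if (!group %in% names(data)) abort(paste0("Grouping column not found: ",
                                            group))
  g <- data[[group]]
  lev <- sort(unique(as.character(g)))
  if (length(lev) != 2) abort("Grouping column must have exactly two levels.")
  cols <- setdiff(names(data), group)
  types <- (cohort_types(data) %||% infer_types(data, cols))[cols]
  estimator <- estimator %||%
    default_estimator(types = types,
                      communities = cohort_communities(data), ...)
  d1 <- data[g == lev[1], cols, drop = FALSE]
  d2 <- data[g == lev[2], cols, drop = FALSE]
  p <- length(cols)
  if (min(nrow(d1), nrow(d2)) <= p) {
    warn("A group has n <= p; network estimates will be unstable.")
  }

  net1 <- estimator(d1)
  net2 <- estimator(d2)
  obs <- nct_stats(net1, net2)
  track <- net1$weights != 0 | net2$weights != 0
  track <- track & upper.tri(track)

  # pooled rows keep the input order, so with equal group sizes the
  # permutation draws (and hence the p-values) are invariant to swapping
  # the two group labels
  pooled <- data[cols]
  n1 <- nrow(d1)
  n <- nrow(pooled)
  seeds <- replicate_seeds(seed, n_perm)
  null_M <- null_S <- numeric(n_perm)
  exceed_edges <- matrix(0, nrow(net1$weights), ncol(net1$weights))
  failed <- 0L
  for (b in seq_len(n_perm)) {
    set.seed(seeds[b])
    idx1 <- sample.int(n, n1, replace = FALSE)
    r <- tryCatch({
      p1 <- estimator(pooled[idx1, , drop = FALSE])
      p2 <- estimator(pooled[-idx1, , drop = FALSE])
      nct_stats(p1, p2)
    }, error = function(e) NULL)
    if (is.null(r)) {
      failed <- failed + 1L
      null_M[b] <- NA
      null_S[b] <- NA
      next
    }
    null_M[b] <- r$M
    null_S[b] <- r$S
    exceed_edges <- exceed_edges + (r$edge_diff >= obs$edge_diff)
  }
  ok <- sum(!is.na(null_M))
  p_structure <- (1 + sum(null_M >= obs$M, na.rm = TRUE)) / (1 + ok)
  p_strength <- (1 + sum(null_S >= obs$S, na.rm = TRUE)) / (1 + ok)

  idx <- which(track, arr.ind = TRUE)
  edge_tests <- tibble::tibble(
    node_i = net1$nodes[idx[, 1]], node_j = net1$nodes[idx[, 2]],
    weight_1 = net1$weights[idx], weight_2 = net2$weights[idx],
    p = (1 + exceed_edges[idx]) / (1 + ok)
  )
  edge_tests$p_adj <- p.adjust(edge_tests$p, method = adjust)

  structure(
    list(M = obs$M, S = obs$S,
         strengths = setNames(c(global_strength(net1),
                                global_strength(net2)), lev),
         p_structure = p_structure, p_strength = p_strength,
         edge_tests = edge_tests, networks = list(net1, net2),
         null_M = null_M, null_S = null_S, n_perm = n_perm,
         failed = failed, groups = lev, adjust = adjust, seed = seed),
    class = "nct_result"
  )
}

#' @export
print.nct_result <- function(x, ...) {
  cat("Network comparison test (", x$groups[1], " vs ", x$groups[2], ", ",
      x$n_perm, " permutations)\n", sep = "")
  cat(sprintf("  structure:       M = %.3f, p = %.3f\n", x$M, x$p_structure))
  cat(sprintf("  global strength: S = %.3f, p = %.3f (%s %.2f vs %s %.2f)\n",
              x$S, x$p_strength, x$groups[1], x$strengths[1],
              x$groups[2], x$strengths[2]))
  sig <- sum(x$edge_tests$p_adj < 0.05)
  cat("  per-edge tests: ", sig, " of ", nrow(x$edge_tests),
      " significant after ", x$adjust, " adjustment\n", sep = "")
  invisible(x)
}
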