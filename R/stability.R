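# Bootstrap machinery for network accuracy and stability: nonparametric
# (row-resampling) bootstrap of edge weights and centralities, bootstrap
# edge-difference tests, case-dropping subset bootstrap with the
# CS-coefficient, and the focal-node predictive-betweenness bootstrap.
# All routines draw per-replicate seeds up front from the master seed, so
# results are reproducible and independent of execution order.

default_estimator <- function(types = NULL, communities = NULL, ...) {
  args <- list(...)
  function(d) {
    do.call(ebic_glasso, c(list(d, types = types, communities = communities),
                           args))
  }
}

edge_names <- function(nodes) {
  idx <- which(upper.tri(diag(length(nodes))), arr.ind = TRUE)
  paste0(nodes[idx[, 1]], "--", nodes[idx[, 2]])
}

edge_vector <- function(net) {
  W <- net$weights
  setNames(W[upper.tri(W)], edge_names(net$nodes))
}

replicate_seeds <- function(seed, B) {
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, B)
}

#' Nonparametric bootstrap of the network pipeline
#'
#' Resamples rows with replacement `B` times and re-runs the full
#' estimation pipeline (mixed-type correlations, EBIC graphical lasso,
#' centralities) on each replicate. Edge weights get 2.5/97.5% quantile
#' confidence intervals. Replicates whose estimation fails are excluded and
#' counted. Deterministic given `seed`.
#'
#' @param data Cohort data frame.
#' @param B Number of bootstrap replicates.
#' @param seed Master seed; per-replicate seeds are drawn from it, so
#'   results do not depend on execution order.
#' @param estimator Function `data -> weighted_network` (or -> named numeric
#'   vector of statistics). Default: [ebic_glasso()] with the cohort's
#'   types/communities.
#' @param keep_networks Keep each replicate's weight matrix (needed by
#'   [bootstrap_predictive_betweenness()] reuse).
#' @param ... Passed to the default estimator (e.g. `gamma`, `n_lambdas`).
#' @return Object of class `network_bootstrap`: `summary` tibble
#'   (statistic, type, sample value, boot median, ci_lower, ci_upper),
#'   `replicates` (B x statistics matrix), `networks` (list or NULL),
#'   `sample_network`, `failed`, `B`, `seed`.
#' @export
bootstrap_network <- function(data, B = 1000, seed = 1, estimator = NULL,
                              keep_networks = TRUE, ...) {
  stopifnot(B >= 2)
  estimator <- estimator %||%
    default_estimator(types = cohort_types(data) %||% infer_types(data),
                      communities = cohort_communities(data), ...)
  full <- estimator(data)
  is_net <- inherits(full, "weighted_network")
  stat_fun <- function(res) {
    if (inherits(res, "weighted_network")) {
      ei <- expected_influence(res)
      c(edge_vector(res),
        setNames(ei$expected_influence, paste0("EI:", ei$node)),
        setNames(ei$strength, paste0("strength:", ei$node)))
    } else res
  }
  full_stats <- stat_fun(full)

  seeds <- replicate_seeds(seed, B)
  n <- nrow(data)
  reps <- matrix(NA_real_, B, length(full_stats),
                 dimnames = list(NULL, names(full_stats)))
  networks <- if (keep_networks && is_net) vector("list", B)
  failed <- 0L
  for (b in seq_len(B)) {
    set.seed(seeds[b])
    idx <- sample.int(n, n, replace = TRUE)
    res <- tryCatch(estimator(data[idx, , drop = FALSE]),
                    error = function(e) NULL)
    if (is.null(res)) {
      failed <- failed + 1L
      next
    }
    reps[b, ] <- stat_fun(res)
    if (!is.null(networks)) networks[[b]] <- res$weights
  }
  ok <- !is.na(reps[, 1])
  qs <- apply(reps[ok, , drop = FALSE], 2, quantile,
              probs = c(0.025, 0.5, 0.975), names = FALSE)
  summary <- tibble::tibble(
    statistic = names(full_stats),
    type = dplyr::case_when(
      grepl("^EI:", names(full_stats)) ~ "expected_influence",
      grepl("^strength:", names(full_stats)) ~ "strength",
      is_net ~ "edge",
      TRUE ~ "statistic"
    ),
    sample = unname(full_stats),
    boot_median = unname(qs[2, ]), ci_lower = unname(qs[1, ]),
    ci_upper = unname(qs[3, ])
  )
  structure(
    list(summary = summary, replicates = reps[ok, , drop = FALSE],
         networks = if (!is.null(networks)) networks[ok],
         sample_network = if (is_net) full, failed = failed, B = B,
         seed = seed),
    class = "network_bootstrap"
  )
}

#' @export
print.network_bootstrap <- function(x, ...) {
  cat("Network bootstrap: B = ", x$B, " (", x$failed, " failed), ",
      sum(x$summary$type == "edge"), " edges tracked\n", sep = "")
  invisible(x)
}

canonical_edge <- function(boot, edge) {
  if (length(edge) == 2) {
    cand <- c(paste0(edge[1], "--", edge[2]), paste0(edge[2], "--", edge[1]))
    edge <- cand[cand %in% colnames(boot$replicates)][1]
  }
  if (is.na(edge) || !edge %in% colnames(boot$replicates)) {
    abort("Edge not tracked in the bootstrap result.")
  }
  edge
}

#' Bootstrap edge-weight difference test
#'
#' Two edges differ significantly when the bootstrap 95% quantile interval
#' of their weight difference excludes zero.
#'
#' @param boot A `network_bootstrap`.
#' @param edge1,edge2 Edge names (`"A--B"` or `c("A", "B")`).
#' @return List with `significant`, `ci` (2.5/97.5% quantiles of the
#'   difference) and the edge names.
#' @export
edge_difference_test <- function(boot, edge1, edge2) {
  e1 <- canonical_edge(boot, edge1)
  e2 <- canonical_edge(boot, edge2)
  d <- boot$replicates[, e1] - boot$replicates[, e2]
  ci <- quantile(d, c(0.025, 0.975), names = FALSE)
  list(edge1 = e1, edge2 = e2, ci = ci,
       significant = ci[1] > 0 || ci[2] < 0)
}

#' All-pairs edge difference tests
#'
#' Runs [edge_difference_test()] over all pairs of edges that are non-zero
#' in the sample network.
#'
#' @param boot A `network_bootstrap`.
#' @return Tibble with `edge1`, `edge2`, `ci_lower`, `ci_upper`,
#'   `significant` (symmetric in its two edge arguments).
#' @export
edge_difference_matrix <- function(boot) {
  edges <- dplyr::filter(boot$summary, .data$type == "edge",
                         .data$sample != 0)$statistic
  if (length(edges) < 2) {
    return(tibble::tibble(edge1 = character(), edge2 = character(),
                          ci_lower = numeric(), ci_upper = numeric(),
                          significant = logical()))
  }
  prs <- combn(edges, 2)
  purrr::map_dfr(seq_len(ncol(prs)), function(i) {
    r <- edge_difference_test(boot, prs[1, i], prs[2, i])
    tibble::tibble(edge1 = r$edge1, edge2 = r$edge2,
                   ci_lower = r$ci[1], ci_upper = r$ci[2],
                   significant = r$significant)
  })
}

#' Case-dropping bootstrap for centrality stability
#'
#' For each drop proportion `q`, draws `B` subsamples retaining
#' `ceiling((1 - q) n)` rows without replacement, re-estimates the network,
#' and records the correlation between the subset and full-sample
#' centrality vectors for each requested index. Proportions whose subsets
#' are too small to estimate (`n_sub <= p`) are skipped with a warning.
#'
#' @param data Cohort data frame.
#' @param proportions Drop proportions (default 0.05 to 0.75 by 0.05).
#' @param B Subsamples per proportion.
#' @param indices Centrality indices to track (columns of [centrality()]).
#' @param seed Master seed.
#' @param estimator As in [bootstrap_network()].
#' @param ... Passed to the default estimator.
#' @return Object of class `case_drop`: `samples` tibble (proportion,
#'   replicate, index, correlation), `full` centrality tibble, `skipped`
#'   proportions, `B`, `seed`.
#' @export
case_dropping <- function(data, proportions = seq(0.05, 0.75, by = 0.05),
                          B = 50, indices = c("strength",
                                              "expected_influence",
                                              "bridge_expected_influence",
                                              "betweenness"),
                          seed = 1, estimator = NULL, ...) {
  stopifnot(all(proportions >= 0), max(proportions) < 1)
  communities <- cohort_communities(data)
  estimator <- estimator %||%
    default_estimator(types = cohort_types(data) %||% infer_types(data),
                      communities = communities, ...)
  full_net <- estimator(data)
  full_cent <- centrality(full_net, communities = communities)
  indices <- intersect(indices, names(full_cent))
  # an index that is constant on the full sample (e.g. bridge EI in a
  # single-community network) has no defined stability correlation
  degenerate <- vapply(indices, function(ix) sd(full_cent[[ix]]) == 0,
                       logical(1))
  if (any(degenerate)) {
    warn(paste0("Dropping constant centrality index(es): ",
                paste(indices[degenerate], collapse = ", ")))
    indices <- indices[!degenerate]
  }
  n <- nrow(data)
  p <- length(full_net$nodes)

  seeds <- replicate_seeds(seed, length(proportions) * B)
  dim(seeds) <- c(length(proportions), B)
  out <- list()
  skipped <- numeric()
  for (qi in seq_along(proportions)) {
    q <- proportions[qi]
    n_sub <- ceiling((1 - q) * n)
    if (n_sub <= p) {
      warn(sprintf("Proportion %.2f leaves n = %d <= p = %d; skipped.",
                   q, n_sub, p))
      skipped <- c(skipped, q)
      next
    }
    for (b in seq_len(B)) {
      set.seed(seeds[qi, b])
      idx <- sample.int(n, n_sub, replace = FALSE)
      net <- tryCatch(estimator(data[idx, , drop = FALSE]),
                      error = function(e) NULL)
      cors <- rep(NA_real_, length(indices))
      if (!is.null(net)) {
        cent <- centrality(net, communities = communities)
        cent <- cent[match(full_cent$node, cent$node), ]
        cors <- vapply(indices, function(ix) {
          fx <- full_cent[[ix]]; sx <- cent[[ix]]
          if (sd(fx) == 0 || sd(sx) == 0) return(NA_real_)
          cor(fx, sx)
        }, numeric(1))
      }
      out[[length(out) + 1L]] <- tibble::tibble(
        proportion = q, replicate = b, index = indices,
        correlation = unname(cors))
    }
  }
  structure(
    list(samples = dplyr::bind_rows(out), full = full_cent,
         proportions = setdiff(proportions, skipped), skipped = skipped,
         B = B, seed = seed),
    class = "case_drop"
  )
}

#' @export
print.case_drop <- function(x, ...) {
  cat("Case-dropping bootstrap: proportions ",
      paste(format(range(x$proportions)), collapse = "-"),
      ", B = ", x$B, " per proportion\n", sep = "")
  print(cs_coefficient(x))
  invisible(x)
}

#' Correlation-stability (CS) coefficient
#'
#' The largest tested drop proportion `q` such that, at every proportion up
#' to and including `q`, at least `prob` of the subsamples correlate at
#' least `cor_threshold` with the full-sample centrality; 0 when no
#' proportion qualifies. With the default grid the maximum attainable value
#' is 0.75.
#'
#' @param result A `case_drop` object or a tibble shaped like its
#'   `samples` field.
#' @param cor_threshold Correlation threshold (default 0.7).
#' @param prob Required fraction of subsamples above the threshold
#'   (default 0.95).
#' @return Tibble with `index`, `cs`.
#' @export
cs_coefficient <- function(result, cor_threshold = 0.7, prob = 0.95) {
  samples <- if (inherits(result, "case_drop")) result$samples else result
  if (!nrow(samples)) abort("Empty case-dropping result.")
  pass <- samples |>
    dplyr::group_by(.data$index, .data$proportion) |>
    dplyr::summarise(
      # a proportion with no usable replicates counts as unstable
      ok = {
        m <- mean(.data$correlation >= cor_threshold, na.rm = TRUE)
        !is.na(m) && m >= prob
      },
      .groups = "drop_last") |>
    dplyr::arrange(.data$proportion, .by_group = TRUE) |>
    dplyr::summarise(
      cs = {
        run <- cumprod(.data$ok) == 1
        if (any(run)) max(.data$proportion[run]) else 0
      }, .groups = "drop")
  pass
}

#' Bootstrap of focal-node predictive betweenness
#'
#' Point values of [predictive_betweenness()] on the full sample, plus its
#' distribution across nonparametric bootstrap replicates (median and
#' 2.5/97.5% quantiles per node).
#'
#' @param data Cohort data frame, or an existing [bootstrap_network()]
#'   result with `keep_networks = TRUE` (replicate networks are then
#'   reused).
#' @param focal Focal node name.
#' @param B,seed,estimator,... As in [bootstrap_network()] (ignored when
#'   `data` is already a `network_bootstrap`).
#' @return Object of class `pb_bootstrap`: `summary` tibble (node, sample,
#'   boot_median, ci_lower, ci_upper), `replicates` matrix, `focal`, `B`,
#'   `failed`, `seed`.
#' @export
bootstrap_predictive_betweenness <- function(data, focal, B = 1000, seed = 1,
                                             estimator = NULL, ...) {
  boot <- if (inherits(data, "network_bootstrap")) data else {
    bootstrap_network(data, B = B, seed = seed, estimator = estimator,
                      keep_networks = TRUE, ...)
  }
  if (is.null(boot$networks)) {
    abort("Bootstrap was run with keep_networks = FALSE.")
  }
  full <- predictive_betweenness(boot$sample_network, focal)
  reps <- t(vapply(boot$networks, function(W) {
    predictive_betweenness(W, focal)$predictive_betweenness
  }, numeric(nrow(full))))
  colnames(reps) <- full$node
  keep <- full$node != focal
  qs <- apply(reps[, keep, drop = FALSE], 2, quantile,
              probs = c(0.025, 0.5, 0.975), names = FALSE)
  structure(
    list(summary = tibble::tibble(
           node = full$node[keep],
           sample = full$predictive_betweenness[keep],
           boot_median = unname(qs[2, ]), ci_lower = unname(qs[1, ]),
           ci_upper = unname(qs[3, ])),
         replicates = reps[, keep, drop = FALSE], focal = focal,
         B = boot$B, failed = boot$failed, seed = boot$seed),
    class = "pb_bootstrap"
  )
}

#' @export
print.pb_bootstrap <- function(x, ...) {
  cat("Predictive-betweenness bootstrap (focal = ", x$focal, ", B = ",
      x$B, ")\n", sep = "")
  top <- dplyr::arrange(x$summary, dplyr::desc(.data$boot_median))
  print(head(top, 5))
  invisible(x)
}
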