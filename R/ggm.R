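# Sparse Gaussian graphical model estimation: graphical lasso over a
# penalty path with Extended Bayesian Information Criterion selection.
# The selected model is reported as a partial-correlation network
# w_ij = -Theta_ij / sqrt(Theta_ii Theta_jj).

#' Graphical lasso at a single penalty
#'
#' Maximises `log det(Theta) - tr(S Theta) - lambda * sum_{i != j} |Theta_ij|`
#' (penalty on off-diagonals only) by block coordinate descent, stopping when
#' the duality gap `|tr(S Theta) + lambda ||Theta||_1,off - p|` falls below
#' `tol`. Deterministic. At `lambda = 0` this reduces to (iteratively
#' computed) inversion of `S`.
#'
#' @param S Correlation matrix (PSD, unit diagonal) or a
#'   `correlation_matrix` object.
#' @param lambda Non-negative penalty.
#' @param tol Duality-gap tolerance (default 1e-4).
#' @param max_iter Maximum outer sweeps.
#' @param warm Optional previous `glasso_fit` for warm starting.
#' @return Object of class `glasso_fit`: `precision` (Theta), `lambda`,
#'   `loglik` (`log det Theta - tr(S Theta)`), `converged`, `iterations`,
#'   `gap`.
#' @export
glasso_fit <- function(S, lambda, tol = 1e-4, max_iter = 200, warm = NULL) {
  if (inherits(S, "correlation_matrix")) S <- S$values
  stopifnot(isSymmetric(unname(S), tol = 1e-7), all(lambda >= 0))
  S <- (S + t(S)) / 2   # exact symmetry, so soft-thresholds are two-sided
  lam <- if (is.matrix(lambda)) lambda else
    matrix(lambda, nrow(S), ncol(S))
  fit <- .glasso_cpp(S, lam, tol, as.integer(max_iter),
                     warm$W, warm$B)
  Theta <- fit$Theta
  dimnames(Theta) <- dimnames(S)
  if (!fit$converged) {
    warn(sprintf("glasso did not converge (gap %.3g)", fit$gap))
  }
  ld <- determinant(Theta, logarithm = TRUE)
  structure(
    list(precision = Theta,
         lambda = if (is.matrix(lambda)) NA_real_ else lambda,
         loglik = as.numeric(ld$modulus) - sum(S * Theta),
         converged = fit$converged, iterations = fit$iterations,
         gap = fit$gap, W = fit$W, B = fit$B),
    class = "glasso_fit"
  )
}

#' Penalty path for the graphical lasso
#'
#' Logarithmically spaced sequence from `lambda_max` (the largest
#' off-diagonal `|S|`, at which the estimated network is empty) down to
#' `lambda_max * min_ratio`.
#'
#' @param S Correlation matrix or `correlation_matrix` object.
#' @param n_lambdas Path length (default 100).
#' @param min_ratio Ratio of smallest to largest penalty (default 0.01).
#' @return Strictly decreasing numeric vector (a single 0 when `S` has no
#'   non-zero off-diagonal).
#' @export
lambda_path <- function(S, n_lambdas = 100, min_ratio = 0.01) {
  if (inherits(S, "correlation_matrix")) S <- S$values
  stopifnot(n_lambdas >= 2, min_ratio > 0, min_ratio < 1)
  lmax <- max(abs(S[upper.tri(S)]))
  if (lmax == 0) return(0)
  exp(seq(log(lmax), log(lmax * min_ratio), length.out = n_lambdas))
}

ebic_score <- function(fit, n, p, gamma) {
  P <- precision_to_partials(fit$precision)
  E <- sum(abs(P[upper.tri(P)]) > 0)
  nll <- -(n / 2) * fit$loglik
  list(value = 2 * nll + E * log(n) + 4 * E * gamma * log(p), E = E)
}

# Constrained MLE with a fixed zero pattern: an effectively infinite
# penalty on the non-edges reduces the glasso solver to the
# known-structure Gaussian graphical model fit (exact zeros off support).
ggm_refit <- function(S, support, tol = 1e-4, max_iter = 200) {
  lam <- matrix(0, nrow(S), ncol(S))
  lam[!support] <- 1e8
  diag(lam) <- 0
  glasso_fit(S, lam, tol = tol, max_iter = max_iter)
}

#' EBIC-selected graphical lasso network
#'
#' Fits the graphical lasso along the full penalty path (warm-started from
#' sparse to dense) and scores every candidate model with the Extended
#' Bayesian Information Criterion
#' `-2 loglik + E log(n) + 4 E gamma log(p)` (`E` = edge count,
#' `loglik = (n/2)(log det Theta - tr(S Theta))`), returning the
#' partial-correlation network of the minimising model. Ties break toward
#' the larger penalty (sparser model).
#'
#' By default (`refit = TRUE`) each distinct support found on the path is
#' re-estimated as a constrained maximum-likelihood GGM (zeros fixed, no
#' shrinkage) and the EBIC is computed on that decoupled refit, so that
#' selection is not distorted by lasso shrinkage of strong edges; the
#' returned weights are the refit's (unshrunken) partial correlations.
#' `refit = FALSE` scores and returns the penalised fits themselves.
#'
#' @param data A cohort data frame (mixed-type correlations are computed via
#'   [mixed_cor()]), a `correlation_matrix`, or a plain correlation matrix
#'   (then `n` is required).
#' @param n Sample size used for the correlations (taken from the
#'   `correlation_matrix` when available).
#' @param gamma EBIC hyperparameter (default 0.5).
#' @param n_lambdas,min_ratio Path parameters, see [lambda_path()].
#' @param tol,max_iter Passed to [glasso_fit()].
#' @param refit Score supports on decoupled unpenalised refits (default
#'   `TRUE`); see Details.
#' @param communities Optional named community labels for the nodes.
#' @param ... Passed to [mixed_cor()] when `data` is a data frame.
#' @return Object of class `weighted_network`: `weights` (symmetric, zero
#'   diagonal), `nodes`, `communities`, `lambda`, `gamma`, `n`, `fit`
#'   (the selected `glasso_fit`), and `path` (tibble: lambda, edges, ebic).
#' @examples
#' S <- diag(3); S[1, 2] <- S[2, 1] <- 0.4
#' net <- ebic_glasso(S, n = 500)
#' tidy(net)
#' @export
ebic_glasso <- function(data, n = NULL, gamma = 0.5, n_lambdas = 100,
                        min_ratio = 0.01, tol = 1e-4, max_iter = 200,
                        refit = TRUE, communities = NULL, ...) {
  if (is.data.frame(data)) {
    communities <- communities %||% cohort_communities(data)
    data <- mixed_cor(data, ...)
  }
  if (inherits(data, "correlation_matrix")) {
    n <- n %||% data$n
    communities <- communities %||% data$communities
    S <- data$values
  } else {
    S <- data
  }
  if (is.null(n)) abort("Supply `n` (sample size) with a plain matrix.")
  p <- ncol(S)
  if (n <= p) warn("Sample size n <= number of nodes p; estimates unstable.")
  nodes <- colnames(S) %||% paste0("V", seq_len(p))
  dimnames(S) <- list(nodes, nodes)

  lams <- lambda_path(S, n_lambdas = n_lambdas, min_ratio = min_ratio)
  best <- NULL
  warm <- NULL
  path_edges <- integer(length(lams))
  path_ebic <- numeric(length(lams))
  path_pd <- logical(length(lams))
  scored <- new.env(parent = emptyenv())
  for (i in seq_along(lams)) {
    fit <- glasso_fit(S, lams[i], tol = tol, max_iter = max_iter, warm = warm)
    warm <- fit
    support <- fit$precision != 0
    key <- paste0("s", paste(which(support[upper.tri(support)]),
                             collapse = ","))
    if (is.null(scored[[key]])) {
      cand <- if (refit) ggm_refit(S, support, tol = tol,
                                   max_iter = max_iter) else fit
      ev <- min(eigen(cand$precision, symmetric = TRUE,
                      only.values = TRUE)$values)
      scored[[key]] <- c(ebic_score(cand, n, p, gamma),
                         list(fit = cand, pd = ev > 0))
    }
    sc <- scored[[key]]
    path_edges[i] <- sc$E
    path_ebic[i] <- sc$value
    path_pd[i] <- sc$pd
    if (sc$pd && (is.null(best) || sc$value < best$score)) {
      best <- list(fit = sc$fit, score = sc$value, lambda = lams[i])
    }
  }
  path <- list(tibble::tibble(lambda = lams, edges = path_edges,
                              ebic = path_ebic, pd = path_pd))
  if (is.null(best)) abort("No positive-definite fit found on the path.")
  weights <- precision_to_partials(best$fit$precision)
  dimnames(weights) <- list(nodes, nodes)
  best$fit$W <- best$fit$B <- NULL
  structure(
    list(weights = weights, nodes = nodes,
         communities = communities, lambda = best$lambda, gamma = gamma,
         n = n, fit = best$fit, path = dplyr::bind_rows(path)),
    class = "weighted_network"
  )
}

#' Construct a weighted network directly from a weight matrix
#'
#' Mainly for tests and toy examples.
#'
#' @param weights Symmetric matrix with zero diagonal.
#' @param communities Optional named community labels.
#' @return A `weighted_network`.
#' @export
weighted_network <- function(weights, communities = NULL) {
  stopifnot(isSymmetric(unname(weights), tol = 1e-8))
  nodes <- colnames(weights) %||% paste0("V", seq_len(ncol(weights)))
  dimnames(weights) <- list(nodes, nodes)
  diag(weights) <- 0
  structure(list(weights = weights, nodes = nodes, communities = communities,
                 lambda = NA_real_, gamma = NA_real_, n = NA_integer_,
                 fit = NULL, path = NULL),
            class = "weighted_network")
}

#' @export
print.weighted_network <- function(x, ...) {
  W <- x$weights
  E <- sum(abs(W[upper.tri(W)]) > 0)
  cat("Weighted partial-correlation network: ", length(x$nodes), " nodes, ",
      E, " edges", sep = "")
  if (!is.na(x$lambda)) cat(", lambda = ", format(x$lambda, digits = 3), sep = "")
  cat("\n")
  invisible(x)
}

#' Export a network as a TSV edge list, GraphML, or JSON summary
#'
#' @param net A `weighted_network`.
#' @param path Output file; format from extension (`.tsv`, `.graphml`,
#'   `.json`).
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path) {
  ext <- tolower(tools::file_ext(path))
  edges <- tidy(net)
  if (ext == "tsv") {
    readr::write_tsv(edges, path)
  } else if (ext == "graphml") {
    g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                       vertices = data.frame(name = net$nodes))
    if (!is.null(net$communities)) {
      igraph::V(g)$community <- unname(net$communities[net$nodes])
    }
    igraph::write_graph(g, path, format = "graphml")
  } else if (ext == "json") {
    jsonlite::write_json(
      list(nodes = net$nodes, communities = as.list(net$communities),
           lambda = net$lambda, gamma = net$gamma, n = net$n,
           edges = edges),
      path, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  } else {
    abort("Unsupported extension; use .tsv, .graphml or .json.")
  }
  invisible(path)
}
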