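# broom-style tidiers for the package's result objects.

#' @rdname tidy.weighted_network
#' @export
glance.weighted_network <- function(x, ...) {
  W <- x$weights
  tibble::tibble(
    nodes = length(x$nodes),
    edges = sum(abs(W[upper.tri(W)]) > 0),
    lambda = x$lambda, gamma = x$gamma, n = x$n,
    global_strength = global_strength(x)
  )
}

#' Tidy a weighted network
#'
#' `tidy()` returns the non-zero edges as a tibble; `glance()` returns a
#' one-row model summary.
#'
#' @param x A `weighted_network`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.weighted_network <- function(x, ...) {
  strongest_edges(x, k = Inf)
}

#' Tidy a polychoric fit
#'
#' @param x A `polychoric_fit`.
#' @param ... Unused.
#' @return One-row tibble with `rho`, `loglik`, `n`, `at_bound`.
#' @export
tidy.polychoric_fit <- function(x, ...) {
  tibble::tibble(rho = x$rho, loglik = x$loglik, n = x$n,
                 at_bound = x$at_bound)
}

#' Tidy bootstrap results
#'
#' `tidy()` on a `network_bootstrap` or `pb_bootstrap` returns the summary
#' tibble (statistic / node, sample value, bootstrap median, CI bounds).
#'
#' @param x A `network_bootstrap` or `pb_bootstrap`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.network_bootstrap <- function(x, ...) x$summary

#' @rdname tidy.network_bootstrap
#' @export
tidy.pb_bootstrap <- function(x, ...) x$summary

#' Tidy case-dropping results
#'
#' `tidy()` returns mean subset-vs-full correlations per proportion and
#' index (with 2.5/97.5% quantiles); `glance()` returns the CS-coefficient
#' per index.
#'
#' @param x A `case_drop` object.
#' @param ... For `glance()`, passed to [cs_coefficient()].
#' @return A tibble.
#' @export
tidy.case_drop <- function(x, ...) {
  x$samples |>
    dplyr::group_by(.data$index, .data$proportion) |>
    dplyr::summarise(
      mean_correlation = mean(.data$correlation, na.rm = TRUE),
      q025 = quantile(.data$correlation, 0.025, na.rm = TRUE),
      q975 = quantile(.data$correlation, 0.975, na.rm = TRUE),
      .groups = "drop"
    )
}

#' @rdname tidy.case_drop
#' @export
glance.case_drop <- function(x, ...) {
  tidyr::pivot_wider(cs_coefficient(x, ...), names_from = "index",
                     values_from = "cs", names_prefix = "cs_")
}

#' Tidy a network comparison test
#'
#' `tidy()` returns the per-edge tests; `glance()` the global statistics.
#'
#' @param x An `nct_result`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.nct_result <- function(x, ...) x$edge_tests

#' @rdname tidy.nct_result
#' @export
glance.nct_result <- function(x, ...) {
  tibble::tibble(
    M = x$M, S = x$S,
    strength_1 = unname(x$strengths[1]), strength_2 = unname(x$strengths[2]),
    p_structure = x$p_structure, p_strength = x$p_strength,
    n_perm = x$n_perm, failed = x$failed
  )
}
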