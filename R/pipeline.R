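# End-to-end orchestration: study configuration, cohort loading and
# validation, the HAMD-24 inclusion rule, prevalence utilities, and
# run_study(), which chains every stage of the analysis with seeds fanned
# out from one master seed.

#' Study configuration
#'
#' Collects the variable roles and estimator settings for [run_study()].
#' Defaults mirror the package's reference design: 24 ordinal HAMD items
#' (HAMD3 excluded from the network but kept in the inclusion total),
#' binary SI/SP/SA, continuous ACTH and Cort, inclusion at HAMD-24 total
#' >= 8, EBIC gamma 0.5, and ACTH as the focal node for flow and
#' predictive betweenness.
#'
#' @param hamd_items,suicidality_items,biomarkers Variable names per role.
#' @param group Optional two-level grouping column for the NCT
#'   (`NULL` disables the comparison).
#' @param exclude Items excluded from the network nodes (still used for the
#'   inclusion total).
#' @param inclusion_threshold Minimum HAMD total for inclusion.
#' @param gamma EBIC hyperparameter.
#' @param n_lambdas,min_ratio Penalty-path settings.
#' @param B Bootstrap replicates (edge CIs and predictive betweenness).
#' @param case_drop_B Subsamples per case-dropping proportion.
#' @param proportions Case-dropping proportions.
#' @param n_perm NCT permutations.
#' @param focal Focal node.
#' @param n Cohort size when simulating.
#' @param seed Master seed; all stage seeds derive from it.
#' @return A `study_config` list.
#' @export
study_config <- function(hamd_items = paste0("HAMD", 1:24),
                         suicidality_items = c("SI", "SP", "SA"),
                         biomarkers = c("ACTH", "Cort"),
                         group = "gender",
                         exclude = "HAMD3",
                         inclusion_threshold = 8,
                         gamma = 0.5, n_lambdas = 100, min_ratio = 0.01,
                         B = 1000, case_drop_B = 50,
                         proportions = seq(0.05, 0.75, by = 0.05),
                         n_perm = 1000, focal = "ACTH",
                         n = 898, seed = 1) {
  stopifnot(inclusion_threshold >= 0)
  cfg <- list(hamd_items = hamd_items,
              suicidality_items = suicidality_items,
              biomarkers = biomarkers, group = group, exclude = exclude,
              inclusion_threshold = inclusion_threshold, gamma = gamma,
              n_lambdas = n_lambdas, min_ratio = min_ratio, B = B,
              case_drop_B = case_drop_B, proportions = proportions,
              n_perm = n_perm, focal = focal, n = n, seed = seed)
  structure(cfg, class = "study_config")
}

config_types <- function(config) {
  c(setNames(rep("ordinal", length(config$hamd_items)), config$hamd_items),
    setNames(rep("binary", length(config$suicidality_items)),
             config$suicidality_items),
    setNames(rep("continuous", length(config$biomarkers)), config$biomarkers))
}

config_communities <- function(config) {
  c(setNames(rep("depression", length(config$hamd_items)), config$hamd_items),
    setNames(rep("suicidality", length(config$suicidality_items)),
             config$suicidality_items),
    setNames(rep("biomarkers", length(config$biomarkers)), config$biomarkers))
}

#' Load and validate a cohort CSV
#'
#' Checks that every analysis column is present, that ordinal items take
#' integer values 0-4 and binary items 0/1 (failures name the offending
#' row and column), and drops rows with any missing analysis value
#' (complete-case analysis), reporting the dropped count.
#'
#' @param path CSV file with a header.
#' @param config A [study_config()].
#' @return A typed cohort tibble.
#' @export
load_cohort <- function(path, config = study_config()) {
  data <- readr::read_csv(path, show_col_types = FALSE)
  types <- config_types(config)
  missing_c <- setdiff(names(types), names(data))
  if (length(missing_c)) {
    abort(paste0("Missing analysis column(s): ",
                 paste(missing_c, collapse = ", ")))
  }
  for (cl in names(types)) {
    x <- data[[cl]]
    bad <- switch(types[cl],
      ordinal = which(!is.na(x) & (x != round(x) | x < 0 | x > 4)),
      binary = which(!is.na(x) & !x %in% c(0, 1)),
      continuous = integer(0)
    )
    if (length(bad)) {
      abort(sprintf("Column %s has out-of-range value %s at row %d.",
                    cl, format(x[bad[1]]), bad[1]))
    }
  }
  complete <- stats::complete.cases(data[names(types)])
  if (any(!complete)) {
    message(sum(!complete), " row(s) dropped for missing analysis values.")
    data <- data[complete, , drop = FALSE]
  }
  as_cohort(data, types = types, communities = config_communities(config))
}

#' Apply the HAMD-total inclusion rule
#'
#' Retains rows whose HAMD total (over *all* configured items, including
#' any network-excluded ones) is at least the configured threshold.
#'
#' @param data Cohort data frame.
#' @param config A [study_config()].
#' @return The filtered cohort (attributes preserved).
#' @export
apply_inclusion <- function(data, config = study_config()) {
  missing_c <- setdiff(config$hamd_items, names(data))
  if (length(missing_c)) {
    abort(paste0("Missing HAMD item(s) for the inclusion total: ",
                 paste(missing_c, collapse = ", ")))
  }
  total <- rowSums(data[config$hamd_items])
  keep <- total >= config$inclusion_threshold
  out <- data[keep, , drop = FALSE]
  structure(out, types = cohort_types(data),
            communities = cohort_communities(data),
            truth = attr(data, "truth"), class = class(data))
}

#' Binomial prevalence with a confidence interval
#'
#' Wald (normal-approximation) interval by default:
#' `p_hat +/- z * sqrt(p_hat (1 - p_hat) / n)`, truncated to `[0, 1]` and
#' reported in percent to two decimals. A Wilson score interval is
#' available via `method`.
#'
#' @param count Number of positives.
#' @param n Total.
#' @param level Confidence level (default 0.95).
#' @param method `"wald"` (default) or `"wilson"`.
#' @return Tibble with `estimate`, `lower`, `upper` (percent, 2 dp).
#' @examples
#' prevalence_ci(280, 898)
#' @export
prevalence_ci <- function(count, n, level = 0.95,
                          method = c("wald", "wilson")) {
  stopifnot(count >= 0, count <= n, n >= 1)
  method <- match.arg(method)
  phat <- count / n
  z <- qnorm(1 - (1 - level) / 2)
  if (method == "wald") {
    half <- z * sqrt(phat * (1 - phat) / n)
    lo <- phat - half
    hi <- phat + half
  } else {
    den <- 1 + z^2 / n
    ctr <- (phat + z^2 / (2 * n)) / den
    half <- z * sqrt(phat * (1 - phat) / n + z^2 / (4 * n^2)) / den
    lo <- ctr - half
    hi <- ctr + half
  }
  tibble::tibble(estimate = round(100 * phat, 2),
                 lower = round(100 * max(0, lo), 2),
                 upper = round(100 * min(1, hi), 2))
}

#' Run the full study pipeline
#'
#' Executes, in order: cohort simulation (when `data` is `NULL`), the
#' inclusion rule, node selection (dropping excluded items), mixed-type
#' correlations, EBIC graphical lasso, centrality and bridge centrality,
#' strongest edges, the focal-node flow view, the nonparametric bootstrap
#' (edge CIs + difference tests), case-dropping stability with the
#' CS-coefficient, the focal-node predictive-betweenness bootstrap, and an
#' optional network comparison test by the grouping column. All stage
#' seeds derive deterministically from `config$seed`.
#'
#' @param config A [study_config()].
#' @param data Optional cohort tibble (e.g. from [load_cohort()]); when
#'   `NULL`, [simulate_study_cohort()] supplies a synthetic cohort.
#' @return Object of class `analysis_report`; see [write_report()].
#' @export
run_study <- function(config = study_config(), data = NULL) {
  set.seed(config$seed)
  stage_seeds <- sample.int(.Machine$integer.max - 1L, 4)

  if (is.null(data)) {
    data <- simulate_study_cohort(n = config$n, seed = stage_seeds[1])
  }
  data <- apply_inclusion(data, config)
  n <- nrow(data)

  prevalence <- purrr::map_dfr(config$suicidality_items, function(v) {
    dplyr::bind_cols(tibble::tibble(item = v, count = sum(data[[v]]), n = n),
                     prevalence_ci(sum(data[[v]]), n))
  })
  hamd_total <- rowSums(data[config$hamd_items])
  summaries <- tibble::tibble(
    variable = c("HAMD_total", config$biomarkers),
    mean = c(mean(hamd_total),
             vapply(config$biomarkers, function(v) mean(data[[v]]),
                    numeric(1))),
    sd = c(sd(hamd_total),
           vapply(config$biomarkers, function(v) sd(data[[v]]), numeric(1)))
  )

  nodes <- setdiff(c(config$hamd_items, config$suicidality_items,
                     config$biomarkers), config$exclude)
  types <- config_types(config)[nodes]
  communities <- config_communities(config)[nodes]

  corr <- mixed_cor(data, types = types, columns = nodes)
  net <- ebic_glasso(corr, gamma = config$gamma,
                     n_lambdas = config$n_lambdas,
                     min_ratio = config$min_ratio,
                     communities = communities)
  cent <- centrality(net, communities = communities)
  top_edges <- strongest_edges(net, k = 10)
  flow <- flow_edges(net, config$focal)

  net_data <- data[nodes]
  est_args <- list(types = types, communities = communities,
                   gamma = config$gamma, n_lambdas = config$n_lambdas,
                   min_ratio = config$min_ratio)
  estimator <- do.call(default_estimator, est_args)
  boot <- bootstrap_network(net_data, B = config$B, seed = stage_seeds[2],
                            estimator = estimator)
  diffs <- edge_difference_matrix(boot)
  drop_res <- case_dropping(
    net_data, proportions = config$proportions, B = config$case_drop_B,
    seed = stage_seeds[3], estimator = estimator
  )
  cs <- cs_coefficient(drop_res)
  pb <- bootstrap_predictive_betweenness(boot, focal = config$focal)

  nct_res <- NULL
  if (!is.null(config$group) && config$group %in% names(data)) {
    nct_res <- nct(as_cohort(data[c(nodes, config$group)], types = types,
                             communities = communities),
                   group = config$group, n_perm = config$n_perm,
                   seed = stage_seeds[4], estimator = estimator)
  }

  structure(
    list(config = config, n = n, prevalence = prevalence,
         summaries = summaries, correlations = corr, network = net,
         centrality = cent, strongest_edges = top_edges, flow = flow,
         bootstrap = boot, edge_differences = diffs,
         case_dropping = drop_res, cs = cs,
         predictive_betweenness = pb, nct = nct_res,
         stage_seeds = stage_seeds),
    class = "analysis_report"
  )
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("Analysis report: n = ", x$n, ", ", length(x$network$nodes),
      "-node network (lambda = ", format(x$network$lambda, digits = 3),
      ")\n", sep = "")
  cat("Top expected influence:\n")
  print(head(dplyr::arrange(x$centrality,
                            dplyr::desc(.data$expected_influence)), 3))
  print(x$cs)
  invisible(x)
}

report_json <- function(report) {
  sig_share <- if (nrow(report$edge_differences)) {
    mean(report$edge_differences$significant)
  } else NA_real_
  list(
    seed = report$config$seed,
    stage_seeds = report$stage_seeds,
    n = report$n,
    prevalence = report$prevalence,
    summaries = report$summaries,
    network = list(
      nodes = report$network$nodes,
      lambda = report$network$lambda,
      gamma = report$network$gamma,
      edges = tidy(report$network)
    ),
    centrality = report$centrality,
    strongest_edges = report$strongest_edges,
    flow = tibble::as_tibble(report$flow),
    bootstrap = list(B = report$bootstrap$B, failed = report$bootstrap$failed,
                     edges = dplyr::filter(report$bootstrap$summary,
                                           .data$type == "edge")),
    edge_difference_significant_share = sig_share,
    cs_coefficient = report$cs,
    predictive_betweenness = report$predictive_betweenness$summary,
    nct = if (!is.null(report$nct)) list(
      M = report$nct$M, S = report$nct$S,
      strengths = as.list(report$nct$strengths),
      p_structure = report$nct$p_structure,
      p_strength = report$nct$p_strength,
      n_perm = report$nct$n_perm
    )
  )
}

#' Write an analysis report to disk
#'
#' Emits `report.json` (full summary, reproducible byte-for-byte given the
#' same master seed) plus TSVs for the network edge list, centrality table
#' and strongest edges.
#'
#' @param report An `analysis_report`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(report_json(report), file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows",
                       na = "null")
  readr::write_tsv(tidy(report$network), file.path(dir, "edges.tsv"))
  readr::write_tsv(report$centrality, file.path(dir, "centrality.tsv"))
  readr::write_tsv(report$strongest_edges,
                   file.path(dir, "strongest_edges.tsv"))
  invisible(dir)
}
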