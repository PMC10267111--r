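# Latent-Gaussian synthetic cohorts with a known sparse partial-correlation
# structure. The generator exists so that every downstream stage (mixed-type
# correlations -> EBIC glasso -> centrality -> bootstrap -> NCT) can be
# validated against ground truth; its defaults emulate the clinical cohort
# the package was designed around (24 HAMD items scored 0-4, binary SI/SP/SA,
# right-skewed ACTH and Cort, a gender column).

#' Construct a ground-truth partial-correlation network
#'
#' Builds a symmetric positive-definite precision matrix whose implied
#' partial-correlation matrix has a requested sparse support: random
#' within-community edges drawn at an expected density of `sparsity`, plus
#' explicitly specified edges (typically cross-community "bridge" edges).
#' Positive-definiteness is enforced by adding a diagonal shift `delta`,
#' doubled from 1e-3 until the smallest eigenvalue exceeds 1e-6.
#'
#' @param p Number of nodes; ignored when `communities` is given (then
#'   `p = length(communities)`).
#' @param communities Named character vector mapping node name to community
#'   label. When `NULL`, nodes are `V1..Vp` in one community.
#' @param sparsity Expected fraction of off-diagonal pairs (within a
#'   community) that receive a random edge, in `[0, 1)`.
#' @param edge_spec Data frame or tibble with columns `from`, `to`, `weight`:
#'   edges set deterministically (e.g. designated bridge edges). These
#'   override any randomly drawn edge on the same pair.
#' @param weight_range Absolute-size range for random edge weights.
#' @param negative_fraction Probability a random edge is negative.
#' @param seed RNG seed for the random support.
#' @return An object of class `ground_truth_network`: a list with `precision`,
#'   `partials` (zero diagonal), `nodes`, `communities`, `bridge_nodes`
#'   (nodes incident to a cross-community edge in `edge_spec`) and `delta`
#'   (the diagonal shift applied, 0 if none was needed).
#' @examples
#' gt <- make_ground_truth(6, sparsity = 0.2, seed = 1)
#' range(eigen(gt$precision)$values)
#' @export
make_ground_truth <- function(p = NULL, communities = NULL, sparsity = 0.1,
                              edge_spec = NULL, weight_range = c(0.1, 0.3),
                              negative_fraction = 0.25, seed = 1) {
  if (is.null(communities)) {
    if (is.null(p)) abort("Supply `p` or `communities`.")
    communities <- setNames(rep("all", p), paste0("V", seq_len(p)))
  }
  nodes <- names(communities)
  p <- length(nodes)
  if (p < 2) abort("Need at least 2 nodes.")
  if (sparsity < 0 || sparsity >= 1) abort("`sparsity` must be in [0, 1).")

  set.seed(seed)
  A <- matrix(0, p, p, dimnames = list(nodes, nodes))
  pairs <- which(upper.tri(A), arr.ind = TRUE)
  same_comm <- communities[pairs[, 1]] == communities[pairs[, 2]]
  draw <- runif(nrow(pairs)) < sparsity & same_comm
  if (any(draw)) {
    w <- runif(sum(draw), weight_range[1], weight_range[2]) *
      ifelse(runif(sum(draw)) < negative_fraction, -1, 1)
    A[pairs[draw, , drop = FALSE]] <- w
  }
  bridge_nodes <- character()
  if (!is.null(edge_spec)) {
    edge_spec <- as.data.frame(edge_spec)
    bad <- setdiff(unique(c(edge_spec$from, edge_spec$to)), nodes)
    if (length(bad)) abort(paste0("Unknown nodes in edge_spec: ",
                                  paste(bad, collapse = ", ")))
    for (i in seq_len(nrow(edge_spec))) {
      A[edge_spec$from[i], edge_spec$to[i]] <- edge_spec$weight[i]
      A[edge_spec$to[i], edge_spec$from[i]] <- edge_spec$weight[i]
    }
    cross <- communities[edge_spec$from] != communities[edge_spec$to]
    bridge_nodes <- unique(c(edge_spec$from[cross], edge_spec$to[cross]))
  }
  A <- A + t(A * upper.tri(A) * 0)  # already symmetric by construction
  A[lower.tri(A)] <- t(A)[lower.tri(A)]

  # Precision with requested partials: Theta_ij = -w_ij, unit diagonal,
  # then shift the diagonal until positive-definite.
  Theta <- -A
  diag(Theta) <- 1
  delta <- 0
  shift <- 1e-3
  for (i in 1:60) {
    ev <- min(eigen(Theta + delta * diag(p), symmetric = TRUE,
                    only.values = TRUE)$values)
    if (ev > 1e-6) break
    delta <- if (delta == 0) shift else delta * 2
    if (i == 60) abort("Could not reach positive-definiteness by diagonal shift.")
  }
  Theta <- Theta + delta * diag(p)
  partials <- precision_to_partials(Theta)

  structure(
    list(precision = Theta, partials = partials, nodes = nodes,
         communities = communities, bridge_nodes = bridge_nodes,
         delta = delta, seed = seed),
    class = "ground_truth_network"
  )
}

# partial correlations implied by a precision matrix (zero diagonal)
precision_to_partials <- function(Theta) {
  d <- sqrt(diag(Theta))
  P <- -Theta / outer(d, d)
  diag(P) <- 0
  P
}

#' Latent correlation matrix implied by a ground-truth network
#'
#' @param truth A `ground_truth_network`.
#' @return The correlation matrix of the latent Gaussian, i.e.
#'   `cov2cor(solve(precision))`.
#' @export
latent_correlation <- function(truth) {
  stopifnot(inherits(truth, "ground_truth_network"))
  cov2cor(solve(truth$precision))
}

#' Node specification for the default study cohort
#'
#' The default layout mirrors a psychiatric-emergency mood-disorder cohort:
#' 24 ordinal HAMD items scored 0-4 (community `"depression"`), three binary
#' suicidality indicators SI/SP/SA (community `"suicidality"`), and two
#' continuous, right-skewed HPA-axis biomarkers ACTH (pg/ml) and Cort
#' (nmol/L) (community `"biomarkers"`). Binary thresholds are set from the
#' target prevalences (0.312, 0.304, 0.3062); lognormal parameters match the
#' reported biomarker means/SDs; the shared ordinal thresholds put the mean
#' HAMD-24 total near 13.9.
#'
#' @return A tibble with one row per node: `node`, `type`, `community`, and
#'   list-column `par` holding type-specific parameters (`thresholds` for
#'   ordinal/binary, `meanlog`/`sdlog` for continuous).
#' @export
study_nodes <- function() {
  hamd <- paste0("HAMD", 1:24)
  ord_thr <- c(0.25, 1.10, 1.90, 2.60)
  lognorm_par <- function(m, s) {
    s2 <- log(1 + (s / m)^2)
    list(meanlog = log(m) - s2 / 2, sdlog = sqrt(s2))
  }
  dplyr::bind_rows(
    tibble::tibble(node = hamd, type = "ordinal", community = "depression",
                   par = purrr::map(hamd, ~ list(thresholds = ord_thr))),
    tibble::tibble(node = c("SI", "SP", "SA"), type = "binary",
                   community = "suicidality",
                   par = purrr::map(c(0.312, 0.304, 0.3062),
                                    ~ list(thresholds = qnorm(1 - .x)))),
    tibble::tibble(node = c("ACTH", "Cort"), type = "continuous",
                   community = "biomarkers",
                   par = list(lognorm_par(31.84, 28.77),
                              lognorm_par(16.68, 11.41)))
  )
}

# Designated edges of the default ground truth. Within-community backbones
# plus bridge edges chosen so the synthetic network reproduces the
# qualitative findings the package is exercised on: insomnia items form the
# strongest depressive edge, SA-SP the strongest suicidality edge, Cort the
# leading bridge and the strongest ACTH neighbour, HAMD3 redundant with SI.
study_edges <- function() {
  tibble::tribble(
    ~from,    ~to,      ~weight,
    "HAMD4",  "HAMD5",  0.40,
    "HAMD5",  "HAMD6",  0.30,
    "HAMD10", "HAMD11", 0.35,
    "HAMD18", "HAMD19", 0.30,
    "HAMD1",  "HAMD2",  0.25,
    "HAMD1",  "HAMD23", 0.25,
    "HAMD7",  "HAMD8",  0.25,
    "HAMD13", "HAMD14", 0.25,
    "SA",     "SP",     0.40,
    "SA",     "SI",     0.35,
    "SI",     "SP",     0.20,
    "HAMD3",  "SI",     0.45,
    "ACTH",   "Cort",   0.35,
    "Cort",   "HAMD23", 0.20,
    "Cort",   "SA",     0.20,
    "ACTH",   "HAMD13", 0.15,
    "ACTH",   "HAMD9",  0.12,
    "SI",     "HAMD23", 0.15,
    "HAMD8",  "ACTH",   0.12
  )
}

#' Ground-truth network for the default study cohort
#'
#' @param sparsity Density of additional random within-community edges.
#' @param seed Seed for the random support.
#' @return A `ground_truth_network` over the 29 `study_nodes()` variables.
#' @export
study_truth <- function(sparsity = 0.06, seed = 2026) {
  spec <- study_nodes()
  make_ground_truth(
    communities = setNames(spec$community, spec$node),
    sparsity = sparsity, edge_spec = study_edges(),
    weight_range = c(0.08, 0.2), seed = seed
  )
}

#' Generate a cohort from a ground-truth network
#'
#' Samples `n` latent vectors from the Gaussian implied by the truth's
#' precision matrix, then maps each latent column to its observable:
#' ordinal columns are discretised at their thresholds (values `0..K`),
#' binary columns thresholded (`0/1`), continuous columns transformed to
#' lognormal via `exp(meanlog + sdlog * z)`. Deterministic given `seed`.
#'
#' @param truth A `ground_truth_network`.
#' @param n Number of rows.
#' @param node_spec Tibble as returned by [study_nodes()]; when `NULL`, all
#'   nodes are ordinal with thresholds `c(-1.5, -0.5, 0.5, 1.5)` unless
#'   `default_type = "continuous"`, in which case latents are returned as-is.
#' @param subgroup Optional named list `list(name=, prevalence=, labels=)`
#'   adding an independent binary grouping column (e.g. gender).
#' @param default_type Observable type used when `node_spec` is `NULL`.
#' @param seed RNG seed.
#' @return A cohort tibble with attributes `types` and `communities`
#'   (named character vectors) and `seed`; see [cohort_types()].
#' @examples
#' gt <- make_ground_truth(4, sparsity = 0.3, seed = 1)
#' generate_cohort(gt, n = 5, seed = 1)
#' @export
generate_cohort <- function(truth, n, node_spec = NULL, subgroup = NULL,
                            default_type = c("ordinal", "continuous"),
                            seed = 1) {
  stopifnot(inherits(truth, "ground_truth_network"), n >= 1)
  default_type <- match.arg(default_type)
  nodes <- truth$nodes
  p <- length(nodes)
  if (is.null(node_spec)) {
    node_spec <- tibble::tibble(
      node = nodes, type = default_type,
      community = unname(truth$communities[nodes]),
      par = purrr::map(nodes, ~ if (default_type == "ordinal") {
        list(thresholds = c(-1.5, -0.5, 0.5, 1.5))
      } else list(raw = TRUE))
    )
  }
  if (!setequal(node_spec$node, nodes) || nrow(node_spec) != p) {
    abort("`node_spec` nodes must match the truth network's nodes.")
  }
  node_spec <- node_spec[match(nodes, node_spec$node), ]

  Sigma <- latent_correlation(truth)
  set.seed(seed)
  Z <- matrix(rnorm(n * p), n, p) %*% chol(Sigma)
  colnames(Z) <- nodes

  cols <- purrr::pmap(node_spec, function(node, type, community, par) {
    z <- Z[, node]
    switch(type,
      ordinal = as.integer(cut(z, c(-Inf, par$thresholds, Inf))) - 1L,
      binary = as.integer(z > par$thresholds),
      continuous = if (isTRUE(par$raw)) z else
        exp(par$meanlog + par$sdlog * z)
    )
  })
  out <- tibble::as_tibble(setNames(cols, nodes))
  types <- setNames(node_spec$type, node_spec$node)
  comms <- setNames(node_spec$community, node_spec$node)
  if (!is.null(subgroup)) {
    lab <- subgroup$labels %||% c(0L, 1L)
    out[[subgroup$name]] <- lab[1L + rbinom(n, 1L, subgroup$prevalence)]
  }
  structure(out, types = types, communities = comms, seed = seed,
            subgroup = if (!is.null(subgroup)) subgroup$name else NULL,
            class = class(out))
}

#' Simulate the default study cohort
#'
#' One call producing the full synthetic analogue of the study data:
#' 24 HAMD items, SI/SP/SA, ACTH, Cort and a `gender` column
#' (41% `"male"`, matching the cohort's composition).
#'
#' @param n Number of participants.
#' @param seed RNG seed (controls sampling only; the truth uses `truth_seed`).
#' @param truth Optional `ground_truth_network`; defaults to [study_truth()].
#' @param truth_seed Seed for the default truth's random support.
#' @return A cohort tibble (see [generate_cohort()]); the truth network is
#'   attached as attribute `truth`.
#' @export
simulate_study_cohort <- function(n = 898, seed = 1, truth = NULL,
                                  truth_seed = 2026) {
  if (is.null(truth)) truth <- study_truth(seed = truth_seed)
  out <- generate_cohort(
    truth, n, node_spec = study_nodes(),
    subgroup = list(name = "gender", prevalence = 0.41,
                    labels = c("female", "male")),
    seed = seed
  )
  attr(out, "truth") <- truth
  out
}

#' @rdname cohort_types
#' @export
cohort_communities <- function(data) attr(data, "communities")

#' Cohort metadata accessors
#'
#' Cohort tibbles carry their variable metadata in attributes: `types`
#' (named vector, values `ordinal`/`binary`/`continuous`) and `communities`.
#' dplyr verbs may drop these; [as_cohort()] re-attaches them.
#'
#' @param data A cohort tibble.
#' @return A named character vector (or `NULL` if absent).
#' @export
cohort_types <- function(data) attr(data, "types")

#' Attach (or re-attach) cohort metadata
#'
#' @param data A data frame of observed variables.
#' @param types Named character vector of variable types; inferred via
#'   [infer_types()] when `NULL`.
#' @param communities Optional named character vector of community labels.
#' @return `data` as a tibble with `types`/`communities` attributes.
#' @export
as_cohort <- function(data, types = NULL, communities = NULL) {
  data <- tibble::as_tibble(data)
  if (is.null(types)) types <- infer_types(data)
  structure(data, types = types, communities = communities,
            class = class(data))
}

#' Infer variable types from columns
#'
#' Columns with integer values confined to `{0, 1}` are `binary`, integer
#' values in `0..10` with at most 11 distinct levels are `ordinal`, anything
#' else numeric is `continuous`.
#'
#' @param data A data frame.
#' @param columns Columns to type (default: all numeric columns).
#' @return Named character vector of types.
#' @export
infer_types <- function(data, columns = NULL) {
  columns <- columns %||% names(data)[vapply(data, is.numeric, logical(1))]
  vapply(columns, function(cl) {
    x <- data[[cl]]
    u <- unique(x[!is.na(x)])
    if (all(u %in% c(0, 1))) return("binary")
    if (all(u == round(u)) && all(u >= 0 & u <= 10) && length(u) <= 11)
      return("ordinal")
    "continuous"
  }, character(1))
}

#' Write / read a cohort as CSV plus JSON metadata sidecar
#'
#' @param data A cohort tibble.
#' @param path CSV path; metadata goes to `<path>.meta.json`.
#' @param truth Optional `ground_truth_network` stored as a nested edge list.
#' @return `path`, invisibly (`write_cohort`); a cohort tibble (`read_cohort`).
#' @export
write_cohort <- function(data, path, truth = attr(data, "truth")) {
  readr::write_csv(data, path)
  meta <- list(
    types = as.list(cohort_types(data) %||% infer_types(data)),
    communities = as.list(cohort_communities(data)),
    seed = attr(data, "seed"),
    subgroup = attr(data, "subgroup")
  )
  if (!is.null(truth)) {
    P <- truth$partials
    idx <- which(upper.tri(P) & P != 0, arr.ind = TRUE)
    meta$truth <- list(
      nodes = truth$nodes,
      communities = as.list(truth$communities),
      edges = purrr::map(seq_len(nrow(idx)), function(i) {
        list(from = truth$nodes[idx[i, 1]], to = truth$nodes[idx[i, 2]],
             weight = P[idx[i, 1], idx[i, 2]])
      })
    )
  }
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  data <- readr::read_csv(path, show_col_types = FALSE)
  meta_path <- paste0(path, ".meta.json")
  types <- communities <- NULL
  if (file.exists(meta_path)) {
    meta <- jsonlite::read_json(meta_path)
    types <- unlist(meta$types)
    communities <- if (length(meta$communities)) unlist(meta$communities)
  }
  as_cohort(data, types = types, communities = communities)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
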