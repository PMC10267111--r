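# Bootstrap machinery: determinism, degenerate fixtures, difference tests,
# case-dropping stability and the CS-coefficient definition.

# fast estimator for continuous fixtures
lean_estimator <- function(communities = NULL) {
  function(d) {
    ebic_glasso(cor(as.matrix(d)), n = nrow(d), n_lambdas = 20,
                communities = communities)
  }
}

chain_cohort <- function(p, n, seed, weight = 0.3) {
  gt <- make_ground_truth(
    communities = setNames(rep("a", p), paste0("V", seq_len(p))),
    sparsity = 0,
    edge_spec = data.frame(from = paste0("V", seq_len(p - 1)),
                           to = paste0("V", 2:p), weight = weight))
  generate_cohort(gt, n, default_type = "continuous", seed = seed)
}

test_that("bootstrap is reproducible from its seed", {
  co <- chain_cohort(5, 300, seed = 1)
  b1 <- bootstrap_network(co, B = 12, seed = 5, estimator = lean_estimator())
  b2 <- bootstrap_network(co, B = 12, seed = 5, estimator = lean_estimator())
  expect_identical(b1$summary, b2$summary)
  expect_identical(b1$replicates, b2$replicates)
  b3 <- bootstrap_network(co, B = 12, seed = 6, estimator = lean_estimator())
  expect_false(identical(b1$replicates, b3$replicates))
})

test_that("a constant statistic yields degenerate intervals", {
  co <- tibble::tibble(x = rep(1, 40), y = rep(2, 40))
  boot <- bootstrap_network(co, B = 20, seed = 3,
                            estimator = function(d) colMeans(d))
  expect_equal(boot$summary$ci_lower, c(1, 2))
  expect_equal(boot$summary$ci_upper, c(1, 2))
  expect_equal(boot$summary$sample, c(1, 2))
})

test_that("edge CIs cover a strong generating weight", {
  # 6-node chain, strong first edge; reduced replicates
  covered <- vapply(1:20, function(s) {
    co <- chain_cohort(6, 1000, seed = 40 + s, weight = 0.4)
    boot <- bootstrap_network(co, B = 60, seed = s,
                              estimator = lean_estimator(),
                              keep_networks = FALSE)
    e <- boot$summary[boot$summary$statistic == "V1--V2", ]
    truth <- 0.4
    e$ci_lower <= truth && truth <= e$ci_upper
  }, logical(1))
  expect_gte(sum(covered), 16)
})

test_that("bootstrap intervals widen as the sample shrinks", {
  widths <- vapply(c(200, 1000, 5000), function(n) {
    co <- chain_cohort(4, n, seed = 77)
    boot <- bootstrap_network(co, B = 40, seed = 11,
                              estimator = lean_estimator(),
                              keep_networks = FALSE)
    e <- boot$summary[boot$summary$statistic == "V1--V2", ]
    e$ci_upper - e$ci_lower
  }, numeric(1))
  expect_true(all(diff(widths) < 0))
})

test_that("edge difference test separates distinct weights only", {
  # one strong edge, one absent edge in truth
  gt <- make_ground_truth(
    communities = setNames(rep("a", 4), paste0("V", 1:4)), sparsity = 0,
    edge_spec = data.frame(from = c("V1", "V3"), to = c("V2", "V4"),
                           weight = c(0.5, 0.2)))
  co <- generate_cohort(gt, 2000, default_type = "continuous", seed = 19)
  boot <- bootstrap_network(co, B = 200, seed = 2,
                            estimator = lean_estimator(),
                            keep_networks = FALSE)
  # an edge against itself: difference identically zero
  self <- edge_difference_test(boot, "V1--V2", "V1--V2")
  expect_false(self$significant)
  strong_vs_null <- edge_difference_test(boot, "V1--V2", "V1--V3")
  expect_true(strong_vs_null$significant)
  expect_error(edge_difference_test(boot, "V1--V2", "V1--V9"),
               "not tracked")
  # nearly equal truths at small n stay indistinguishable
  gt2 <- make_ground_truth(
    communities = setNames(rep("a", 5), paste0("V", 1:5)), sparsity = 0,
    edge_spec = data.frame(from = c("V1", "V3"), to = c("V2", "V4"),
                           weight = c(0.30, 0.29)))
  co2 <- generate_cohort(gt2, 200, default_type = "continuous", seed = 23)
  boot2 <- bootstrap_network(co2, B = 200, seed = 3,
                             estimator = lean_estimator(),
                             keep_networks = FALSE)
  near <- edge_difference_test(boot2, "V1--V2", "V3--V4")
  expect_false(near$significant)
})

test_that("case dropping with redundant rows stays maximally stable", {
  base <- chain_cohort(5, 150, seed = 55, weight = 0.45)
  dup <- base[rep(seq_len(nrow(base)), each = 4), ]
  # single-community fixture: the constant bridge-EI index is dropped
  cd <- suppressWarnings(
    case_dropping(dup, proportions = c(0.25, 0.5), B = 10, seed = 4,
                  estimator = lean_estimator()))
  med <- tapply(cd$samples$correlation, cd$samples$proportion,
                median, na.rm = TRUE)
  expect_true(all(med > 0.95))
})

test_that("no dropping reproduces the full-sample centrality exactly", {
  co <- chain_cohort(5, 200, seed = 66, weight = 0.4)
  cd <- suppressWarnings(
    case_dropping(co, proportions = 0, B = 2, seed = 9,
                  estimator = lean_estimator()))
  expect_true(all(cd$samples$correlation > 1 - 1e-12))
})

test_that("subsets too small to estimate are skipped with a warning", {
  co <- chain_cohort(5, 20, seed = 3)
  expect_warning(
    cd <- case_dropping(co, proportions = c(0.1, 0.75), B = 2,
                        seed = 1, estimator = lean_estimator()),
    "skipped")
  expect_false(0.75 %in% cd$samples$proportion)
})

test_that("CS-coefficient implements its definition on fixed grids", {
  grid <- seq(0.05, 0.75, by = 0.05)
  # perfect stability: all correlations 1 -> CS at the grid maximum
  all_one <- tidyr::crossing(proportion = grid, replicate = 1:20,
                             index = "strength")
  all_one$correlation <- 1
  expect_equal(cs_coefficient(all_one)$cs, 0.75)
  # no stability: all correlations 0 -> CS = 0
  all_zero <- all_one
  all_zero$correlation <- 0
  expect_equal(cs_coefficient(all_zero)$cs, 0)
  # stability up to q = 0.25 only
  partial <- all_one
  partial$correlation <- ifelse(partial$proportion <= 0.25, 0.9, 0.3)
  expect_equal(cs_coefficient(partial)$cs, 0.25)
})

test_that("CS-coefficient is monotone in threshold and probability", {
  set.seed(31)
  grid <- seq(0.05, 0.75, by = 0.05)
  samp <- tidyr::crossing(proportion = grid, replicate = 1:30,
                          index = "ei")
  # correlations decay with the dropped proportion, with noise
  samp$correlation <- pmin(1, pmax(-1, 1 - samp$proportion +
                                     rnorm(nrow(samp), 0, 0.15)))
  for (i in 1:5) {
    t1 <- runif(1, 0.3, 0.6); t2 <- t1 + runif(1, 0.05, 0.3)
    expect_gte(cs_coefficient(samp, cor_threshold = t1)$cs,
               cs_coefficient(samp, cor_threshold = t2)$cs)
    p1 <- runif(1, 0.5, 0.8); p2 <- p1 + runif(1, 0.05, 0.19)
    expect_gte(cs_coefficient(samp, prob = p1)$cs,
               cs_coefficient(samp, prob = p2)$cs)
  }
})

test_that("predictive-betweenness bootstrap reflects the true topology", {
  # star truth centred on the focal node: nothing mediates
  p <- 5
  star <- make_ground_truth(
    communities = setNames(rep("a", p), paste0("V", 1:p)), sparsity = 0,
    edge_spec = data.frame(from = "V1", to = paste0("V", 2:p),
                           weight = 0.35))
  co_s <- generate_cohort(star, 2000, default_type = "continuous", seed = 8)
  pb_s <- bootstrap_predictive_betweenness(co_s, "V1", B = 30, seed = 12,
                                           estimator = lean_estimator())
  expect_true(all(pb_s$summary$boot_median == 0))
  # chain truth: the node adjacent to the focal mediates everything
  co_c <- chain_cohort(5, 2000, seed = 9, weight = 0.4)
  pb_c <- bootstrap_predictive_betweenness(co_c, "V1", B = 30, seed = 13,
                                           estimator = lean_estimator())
  top <- pb_c$summary$node[which.max(pb_c$summary$boot_median)]
  expect_equal(top, "V2")
  # determinism
  pb_c2 <- bootstrap_predictive_betweenness(co_c, "V1", B = 30, seed = 13,
                                            estimator = lean_estimator())
  expect_identical(pb_c$summary, pb_c2$summary)
})
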