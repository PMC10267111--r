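# Ground-truth construction and cohort generation: the generator must have
# exactly the latent-Gaussian structure the downstream estimators assume.

test_that("ground truth honours requested support and weights", {
  # no edges requested -> zero off-diagonal partials
  gt0 <- make_ground_truth(p = 3, sparsity = 0, seed = 1)
  expect_equal(gt0$partials, matrix(0, 3, 3,
                                    dimnames = dimnames(gt0$partials)))
  # two nodes, one edge: implied partial equals the requested weight
  gt2 <- make_ground_truth(
    communities = c(A = "x", B = "x"), sparsity = 0,
    edge_spec = data.frame(from = "A", to = "B", weight = 0.3))
  expect_equal(gt2$partials["A", "B"], 0.3, tolerance = 1e-12)
})

test_that("random ground truth is positive-definite with calibrated density", {
  gt <- make_ground_truth(p = 28, sparsity = 0.15, seed = 1)
  ev <- eigen(gt$precision, symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), 0)
  off <- gt$partials[upper.tri(gt$partials)]
  expect_lt(abs(mean(off != 0) - 0.15), 0.05)
  # partials identity and symmetry
  Theta <- gt$precision
  d <- sqrt(diag(Theta))
  expect_equal(gt$partials, -Theta / outer(d, d) + diag(28),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("binary prevalence converges to the normal-CDF of its threshold", {
  thr <- qnorm(0.69)  # target prevalence 0.31
  gt <- make_ground_truth(p = 2, sparsity = 0, seed = 1)
  spec <- tibble::tibble(
    node = gt$nodes, type = "binary", community = "all",
    par = list(list(thresholds = thr), list(thresholds = thr)))
  co <- generate_cohort(gt, 50000, node_spec = spec, seed = 7)
  expect_lt(abs(mean(co$V1) - 0.31), 0.01)
  expect_lt(abs(mean(co$V2) - 0.31), 0.01)
})

test_that("ordinal category frequencies match the Phi-implied probabilities", {
  cuts <- c(-1.5, -0.5, 0.5, 1.5)
  gt <- make_ground_truth(p = 2, sparsity = 0, seed = 1)
  co <- generate_cohort(gt, 50000, seed = 11)  # default ordinal thresholds
  want <- diff(pnorm(c(-Inf, cuts, Inf)))
  got <- as.vector(table(factor(co$V1, levels = 0:4))) / 50000
  expect_lt(max(abs(got - want)), 0.01)
})

test_that("generation is deterministic given the seed", {
  gt <- study_truth()
  a <- simulate_study_cohort(n = 120, seed = 9, truth = gt)
  b <- simulate_study_cohort(n = 120, seed = 9, truth = gt)
  expect_identical(as.data.frame(a), as.data.frame(b))
  c <- simulate_study_cohort(n = 120, seed = 10, truth = gt)
  expect_false(identical(as.data.frame(a), as.data.frame(c)))
})

test_that("default study cohort matches the designed layout", {
  co <- simulate_study_cohort(n = 300, seed = 2)
  expect_equal(ncol(co), 30)  # 24 HAMD + SI/SP/SA + ACTH + Cort + gender
  types <- cohort_types(co)
  expect_equal(sum(types == "ordinal"), 24)
  expect_equal(sum(types == "binary"), 3)
  expect_equal(sum(types == "continuous"), 2)
  expect_true(all(co$ACTH > 0) && all(co$Cort > 0))
  expect_true(all(unlist(co[paste0("HAMD", 1:24)]) %in% 0:4))
  expect_setequal(unique(co$gender), c("female", "male"))
})

test_that("estimation pipeline recovers the generating network", {
  # mixed-type cohort from a truth with strong edges: every true edge sign
  # recovered, and >= 90% of true non-edges estimated below 0.05
  comm <- c(O1 = "a", O2 = "a", O3 = "a", O4 = "a", O5 = "a", O6 = "a",
            B1 = "b", B2 = "b", C1 = "c", C2 = "c")
  es <- tibble::tribble(
    ~from, ~to, ~weight,
    "O1", "O2", 0.3, "O2", "O3", 0.25, "O4", "O5", -0.25,
    "B1", "B2", 0.3, "C1", "C2", 0.3, "O6", "C1", 0.25, "B1", "O1", 0.2)
  gt <- make_ground_truth(communities = comm, sparsity = 0, edge_spec = es)
  spec <- tibble::tibble(
    node = names(comm),
    type = rep(c("ordinal", "binary", "continuous"), c(6, 2, 2)),
    community = unname(comm),
    par = c(rep(list(list(thresholds = c(-1, -0.2, 0.6, 1.4))), 6),
            rep(list(list(thresholds = 0.5)), 2),
            rep(list(list(meanlog = 1, sdlog = 0.6)), 2)))
  co <- generate_cohort(gt, 5000, node_spec = spec, seed = 31)
  net <- ebic_glasso(co)
  W <- net$weights[names(comm), names(comm)]
  truth <- gt$partials
  ut <- upper.tri(W)
  is_edge <- truth != 0 & ut
  expect_true(all(sign(W[is_edge]) == sign(truth[is_edge])))
  non_edge <- truth == 0 & ut
  expect_gte(mean(abs(W[non_edge]) < 0.05), 0.9)
})

test_that("cohort CSV + metadata sidecar round-trips", {
  co <- simulate_study_cohort(n = 60, seed = 3)
  path <- file.path(tempdir(), "cohort.csv")
  write_cohort(co, path)
  expect_true(file.exists(paste0(path, ".meta.json")))
  back <- read_cohort(path)
  expect_equal(as.data.frame(back), as.data.frame(co), ignore_attr = TRUE)
  expect_equal(cohort_types(back), cohort_types(co))
  expect_equal(cohort_communities(back), cohort_communities(co))
  unlink(c(path, paste0(path, ".meta.json")))
})
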