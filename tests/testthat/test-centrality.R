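# Centrality measures against hand computations and the brute-force path
# enumeration oracle.

test_that("expected influence and strength match hand sums", {
  W <- toy_net(list("A", "B", 0.3), list("A", "C", -0.2))
  ei <- expected_influence(W)
  a <- ei[ei$node == "A", ]
  expect_equal(a$expected_influence, 0.1)
  expect_equal(a$strength, 0.5)
  # all-positive network: EI equals strength everywhere
  Wp <- random_weights(6, seed = 2, allow_negative = FALSE)
  eip <- expected_influence(Wp)
  expect_equal(eip$expected_influence, eip$strength)
  # empty network
  e0 <- expected_influence(matrix(0, 3, 3,
                                  dimnames = rep(list(c("A", "B", "C")), 2)))
  expect_true(all(e0$expected_influence == 0))
})

test_that("EI never exceeds strength", {
  for (s in 1:10) {
    W <- random_weights(6, seed = s)
    ei <- expected_influence(W)
    expect_true(all(abs(ei$expected_influence) <= ei$strength + 1e-12))
  }
})

test_that("bridge EI sums only cross-community edges", {
  W <- toy_net(list("A", "B", 0.2), list("A", "C", 0.4))
  comm <- c(A = "g1", B = "g1", C = "g2")
  b <- bridge_expected_influence(W, comm)
  expect_equal(b$bridge_expected_influence[b$node == "A"], 0.4)
  # single community: all zero
  b1 <- bridge_expected_influence(W, c(A = "g", B = "g", C = "g"))
  expect_true(all(b1$bridge_expected_influence == 0))
  # two-node bridge: both ends carry the edge weight
  W2 <- toy_net(list("A", "B", 0.33))
  b2 <- bridge_expected_influence(W2, c(A = "x", B = "y"))
  expect_equal(b2$bridge_expected_influence, c(0.33, 0.33))
  # unlabeled node is named in the failure
  expect_error(bridge_expected_influence(W, c(A = "g1", B = "g1")), "C")
})

test_that("betweenness matches hand counts on canonical graphs", {
  # path graph: only the interior node scores
  Wp <- toy_net(list("A", "B", 0.5), list("B", "C", 0.2))
  b <- node_betweenness(Wp)
  expect_equal(b$betweenness, c(0, 1, 0))
  # complete triangle with equal weights: direct edges always win
  Wt <- toy_net(list("A", "B", 0.4), list("B", "C", 0.4),
                list("A", "C", 0.4))
  expect_true(all(node_betweenness(Wt)$betweenness == 0))
})

test_that("betweenness agrees with exhaustive enumeration", {
  for (s in 1:30) {
    p <- sample(4:7, 1)
    W <- random_weights(p, seed = 100 + s, density = 0.45)
    got <- node_betweenness(W)
    want <- brute_betweenness(W)
    expect_equal(got$betweenness, unname(want[got$node]), tolerance = 1e-9)
  }
})

test_that("predictive betweenness counts focal-anchored paths", {
  Wp <- toy_net(list("A", "B", 0.5), list("B", "C", 0.2))
  pb <- predictive_betweenness(Wp, "A")
  expect_equal(pb$predictive_betweenness[pb$node == "B"], 1)
  expect_equal(pb$predictive_betweenness[pb$node == "C"], 0)
  expect_true(is.na(pb$predictive_betweenness[pb$node == "A"]))
  # star centred on the focal node: every connection is direct
  Ws <- toy_net(list("F", "A", 0.3), list("F", "B", 0.2),
                list("F", "C", 0.4))
  pbs <- predictive_betweenness(Ws, "F")
  expect_true(all(pbs$predictive_betweenness[pbs$node != "F"] == 0))
  expect_error(predictive_betweenness(Wp, "Z"), "Z")
})

test_that("predictive betweenness agrees with exhaustive enumeration", {
  for (s in 1:30) {
    p <- sample(4:7, 1)
    W <- random_weights(p, seed = 300 + s, density = 0.45)
    focal <- colnames(W)[1 + (s %% p)]
    got <- predictive_betweenness(W, focal)
    want <- brute_predictive(W, focal)
    expect_equal(got$predictive_betweenness, unname(want[got$node]),
                 tolerance = 1e-9)
  }
})

test_that("summed predictive betweenness respects the pair bound", {
  for (s in 1:10) {
    W <- random_weights(7, seed = 500 + s, density = 0.6)
    pb <- predictive_betweenness(W, "A")
    tot <- sum(pb$predictive_betweenness, na.rm = TRUE)
    expect_lte(tot, 6 * 5)
  }
})

test_that("centralities are equivariant under node relabelling", {
  W <- random_weights(6, seed = 9)
  comm <- setNames(rep(c("x", "y"), 3), colnames(W))
  perm <- c(4, 2, 6, 1, 3, 5)
  Wp <- W[perm, perm]
  a <- centrality(W, communities = comm)
  b <- centrality(Wp, communities = comm)
  b <- b[match(a$node, b$node), ]
  expect_equal(a$expected_influence, b$expected_influence)
  expect_equal(a$betweenness, b$betweenness)
  expect_equal(a$bridge_expected_influence, b$bridge_expected_influence)
})

test_that("flow view orders direct neighbours by absolute weight", {
  W <- toy_net(list("F", "A", 0.5), list("F", "B", -0.3),
               list("F", "C", 0.1), list("C", "D", 0.4),
               nodes = c("F", "A", "B", "C", "D", "E"))
  fl <- flow_edges(W, "F")
  direct <- fl[fl$relation == "direct", ]
  expect_equal(direct$node, c("A", "B", "C"))
  expect_equal(direct$weight, c(0.5, -0.3, 0.1))
  expect_equal(fl$relation[fl$node == "D"], "indirect")
  expect_equal(fl$relation[fl$node == "E"], "unreachable")
  # isolated focal node
  W0 <- matrix(0, 3, 3, dimnames = rep(list(c("F", "A", "B")), 2))
  fl0 <- flow_edges(W0, "F")
  expect_equal(sum(fl0$relation == "direct"), 0)
})

test_that("strongest edges rank by |weight| with lexicographic ties", {
  W <- toy_net(list("A", "B", 0.4), list("B", "C", -0.5),
               list("A", "C", 0.1))
  top2 <- strongest_edges(W, 2)
  expect_equal(top2$node_i, c("B", "A"))
  expect_equal(top2$node_j, c("C", "B"))
  expect_equal(top2$weight, c(-0.5, 0.4))
  # k exceeding the edge count returns everything
  expect_equal(nrow(strongest_edges(W, 10)), 3)
  # empty network
  expect_equal(nrow(strongest_edges(matrix(0, 2, 2), 1)), 0)
  # ties break on the lexicographic node pair
  Wt <- toy_net(list("B", "D", 0.3), list("A", "C", -0.3))
  tt <- strongest_edges(Wt, 2)
  expect_equal(tt$node_i, c("A", "B"))
})
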