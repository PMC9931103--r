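test_that("degree and strength follow their definitions", {
  W <- matrix(0, 4, 4)
  W[1, 2] <- W[2, 1] <- 0.5
  W[1, 3] <- W[3, 1] <- -0.3
  net <- toyNetwork(W)
  ds <- degreeStrength(net)
  expect_equal(unname(ds$degree), c(2, 1, 1, 0))
  expect_equal(unname(ds$strength), c(0.8, 0.5, 0.3, 0))
  expect_equal(unname(ds$expected_influence), c(0.2, 0.5, -0.3, 0))
  # isolated node scores zero everywhere
  expect_equal(unname(ds$degree[4]), 0)
  # brute-force row scan on random networks
  set.seed(21)
  for (rep in 1:10) {
    W <- randomWeights(17, 0.3)
    ds <- degreeStrength(toyNetwork(W, genericBattery(17)))
    for (i in 1:17) {
      expect_equal(unname(ds$degree[i]), sum(W[i, -i] != 0))
      expect_equal(unname(ds$strength[i]), sum(abs(W[i, -i])))
    }
  }
})

test_that("blended degree hits its formula and limits", {
  expect_equal(blendedDegree(3, 1.5, 0.5), sqrt(3 * 1.5))
  expect_equal(blendedDegree(0, 0, 0.5), 0)
  expect_equal(blendedDegree(0, 0, 0), 0)
  set.seed(22)
  for (rep in 1:50) {
    W <- randomWeights(sample(5:17, 1), 0.4)
    ds <- degreeStrength(toyNetwork(W, genericBattery(nrow(W))))
    expect_identical(blendedDegree(ds$degree, ds$strength, 0), ds$degree)
    expect_identical(blendedDegree(ds$degree, ds$strength, 1), ds$strength)
  }
})

test_that("single-edge and detour distances follow the Dijkstra rule", {
  W <- matrix(0, 2, 2); W[1, 2] <- W[2, 1] <- 0.5
  p <- shortestPaths(toyNetwork(W))
  expect_equal(p$distances[1, 2], 2)

  # strong-ties detour beats the weak direct tie
  W <- matrix(0, 3, 3)
  W[1, 3] <- W[3, 1] <- 0.1
  W[1, 2] <- W[2, 1] <- 1
  W[2, 3] <- W[3, 2] <- 1
  p <- shortestPaths(toyNetwork(W))
  expect_equal(p$distances[1, 3], 2)
  expect_equal(p$counts[1, 3], 1)

  # alpha rescales the trade-off: small alpha discounts weights enough
  # that the single weak direct tie beats the two-hop detour
  p2 <- shortestPaths(toyNetwork(W), alpha = 0.2)
  expect_equal(p2$distances[1, 3], 10^0.2)
})

test_that("tied shortest paths are counted with tolerance", {
  # 4-cycle with equal weights: two tied paths between opposite corners
  W <- matrix(0, 4, 4)
  for (e in list(c(1, 2), c(2, 3), c(3, 4), c(4, 1)))
    W[e[1], e[2]] <- W[e[2], e[1]] <- 0.5
  p <- shortestPaths(toyNetwork(W))
  expect_equal(p$distances[1, 3], 4)
  expect_equal(p$counts[1, 3], 2)
  cb <- nodeBetweenness(p)
  expect_equal(unname(cb), rep(0.5, 4))  # each corner carries half a path
})

test_that("star and complete graphs give the textbook betweenness", {
  W <- matrix(0, 5, 5)
  W[1, 2:5] <- W[2:5, 1] <- 0.7
  cb <- nodeBetweenness(shortestPaths(toyNetwork(W)))
  expect_equal(unname(cb), c(6, 0, 0, 0, 0))

  Wc <- matrix(0.4, 4, 4); diag(Wc) <- 0
  cbc <- nodeBetweenness(shortestPaths(toyNetwork(Wc)))
  expect_equal(unname(cbc), rep(0, 4))
})

test_that("closeness matches its reciprocal-distance definition", {
  W <- matrix(0, 2, 2); W[1, 2] <- W[2, 1] <- 1
  cl <- nodeCloseness(shortestPaths(toyNetwork(W)))
  expect_equal(unname(cl), c(1, 1))

  W <- matrix(0, 3, 3)
  W[1, 2] <- W[2, 1] <- 1
  W[2, 3] <- W[3, 2] <- 1
  cl <- nodeCloseness(shortestPaths(toyNetwork(W)))
  expect_equal(unname(cl), c(1 / 3, 1 / 2, 1 / 3))
  # isolated node scores 0; others ignore it
  W4 <- rbind(cbind(W, 0), 0)
  cl4 <- nodeCloseness(shortestPaths(toyNetwork(W4)))
  expect_equal(unname(cl4[4]), 0)
  expect_equal(unname(cl4[1:3]), unname(cl))
})

test_that("path measures match exhaustive enumeration on random graphs", {
  set.seed(23)
  for (rep in 1:30) {
    n <- sample(4:7, 1)
    W <- randomWeights(n, 0.5)
    net <- toyNetwork(W, genericBattery(n))
    p <- shortestPaths(net)
    o <- oraclePaths(W)
    expect_equal(unname(p$distances), o$distances, tolerance = 1e-9)
    expect_equal(unname(p$counts), o$counts)
    expect_equal(unname(nodeBetweenness(p)), o$betweenness, tolerance = 1e-9)
    expect_equal(unname(nodeCloseness(p)), o$closeness, tolerance = 1e-9)
  }
})

test_that("distances and betweenness agree with igraph", {
  skip_if_not_installed("igraph")
  set.seed(24)
  for (rep in 1:10) {
    n <- sample(5:9, 1)
    W <- randomWeights(n, 0.5)
    net <- toyNetwork(W, genericBattery(n))
    p <- shortestPaths(net)
    g <- igraph::graph_from_adjacency_matrix(abs(W), mode = "undirected",
                                             weighted = TRUE)
    D <- igraph::distances(g, weights = 1 / igraph::E(g)$weight)
    expect_equal(unname(p$distances), unname(D), tolerance = 1e-9)
    cb <- igraph::betweenness(g, weights = 1 / igraph::E(g)$weight)
    expect_equal(unname(nodeBetweenness(p)), unname(cb), tolerance = 1e-6)
  }
})

test_that("scaling all weights rescales path measures covariantly", {
  set.seed(25)
  W <- randomWeights(7, 0.6)
  net <- toyNetwork(W, genericBattery(7))
  for (a in c(0.5, 1, 2)) {
    p1 <- shortestPaths(net, alpha = a)
    p2 <- shortestPaths(toyNetwork(3 * W, genericBattery(7)), alpha = a)
    fin <- is.finite(p1$distances)
    expect_equal(p2$distances[fin], p1$distances[fin] * 3^(-a),
                 tolerance = 1e-12)
    expect_equal(nodeBetweenness(p2), nodeBetweenness(p1), tolerance = 1e-12)
    expect_equal(nodeCloseness(p2), nodeCloseness(p1) * 3^a,
                 tolerance = 1e-12)
  }
})

test_that("degree-1 nodes have zero betweenness", {
  set.seed(26)
  for (rep in 1:10) {
    W <- randomWeights(8, 0.3)
    net <- toyNetwork(W, genericBattery(8))
    cb <- nodeBetweenness(shortestPaths(net))
    deg <- rowSums(W != 0)
    expect_true(all(cb[deg <= 1] == 0))
  }
})

test_that("the centrality table standardizes each measure", {
  set.seed(27)
  W <- randomWeights(17, 0.25)
  tab <- centralityTable(toyNetwork(W, genericBattery(17)))
  expect_equal(nrow(tab), 17)
  expect_lt(abs(mean(tab$z_strength)), 1e-12)
  expect_equal(sd(tab$z_strength), 1, tolerance = 1e-12)
  expect_equal(tab$blended_degree, tab$strength)  # alpha = 1 default

  empty <- centralityTable(toyNetwork(matrix(0, 17, 17), genericBattery(17)))
  expect_true(all(empty$degree == 0))
  expect_true(all(empty$betweenness == 0))
  expect_true(all(empty$z_strength == 0))  # sd = 0 rule
})
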