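test_that("perfect monotone pairs give rho of +/-1 with p = 0", {
  b <- genericBattery(3)
  X <- cbind(1:5, 2 * (1:5), 5:1)
  est <- spearmanMatrix(scoreTableFromMatrix(X, b))
  expect_equal(est$rho[1, 2], 1)
  expect_equal(est$p[1, 2], 0)
  expect_equal(est$rho[1, 3], -1)
  expect_equal(est$p[1, 3], 0)
})

test_that("tied data match the rank-then-Pearson oracle", {
  b <- genericBattery(2)
  x <- c(1, 2, 3, 4, 5)
  y <- c(3, 1, 4, 1, 5)
  est <- spearmanMatrix(scoreTableFromMatrix(cbind(x, y), b))
  expect_equal(est$rho[1, 2], oracleSpearman(x, y), tolerance = 1e-12)
  # heavy-tie stress over random integer-valued columns
  set.seed(42)
  for (rep in 1:25) {
    x <- sample(0:4, 30, replace = TRUE)
    y <- sample(0:3, 30, replace = TRUE)
    est <- spearmanMatrix(scoreTableFromMatrix(cbind(x, y), b))
    expect_equal(est$rho[1, 2], oracleSpearman(x, y), tolerance = 1e-12)
  }
})

test_that("the t-approximation p-value follows its closed form", {
  b <- genericBattery(2)
  set.seed(7)
  x <- rnorm(20); y <- 0.5 * x + rnorm(20)
  est <- spearmanMatrix(scoreTableFromMatrix(cbind(x, y) * 10 + 50, b))
  r <- est$rho[1, 2]; n <- 20
  tv <- r * sqrt((n - 2) / (1 - r^2))
  expect_equal(est$p[1, 2], 2 * pt(abs(tv), n - 2, lower.tail = FALSE))
})

test_that("spearman is invariant under strictly monotone transforms", {
  b <- genericBattery(3)
  set.seed(8)
  X <- matrix(runif(60, 1, 99), 20, 3)
  est1 <- spearmanMatrix(scoreTableFromMatrix(X, b))
  X2 <- X; X2[, 2] <- X[, 2]^3 / 1e4  # strictly increasing transform
  est2 <- spearmanMatrix(scoreTableFromMatrix(X2, b))
  expect_equal(est1$rho, est2$rho, tolerance = 1e-12)
})

test_that("missing policies differ and report complete cases per pair", {
  b <- genericBattery(3)
  set.seed(9)
  X <- matrix(runif(90, 1, 99), 30, 3)
  X[1:5, 1] <- NA
  st <- scoreTableFromMatrix(X, b)
  el <- spearmanMatrix(st, missing = "complete_rows")
  ep <- spearmanMatrix(st, missing = "pairwise")
  expect_equal(unique(as.vector(el$nPairs)), 25)
  expect_equal(ep$nPairs[2, 3], 30)
  expect_equal(ep$nPairs[1, 2], 25)
  expect_error(
    spearmanMatrix(scoreTableFromMatrix(rbind(X[1:2, ], NA * X[1, ]), b)),
    "fewer than 3")
})

test_that("permutation p-values broadly agree with the t approximation", {
  b <- genericBattery(2)
  set.seed(10)
  x <- rnorm(25); y <- 0.7 * x + 0.5 * rnorm(25)
  st <- scoreTableFromMatrix(cbind(x, y) * 5 + 50, b)
  ep <- spearmanMatrix(st, pMethod = "permutation", nPerm = 2000)
  et <- spearmanMatrix(st)
  expect_lt(ep$p[1, 2], 0.05)
  expect_lt(abs(ep$p[1, 2] - et$p[1, 2]), 0.05)
  # seeded: reproducible
  ep2 <- spearmanMatrix(st, pMethod = "permutation", nPerm = 2000)
  expect_identical(ep$p, ep2$p)
})

test_that("thresholding keeps exactly the significant signed weights", {
  b <- genericBattery(3)
  rho <- matrix(c(1, 0.8, 0.5, 0.8, 1, 0, 0.5, 0, 1), 3,
                dimnames = list(nodeLabels(b), nodeLabels(b)))
  p <- matrix(c(0, 0.01, 0.2, 0.01, 0, 0.9, 0.2, 0.9, 0), 3,
              dimnames = dimnames(rho))
  est <- structure(list(rho = rho, p = p,
                        nPairs = matrix(50L, 3, 3, dimnames = dimnames(rho))),
                   class = "CorrelationEstimate")
  net <- thresholdNetwork(est, b, alpha = 0.05)
  w <- networkWeights(net)
  expect_equal(w[1, 2], 0.8)
  expect_equal(w[1, 3], 0)
  expect_equal(diag(w), setNames(rep(0, 3), nodeLabels(b)))
  # all p = 1: empty network
  p1 <- p; p1[] <- 1
  est$p <- p1
  expect_true(all(networkWeights(thresholdNetwork(est, b)) == 0))
  expect_error(thresholdNetwork(est, b, alpha = 0), "alpha")
  expect_error(thresholdNetwork(est, b, alpha = 1.2), "alpha")
})

test_that("the edge set is monotone in alpha", {
  set.seed(12)
  X <- matrix(rnorm(17 * 60), 60, 17) * 8 + 50
  st <- scoreTableFromMatrix(X, genericBattery(17))
  est <- spearmanMatrix(st)
  alphas <- c(0.001, 0.01, 0.05, 0.2, 1)
  prev <- NULL
  for (a in alphas) {
    edges <- adjacencyMatrix(thresholdNetwork(est, st@battery, alpha = a))
    if (!is.null(prev)) expect_true(all(edges >= prev))
    prev <- edges
  }
  # alpha = 1 retains every pair with p < 1
  expect_equal(sum(prev[upper.tri(prev)] == 1), sum(est$p[upper.tri(est$p)] < 1))
})

test_that("network estimation is equivariant under node permutation", {
  set.seed(13)
  X <- matrix(rnorm(8 * 50), 50, 8) * 8 + 50
  b <- genericBattery(8)
  net1 <- estimateNetwork(scoreTableFromMatrix(X, b))
  perm <- sample(8)
  bp <- Battery(batteryItems(b)[perm, ], name = "perm")
  net2 <- estimateNetwork(scoreTableFromMatrix(X[, perm], bp))
  expect_equal(networkWeights(net2),
               networkWeights(net1)[perm, perm])
})

test_that("Holm adjustment never adds edges", {
  set.seed(14)
  X <- matrix(rnorm(10 * 40), 40, 10) * 8 + 50
  st <- scoreTableFromMatrix(X, genericBattery(10))
  est <- spearmanMatrix(st)
  plain <- adjacencyMatrix(thresholdNetwork(est, st@battery))
  holm <- adjacencyMatrix(thresholdNetwork(est, st@battery, adjust = "holm"))
  expect_true(all(holm <= plain))
})

test_that("domain connectivity counts blocks and bridge nodes", {
  b <- toyBattery(2, 1, 2)  # N1 N2 A1 P1 P2
  W <- matrix(0, 5, 5)
  W[1, 2] <- W[2, 1] <- 0.5   # within neurocognitive
  W[4, 5] <- W[5, 4] <- -0.4  # within psychosocial
  net <- toyNetwork(W, b)
  dc <- domainConnectivity(net)
  expect_equal(dc$bridge_nodes, character(0))
  expect_true(all(dc$summary$edges[dc$summary$type == "between"] == 0))
  expect_equal(dc$summary$density[dc$summary$block == "neurocognitive"], 1)
  # one bridge edge N1-P1
  W[1, 4] <- W[4, 1] <- 0.3
  dc2 <- domainConnectivity(toyNetwork(W, b))
  expect_equal(sort(dc2$bridge_nodes), c("N1", "P1"))
  s <- dc2$summary
  expect_equal(s$edges[s$block == "neurocognitive:psychosocial"], 1)
  expect_equal(s$possible[s$block == "neurocognitive:psychosocial"], 4)
})

test_that("a complete 9-node block has density exactly 1", {
  b <- defaultBattery()
  W <- matrix(0, 17, 17)
  nc <- which(nodeDomains(b) == "neurocognitive")
  W[nc, nc] <- 0.5
  diag(W) <- 0
  dc <- domainConnectivity(toyNetwork(W, b))
  s <- dc$summary
  expect_equal(s$edges[s$block == "neurocognitive"], 36)
  expect_equal(s$density[s$block == "neurocognitive"], 1)
})
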