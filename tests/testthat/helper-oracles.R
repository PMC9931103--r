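# Independent oracles and fixture builders. These deliberately avoid the
# package's own code paths (and, for Spearman, base rank()/cor()).

# average ranks computed from first principles
oracleRanks <- function(x) {
  vapply(seq_along(x), function(i)
    sum(x < x[i]) + (sum(x == x[i]) + 1) / 2, numeric(1))
}

# Spearman rho as the Pearson correlation of average ranks, by the sum
# formulas
oracleSpearman <- function(x, y) {
  a <- oracleRanks(x); b <- oracleRanks(y)
  am <- a - mean(a); bm <- b - mean(b)
  den <- sqrt(sum(am^2) * sum(bm^2))
  if (den == 0) return(0)
  sum(am * bm) / den
}

# exhaustive enumeration of simple paths: distances, shortest-path counts
# (ties within relative tolerance rtol), betweenness with fractional tie
# credit, and closeness. Only feasible for small n.
oraclePaths <- function(W, alpha = 1, rtol = 1e-9) {
  n <- nrow(W)
  L <- ifelse(W != 0, (1 / abs(W))^alpha, Inf)
  D <- matrix(Inf, n, n); diag(D) <- 0
  G <- matrix(0, n, n); diag(G) <- 1
  CB <- numeric(n)
  nbr <- lapply(seq_len(n), function(i) which(is.finite(L[i, ])))
  tied <- function(a, b) abs(a - b) <= rtol * max(abs(a), abs(b), 1e-300)
  for (j in seq_len(n - 1)) for (k in (j + 1):n) {
    lens <- numeric(0)
    interiors <- list()
    best <- Inf
    visited <- rep(FALSE, n)
    dfs <- function(u, len, path) {
      if (u == k) {
        lens[length(lens) + 1] <<- len
        interiors[[length(lens)]] <<- path
        best <<- min(best, len)
        return(invisible())
      }
      visited[u] <<- TRUE
      for (v in nbr[[u]]) {
        if (visited[v]) next
        nl <- len + L[u, v]
        # anything clearly beyond the current best cannot tie it
        if (is.finite(best) && nl > best * (1 + 1e-6) && nl > best) next
        dfs(v, nl, if (u == j) path else c(path, u))
      }
      visited[u] <<- FALSE
      invisible()
    }
    dfs(j, 0, integer(0))
    if (length(lens)) {
      dmin <- min(lens)
      is_tied <- vapply(lens, tied, logical(1), b = dmin)
      g <- sum(is_tied)
      D[j, k] <- D[k, j] <- dmin
      G[j, k] <- G[k, j] <- g
      for (idx in which(is_tied))
        for (i in interiors[[idx]])
          CB[i] <- CB[i] + 1 / g
    }
  }
  CL <- vapply(seq_len(n), function(i) {
    d <- D[i, -i]; r <- is.finite(d)
    if (!any(r)) 0 else 1 / sum(d[r])
  }, numeric(1))
  list(distances = D, counts = G, betweenness = CB, closeness = CL)
}

# closed-form OLS R^2 via the normal equations, no lm machinery
oracleR2 <- function(X, y) {
  Z <- cbind(1, X)
  beta <- solve(t(Z) %*% Z, t(Z) %*% y)
  res <- y - Z %*% beta
  sst <- sum((y - mean(y))^2)
  max(0, 1 - sum(res^2) / sst)
}

# ---- fixture builders -----------------------------------------------------

toyBattery <- function(n_nc = 2, n_af = 1, n_ps = 2) {
  labs <- c(sprintf("N%d", seq_len(n_nc)), sprintf("A%d", seq_len(n_af)),
            sprintf("P%d", seq_len(n_ps)))
  Battery(data.frame(
    label = labs,
    full_name = labs,
    domain = c(rep("neurocognitive", n_nc), rep("affective", n_af),
               rep("psychosocial", n_ps)),
    score_min = 0, score_max = 100,
    orientation = "higher_is_better",
    stringsAsFactors = FALSE), name = "toy")
}

genericBattery <- function(n) {
  labs <- sprintf("V%02d", seq_len(n))
  Battery(data.frame(
    label = labs, full_name = labs,
    domain = rep(DOMAIN_LEVELS <- c("neurocognitive", "affective",
                                    "psychosocial"), length.out = n),
    score_min = 0, score_max = 100, orientation = "higher_is_better",
    stringsAsFactors = FALSE), name = sprintf("generic%d", n))
}

# wrap a weight matrix as a SymptomNetwork (p set to match the edges)
toyNetwork <- function(W, battery = genericBattery(nrow(W))) {
  labels <- nodeLabels(battery)
  dimnames(W) <- list(labels, labels)
  p <- ifelse(W != 0, 0.001, 1)
  diag(p) <- 0
  rho <- W; diag(rho) <- 1
  npairs <- matrix(100L, nrow(W), ncol(W), dimnames = dimnames(W))
  new("SymptomNetwork", battery = battery, weights = W, rho = rho, p = p,
      nPairs = npairs, threshold = 0.05, predictability = numeric(0))
}

# random signed weighted graph on n nodes
randomWeights <- function(n, p_edge = 0.5) {
  W <- matrix(0, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (stats::runif(1) < p_edge) {
      w <- stats::runif(1, 0.1, 1) * sample(c(-1, 1), 1)
      W[i, j] <- W[j, i] <- w
    }
  }
  W
}

scoreTableFromMatrix <- function(X, battery = genericBattery(ncol(X))) {
  colnames(X) <- nodeLabels(battery)
  ScoreTable(X, battery)
}
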