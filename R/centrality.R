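#' Degree and strength of every node
#'
#' Degree `k_i` counts the nonzero edges incident to node `i` (the row sum
#' of the adjacency indicator); strength `s_i` sums the absolute weights
#' of those edges (a strong negative correlation is a strong connection).
#' The signed sum is returned alongside as `expected_influence`.
#'
#' @param net a [SymptomNetwork-class].
#' @return list with numeric vectors `degree`, `strength`,
#'   `expected_influence`, named by node label.
#' @export
degreeStrength <- function(net) {
  stopifnot(is(net, "SymptomNetwork"))
  w <- net@weights
  list(degree = rowSums(w != 0),
       strength = rowSums(abs(w)),
       expected_influence = rowSums(w))
}

#' Tuning-parameter blend of degree and strength
#'
#' Opsahl's degree centrality `CD^{w,alpha}(i) = k_i^(1-alpha) * s_i^alpha`,
#' which interpolates between the number of connections (`alpha = 0`) and
#' their total weight (`alpha = 1`). An isolated node (`k = 0`) scores 0
#' for every alpha.
#'
#' @param k degree vector (>= 0).
#' @param s strength vector (>= 0).
#' @param alpha nonnegative tuning parameter.
#' @return numeric vector of blended centralities.
#' @export
blendedDegree <- function(k, s, alpha) {
  stopifnot(all(k >= 0), all(s >= 0), alpha >= 0)
  if (alpha == 0) return(k + 0)
  if (alpha == 1) return(s + 0)
  out <- ifelse(k == 0, 0, k^(1 - alpha) * s^alpha)
  names(out) <- names(k)
  out
}

# relative tolerance under which two path lengths count as tied
PATH_TIE_RTOL <- 1e-9

tiedLengths <- function(a, b) {
  is.finite(a) && is.finite(b) &&
    abs(a - b) <= PATH_TIE_RTOL * max(abs(a), abs(b), 1e-300)
}

#' Weighted shortest paths with multiplicities
#'
#' Edge `(i, j)` gets length `(1 / |w_ij|)^alpha`, so strong ties are
#' short: the distance between two nodes is the Dijkstra minimum
#' `d^{w,alpha}(i, j) = min(1/(w_ih)^alpha + ... + 1/(w_hj)^alpha)` over
#' paths, trading off the number of intermediate nodes against the weight
#' of the connections. The number of distinct shortest paths `g_jk` is
#' counted during the search; path lengths equal within a relative
#' tolerance of 1e-9 count as tied.
#'
#' @param net a [SymptomNetwork-class].
#' @param alpha positive tuning parameter (default 1: length `1/|w|`).
#' @return object of class `PathResult`: list with `distances` (symmetric,
#'   zero diagonal, `Inf` when unreachable), `counts` (`g_jk`; 0 when
#'   unreachable, 1 on the diagonal) and `alpha`.
#' @export
shortestPaths <- function(net, alpha = 1) {
  stopifnot(is(net, "SymptomNetwork"), alpha > 0)
  w <- abs(net@weights)
  labels <- nodeLabels(net)
  n <- nrow(w)
  len <- ifelse(w > 0, (1 / w)^alpha, Inf)
  D <- matrix(Inf, n, n, dimnames = list(labels, labels))
  G <- matrix(0, n, n, dimnames = list(labels, labels))
  for (s in seq_len(n)) {
    dist <- rep(Inf, n); dist[s] <- 0
    sigma <- rep(0, n); sigma[s] <- 1
    done <- rep(FALSE, n)
    for (step in seq_len(n)) {
      u <- which(!done & dist == suppressWarnings(min(dist[!done])))[1]
      if (!is.finite(dist[u])) break
      done[u] <- TRUE
      for (v in which(is.finite(len[u, ]) & !done)) {
        alt <- dist[u] + len[u, v]
        if (!is.finite(dist[v])) {
          dist[v] <- alt; sigma[v] <- sigma[u]
        } else if (tiedLengths(alt, dist[v])) {
          sigma[v] <- sigma[v] + sigma[u]
        } else if (alt < dist[v]) {
          dist[v] <- alt; sigma[v] <- sigma[u]
        }
      }
    }
    D[s, ] <- dist
    G[s, ] <- sigma
  }
  diag(D) <- 0
  diag(G) <- 1
  structure(list(distances = D, counts = G, alpha = alpha),
            class = "PathResult")
}

#' Per-pair through-counts for one node
#'
#' `g_jk(i)`: the number of shortest `j`-`k` paths passing through `i`,
#' from the counting identity
#' `g_jk(i) = g_ji * g_ik` when `d(j,i) + d(i,k)` ties `d(j,k)`.
#'
#' @param paths a `PathResult` from [shortestPaths()].
#' @param i node index.
#' @return matrix of through-counts over pairs `(j, k)`.
#' @keywords internal
throughCounts <- function(paths, i) {
  D <- paths$distances; G <- paths$counts
  n <- nrow(D)
  out <- matrix(0, n, n, dimnames = dimnames(D))
  for (j in seq_len(n)) for (k in seq_len(n)) {
    if (j == i || k == i || j == k) next
    if (is.finite(D[j, k]) && tiedLengths(D[j, i] + D[i, k], D[j, k]))
      out[j, k] <- G[j, i] * G[i, k]
  }
  out
}

#' Weighted betweenness centrality
#'
#' Freeman's betweenness on the Dijkstra shortest paths:
#' `CB^{w,alpha}(i)` sums `g_jk(i) / g_jk` over unordered pairs
#' `{j, k}` with `j != i != k`, giving fractional credit across tied
#' shortest paths and excluding endpoints.
#'
#' @param paths a `PathResult` from [shortestPaths()].
#' @return numeric vector of betweenness values, named by node label.
#' @export
nodeBetweenness <- function(paths) {
  D <- paths$distances; G <- paths$counts
  n <- nrow(D)
  cb <- stats::setNames(rep(0, n), rownames(D))
  for (i in seq_len(n)) {
    tc <- throughCounts(paths, i)
    acc <- 0
    for (j in seq_len(n - 1)) for (k in (j + 1):n) {
      if (j == i || k == i) next
      if (is.finite(D[j, k]) && G[j, k] > 0 && tc[j, k] > 0)
        acc <- acc + tc[j, k] / G[j, k]
    }
    cb[i] <- acc
  }
  cb
}

#' Weighted closeness centrality
#'
#' Reciprocal of the summed shortest-path distance from a node to every
#' node it can reach; an isolated node scores 0. `harmonic = TRUE`
#' instead averages reciprocal distances (robust to disconnection).
#'
#' @param paths a `PathResult` from [shortestPaths()].
#' @param harmonic use harmonic closeness.
#' @return numeric vector of closeness values, named by node label.
#' @export
nodeCloseness <- function(paths, harmonic = FALSE) {
  D <- paths$distances
  n <- nrow(D)
  out <- stats::setNames(rep(0, n), rownames(D))
  for (i in seq_len(n)) {
    d <- D[i, -i]
    reach <- is.finite(d) & d > 0
    if (!any(reach)) next
    out[i] <- if (harmonic) sum(1 / d[reach]) / (n - 1)
              else 1 / sum(d[reach])
  }
  out
}

zScore <- function(x) {
  s <- stats::sd(x)
  if (is.na(s) || s == 0) return(rep(0, length(x)))
  (x - mean(x)) / s
}

#' Full centrality table for a network
#'
#' Assembles degree, strength, expected influence, the tuning-parameter
#' blend, betweenness and closeness per node, plus z-standardized versions
#' of each measure across the nodes (the scale centrality profiles are
#' plotted on). Columns with zero spread standardize to 0.
#'
#' @param net a [SymptomNetwork-class].
#' @param alpha positive tuning parameter for the blend and path measures
#'   (default 1).
#' @param harmonic use harmonic closeness.
#' @return data.frame, one row per node: `label`, `domain`, raw measures
#'   (`degree`, `strength`, `expected_influence`, `blended_degree`,
#'   `betweenness`, `closeness`) and `z_`-prefixed standardized columns.
#' @export
centralityTable <- function(net, alpha = 1, harmonic = FALSE) {
  stopifnot(is(net, "SymptomNetwork"))
  ds <- degreeStrength(net)
  paths <- shortestPaths(net, alpha = alpha)
  tab <- data.frame(
    label = nodeLabels(net),
    domain = nodeDomains(net),
    degree = unname(ds$degree),
    strength = unname(ds$strength),
    expected_influence = unname(ds$expected_influence),
    blended_degree = unname(blendedDegree(ds$degree, ds$strength, alpha)),
    betweenness = unname(nodeBetweenness(paths)),
    closeness = unname(nodeCloseness(paths, harmonic = harmonic)),
    stringsAsFactors = FALSE)
  for (col in c("degree", "strength", "expected_influence",
                "blended_degree", "betweenness", "closeness"))
    tab[[paste0("z_", col)]] <- zScore(tab[[col]])
  tab
}
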