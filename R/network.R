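#' Pairwise Spearman correlation matrix with significance
#'
#' Computes rank correlations (average ranks for ties) for every item
#' pair, with two-sided p-values from the t approximation
#' `t = rho * sqrt((n - 2) / (1 - rho^2))` on `n - 2` degrees of freedom;
#' `|rho| = 1` gives `p = 0`. An exact seeded permutation p-value is
#' available for small samples, where the t approximation is rough.
#'
#' @param scores a [ScoreTable-class].
#' @param missing `"complete_rows"` (listwise deletion, default) or
#'   `"pairwise"` (complete cases per pair).
#' @param pMethod `"tapprox"` (default) or `"permutation"`.
#' @param nPerm number of permutations when `pMethod = "permutation"`.
#' @param permSeed seed for the permutation draw.
#' @return a list of class `CorrelationEstimate` with symmetric matrices
#'   `rho` (unit diagonal), `p`, and integer `nPairs` (complete cases per
#'   pair).
#' @export
spearmanMatrix <- function(scores, missing = c("complete_rows", "pairwise"),
                           pMethod = c("tapprox", "permutation"),
                           nPerm = 10000, permSeed = 1) {
  stopifnot(is(scores, "ScoreTable"))
  missing <- match.arg(missing)
  pMethod <- match.arg(pMethod)
  X <- scores@values
  if (missing == "complete_rows")
    X <- X[stats::complete.cases(X), , drop = FALSE]
  labels <- colnames(X)
  m <- ncol(X)
  rho <- diag(1, m)
  p <- matrix(0, m, m)
  npairs <- matrix(nrow(X), m, m)
  dimnames(rho) <- dimnames(p) <- dimnames(npairs) <- list(labels, labels)
  for (i in seq_len(m - 1)) for (j in (i + 1):m) {
    ok <- stats::complete.cases(X[, c(i, j)])
    n <- sum(ok)
    npairs[i, j] <- npairs[j, i] <- n
    if (n < 3)
      stop(sprintf("fewer than 3 complete observations for pair (%s, %s)",
                   labels[i], labels[j]))
    r <- spearmanRho(X[ok, i], X[ok, j])
    rho[i, j] <- rho[j, i] <- r
    pv <- if (pMethod == "tapprox") {
      spearmanPt(r, n)
    } else {
      spearmanPperm(X[ok, i], X[ok, j], r, nPerm,
                    permSeed + i * m + j)
    }
    p[i, j] <- p[j, i] <- pv
  }
  structure(list(rho = rho, p = p, nPairs = npairs),
            class = "CorrelationEstimate")
}

# Spearman rho = Pearson correlation of average ranks; a constant margin
# has no defined rank correlation and contributes rho = 0
spearmanRho <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) return(0)
  stats::cor(rx, ry)
}

spearmanPt <- function(r, n) {
  if (abs(r) >= 1) return(0)
  tv <- r * sqrt((n - 2) / (1 - r^2))
  2 * stats::pt(abs(tv), df = n - 2, lower.tail = FALSE)
}

spearmanPperm <- function(x, y, r0, nPerm, seed) {
  if (stats::sd(rank(x)) == 0 || stats::sd(rank(y)) == 0) return(1)
  rs <- withr::with_seed(as.integer(seed %% .Machine$integer.max), {
    vapply(seq_len(nPerm),
           function(k) spearmanRho(x, sample(y)), numeric(1))
  })
  (1 + sum(abs(rs) >= abs(r0) - 1e-12)) / (nPerm + 1)
}

#' Threshold a correlation estimate into a symptom network
#'
#' Retains edge `(i, j)` with weight `rho_ij` when `p_ij < alpha`; all
#' other weights are 0 ("in the absence of an edge, the relationship
#' is 0"). Signs are preserved. Optionally adjusts p-values for multiple
#' testing first.
#'
#' @param est a `CorrelationEstimate` from [spearmanMatrix()].
#' @param battery the [Battery-class] the estimate refers to.
#' @param alpha significance level in (0, 1] (default 0.05).
#' @param adjust multiple-testing adjustment applied to the off-diagonal
#'   p-values before thresholding: `"none"` (default), `"holm"` or `"BH"`.
#' @return a [SymptomNetwork-class].
#' @export
thresholdNetwork <- function(est, battery, alpha = 0.05,
                             adjust = c("none", "holm", "BH")) {
  stopifnot(is(battery, "Battery"))
  adjust <- match.arg(adjust)
  if (!is.numeric(alpha) || length(alpha) != 1 || alpha <= 0 || alpha > 1)
    stop("alpha must be a single value in (0, 1]")
  labels <- battery@items$label
  if (!identical(colnames(est$rho), labels))
    stop("correlation estimate does not match the battery")
  p <- est$p
  if (adjust != "none") {
    up <- upper.tri(p)
    adj <- stats::p.adjust(p[up], method = adjust)
    p[up] <- adj
    p <- t(p); p[up] <- adj; p <- t(p)  # restore symmetry
  }
  w <- est$rho * (p < alpha)
  diag(w) <- 0
  new("SymptomNetwork", battery = battery, weights = w, rho = est$rho,
      p = est$p, nPairs = est$nPairs, threshold = alpha,
      predictability = numeric(0))
}

#' Estimate a symptom network from scores in one step
#'
#' Convenience wrapper: [spearmanMatrix()] then [thresholdNetwork()].
#'
#' @inheritParams spearmanMatrix
#' @inheritParams thresholdNetwork
#' @return a [SymptomNetwork-class].
#' @export
estimateNetwork <- function(scores, alpha = 0.05,
                            missing = c("complete_rows", "pairwise"),
                            pMethod = c("tapprox", "permutation"),
                            adjust = c("none", "holm", "BH")) {
  est <- spearmanMatrix(scores, missing = missing, pMethod = pMethod)
  thresholdNetwork(est, scores@battery, alpha = alpha, adjust = adjust)
}

#' Domain-level connectivity summary
#'
#' Counts edges, edge density (edges over possible pairs) and mean
#' absolute weight within each domain and across each unordered domain
#' pair, and lists the bridge nodes (nodes with at least one inter-domain
#' edge).
#'
#' @param net a [SymptomNetwork-class].
#' @return a list with `summary` (data.frame: `block`, `type`
#'   (`"within"`/`"between"`), `edges`, `possible`, `density`,
#'   `mean_abs_weight`) and `bridge_nodes` (character vector).
#' @export
domainConnectivity <- function(net) {
  stopifnot(is(net, "SymptomNetwork"))
  w <- net@weights
  dom <- nodeDomains(net)
  labels <- nodeLabels(net)
  blocks <- list()
  for (d in DOMAIN_LEVELS) {
    idx <- which(dom == d)
    blocks[[d]] <- list(i = idx, j = idx, type = "within")
  }
  prs <- utils::combn(DOMAIN_LEVELS, 2)
  for (k in seq_len(ncol(prs))) {
    key <- domainPairKey(prs[1, k], prs[2, k])
    blocks[[key]] <- list(i = which(dom == prs[1, k]),
                          j = which(dom == prs[2, k]), type = "between")
  }
  rows <- lapply(names(blocks), function(nm) {
    b <- blocks[[nm]]
    if (b$type == "within") {
      sub <- w[b$i, b$j, drop = FALSE]
      vals <- sub[upper.tri(sub)]
      possible <- length(b$i) * (length(b$i) - 1) / 2
    } else {
      vals <- as.vector(w[b$i, b$j, drop = FALSE])
      possible <- length(b$i) * length(b$j)
    }
    ne <- sum(vals != 0)
    data.frame(block = nm, type = b$type, edges = ne, possible = possible,
               density = if (possible > 0) ne / possible else NA_real_,
               mean_abs_weight = if (ne > 0) mean(abs(vals[vals != 0]))
                                 else NA_real_,
               stringsAsFactors = FALSE)
  })
  summary <- do.call(rbind, rows)
  inter <- outer(dom, dom, `!=`) & w != 0
  bridge <- labels[rowSums(inter) > 0]
  list(summary = summary, bridge_nodes = bridge)
}
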