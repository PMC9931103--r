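#' Predictability of one node from its network neighbours
#'
#' Regresses the node's scores on the scores of the nodes it shares an
#' edge with (ordinary least squares with intercept) and returns the
#' proportion of explained variance `R^2 = 1 - SSE/SST`, floored at 0 —
#' the value drawn as the node's predictability ring. A node with no
#' neighbours scores exactly 0. Complete cases across the node and its
#' neighbours are used.
#'
#' @param scores a [ScoreTable-class] bound to the same battery as `net`.
#' @param net a [SymptomNetwork-class].
#' @param node item label.
#' @param ridge when the complete cases cannot support the OLS fit
#'   (fewer rows than parameters), fall back to a ridge fit with penalty
#'   `1e-3 * trace(X'X) / p` instead of erroring.
#' @return list with `predictability` (R^2 in \[0, 1\]), `rmse`, and
#'   `n_neighbors`.
#' @export
nodePredictability <- function(scores, net, node, ridge = FALSE) {
  stopifnot(is(scores, "ScoreTable"), is(net, "SymptomNetwork"))
  labels <- nodeLabels(net)
  if (!identical(nodeLabels(scores), labels))
    stop("scores and network must be bound to the same battery")
  i <- match(node, labels)
  if (is.na(i)) stop("unknown node label: ", node)
  nb <- which(net@weights[i, ] != 0)
  if (length(nb) == 0)
    return(list(predictability = 0, rmse = NA_real_, n_neighbors = 0L))
  X <- scores@values[, nb, drop = FALSE]
  y <- scores@values[, i]
  ok <- stats::complete.cases(cbind(y, X))
  y <- y[ok]; X <- X[ok, , drop = FALSE]
  n <- length(y); p <- ncol(X) + 1
  if (n < p + 1) {
    if (!ridge)
      stop(sprintf(paste0("node '%s': %d complete cases cannot support %d ",
                          "parameters; consider ridge = TRUE"), node, n, p))
    fitted <- ridgeFitted(X, y)
  } else {
    fit <- stats::lm.fit(cbind(1, X), y)
    fitted <- y - fit$residuals
  }
  sst <- sum((y - mean(y))^2)
  sse <- sum((y - fitted)^2)
  r2 <- if (sst == 0) 0 else max(0, 1 - sse / sst)
  list(predictability = min(r2, 1), rmse = sqrt(mean((y - fitted)^2)),
       n_neighbors = length(nb))
}

ridgeFitted <- function(X, y) {
  Xc <- scale(X, center = TRUE, scale = FALSE)
  yc <- y - mean(y)
  p <- ncol(Xc)
  G <- crossprod(Xc)
  lambda <- 1e-3 * sum(diag(G)) / p
  beta <- solve(G + diag(lambda, p), crossprod(Xc, yc))
  mean(y) + as.vector(Xc %*% beta)
}

#' Predictability of every node, with the cohort mean
#'
#' Applies [nodePredictability()] to each node; per-node estimation
#' failures are recorded in the table (with `NA` value) rather than
#' aborting. The cohort mean is the arithmetic mean over all nodes
#' (failed nodes excluded).
#'
#' @inheritParams nodePredictability
#' @return data.frame with one row per node (`label`, `domain`,
#'   `n_neighbors`, `predictability`, `rmse`, `error`) and attribute
#'   `cohort_mean`.
#' @export
predictabilityTable <- function(scores, net, ridge = FALSE) {
  labels <- nodeLabels(net)
  rows <- lapply(labels, function(lab) {
    res <- tryCatch(nodePredictability(scores, net, lab, ridge = ridge),
                    error = function(e) e)
    if (inherits(res, "error"))
      data.frame(label = lab, n_neighbors = NA_integer_,
                 predictability = NA_real_, rmse = NA_real_,
                 error = conditionMessage(res), stringsAsFactors = FALSE)
    else
      data.frame(label = lab, n_neighbors = res$n_neighbors,
                 predictability = res$predictability, rmse = res$rmse,
                 error = NA_character_, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  tab <- data.frame(label = tab$label, domain = nodeDomains(net),
                    tab[, -1, drop = FALSE], stringsAsFactors = FALSE)
  attr(tab, "cohort_mean") <- mean(tab$predictability, na.rm = TRUE)
  tab
}

#' Attach predictability values to a network
#'
#' Stores the per-node predictability on the network so that
#' [writeNetwork()] exports it as the GraphML node attribute drawn as the
#' predictability ring.
#'
#' @param net a [SymptomNetwork-class].
#' @param pred a predictability table from [predictabilityTable()] or a
#'   numeric vector in node order.
#' @return the network with predictability attached.
#' @export
attachPredictability <- function(net, pred) {
  v <- if (is.data.frame(pred)) pred$predictability else as.numeric(pred)
  if (length(v) != length(nodeLabels(net)))
    stop("predictability must have one value per node")
  net@predictability <- ifelse(is.na(v), 0, v)
  net
}
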