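#' Deterministic Fruchterman-Reingold layout
#'
#' Force-directed placement treating nodes as particles: adjacent nodes
#' attract with force `d^2 / k` scaled by `|w|`, all pairs within a
#' cutoff radius of `3k` repel with force `k^2 / d` (repulsion between
#' distant vertices is ignored), where `k = sqrt(area / N)` with unit
#' area. Displacement per iteration is capped by a linearly cooling
#' temperature, so strongly connected nodes settle centrally. Initial
#' positions are a seeded uniform draw on the unit disc; the final layout
#' is centred on its centroid. Identical (network, seed, iterations) give
#' identical coordinates.
#'
#' @param net a [SymptomNetwork-class].
#' @param seed integer seed for the initial placement (default 42).
#' @param iterations number of force iterations (default 500).
#' @return object of class `Layout`: list with `coordinates` (N x 2
#'   matrix, node labels as rownames), `iterations`, `seed`,
#'   `final_max_displacement`.
#' @export
fruchtermanReingold <- function(net, seed = 42, iterations = 500) {
  stopifnot(is(net, "SymptomNetwork"), iterations >= 1)
  w <- abs(net@weights)
  labels <- nodeLabels(net)
  n <- nrow(w)
  if (n == 1) {
    coords <- matrix(0, 1, 2, dimnames = list(labels, c("x", "y")))
    return(structure(list(coordinates = coords, iterations = iterations,
                          seed = seed, final_max_displacement = 0),
                     class = "Layout"))
  }
  k <- sqrt(1 / n)
  cutoff <- 3 * k
  pos <- withr::with_seed(as.integer(seed), {
    r <- sqrt(stats::runif(n)); th <- stats::runif(n, 0, 2 * pi)
    cbind(r * cos(th), r * sin(th))
  })
  t0 <- 0.1
  maxdisp <- 0
  for (it in seq_len(iterations)) {
    disp <- matrix(0, n, 2)
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      delta <- pos[i, ] - pos[j, ]
      d <- sqrt(sum(delta^2))
      if (d < 1e-9) { delta <- c(1e-6, 0); d <- 1e-6 }
      if (d < cutoff) {                       # truncated repulsion
        f <- (k^2 / d) * (delta / d)
        disp[i, ] <- disp[i, ] + f
        disp[j, ] <- disp[j, ] - f
      }
      if (w[i, j] > 0) {                      # weighted attraction
        f <- (d^2 / k) * w[i, j] * (delta / d)
        disp[i, ] <- disp[i, ] - f
        disp[j, ] <- disp[j, ] + f
      }
    }
    temp <- t0 * (1 - (it - 1) / iterations)
    norms <- sqrt(rowSums(disp^2))
    step <- pmin(norms, temp)
    scale <- ifelse(norms > 0, step / norms, 0)
    pos <- pos + disp * scale
    maxdisp <- max(step)
  }
  pos <- sweep(pos, 2, colMeans(pos))
  dimnames(pos) <- list(labels, c("x", "y"))
  structure(list(coordinates = pos, iterations = iterations, seed = seed,
                 final_max_displacement = maxdisp), class = "Layout")
}

domainColors <- function() {
  c(neurocognitive = "#f4a6c6", affective = "#9ecbe8",
    psychosocial = "#a8d5a2")
}

#' Render a network figure
#'
#' Writes a PNG: nodes coloured by domain, edge thickness proportional to
#' `|w|`, positive edges black and negative edges red, and (when given) a
#' blue predictability arc around each node whose angular extent is
#' proportional to the node's predictability (empty at 0, a full ring
#' at 1).
#'
#' @param net a [SymptomNetwork-class].
#' @param layout a `Layout` from [fruchtermanReingold()] (computed with
#'   default settings when omitted).
#' @param pred optional predictability table or numeric vector in node
#'   order.
#' @param path output PNG path.
#' @return `path`, invisibly.
#' @export
renderNetwork <- function(net, path, layout = NULL, pred = NULL) {
  stopifnot(is(net, "SymptomNetwork"))
  if (is.null(layout)) layout <- fruchtermanReingold(net)
  coords <- layout$coordinates
  labels <- nodeLabels(net)
  if (!identical(rownames(coords), labels))
    stop("layout node set does not match the network")
  pv <- NULL
  if (!is.null(pred)) {
    pv <- if (is.data.frame(pred)) pred$predictability else as.numeric(pred)
    if (length(pv) != length(labels))
      stop("predictability node set does not match the network")
    pv[is.na(pv)] <- 0
  } else if (length(net@predictability)) {
    pv <- net@predictability
  }
  w <- net@weights
  cols <- domainColors()[nodeDomains(net)]
  grDevices::png(path, width = 900, height = 900, res = 130)
  on.exit(grDevices::dev.off())
  rng <- max(abs(coords), 0.1) * 1.25
  graphics::par(mar = c(0.5, 0.5, 0.5, 0.5))
  graphics::plot(NA, xlim = c(-rng, rng), ylim = c(-rng, rng), asp = 1,
                 axes = FALSE, xlab = "", ylab = "")
  idx <- which(upper.tri(w) & w != 0, arr.ind = TRUE)
  if (nrow(idx)) for (r in seq_len(nrow(idx))) {
    i <- idx[r, 1]; j <- idx[r, 2]
    graphics::segments(coords[i, 1], coords[i, 2],
                       coords[j, 1], coords[j, 2],
                       col = if (w[i, j] > 0) "black" else "red",
                       lwd = 0.5 + 4 * abs(w[i, j]))
  }
  rad <- rng / 18
  theta <- seq(0, 2 * pi, length.out = 60)
  for (i in seq_along(labels)) {
    graphics::polygon(coords[i, 1] + rad * cos(theta),
                      coords[i, 2] + rad * sin(theta),
                      col = cols[i], border = "grey30")
    if (!is.null(pv) && pv[i] > 0) {
      arc <- seq(pi / 2, pi / 2 - 2 * pi * pv[i], length.out = 60)
      graphics::lines(coords[i, 1] + rad * 1.25 * cos(arc),
                      coords[i, 2] + rad * 1.25 * sin(arc),
                      col = "blue3", lwd = 2.5)
    }
    graphics::text(coords[i, 1], coords[i, 2], labels[i], cex = 0.55)
  }
  invisible(path)
}
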