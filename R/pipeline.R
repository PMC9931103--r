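armStage <- function(arm, stage, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("arm '%s', stage '%s': %s", arm, stage,
                 conditionMessage(e)), call. = FALSE))
}

#' Run the full network comparison analysis
#'
#' For each arm (a cohort x timepoint score table): estimate the Spearman
#' network at the significance threshold, compute the centrality table,
#' node predictability, the domain connectivity summary and the layout;
#' then compute descriptive deltas between every pair of arms sharing the
#' battery. When `outDir` is given, all artifacts are written:
#' `<arm>/net.graphml`, `<arm>/centrality.csv`, `<arm>/predictability.csv`,
#' `<arm>/domains.csv`, `<arm>/network.png`, plus `deltas.csv` and
#' `report.json` at the top level. Identical configuration (including
#' seeds) produces byte-identical CSV/JSON outputs.
#'
#' @param arms named list of [ScoreTable-class] objects or score-file
#'   paths (e.g. `list(MDD_T0 = ..., MDD_T1 = ...)`).
#' @param battery [Battery-class] used to read file-path arms (default
#'   [defaultBattery()]).
#' @param alpha edge significance level (default 0.05).
#' @param centralityAlpha tuning parameter for centrality (default 1).
#' @param layoutSeed,layoutIterations layout settings.
#' @param ridge passed to [predictabilityTable()].
#' @param outDir optional output directory.
#' @param render write PNG figures (requires `outDir`).
#' @return a `ComparisonReport`: list with `arms` (per arm: `scores`,
#'   `network`, `centrality`, `predictability`, `domains`, `layout`),
#'   `deltas` (per arm pair, see [deltaTable()]), and `config`.
#' @export
runAnalysis <- function(arms, battery = defaultBattery(), alpha = 0.05,
                        centralityAlpha = 1, layoutSeed = 42,
                        layoutIterations = 500, ridge = FALSE,
                        outDir = NULL, render = !is.null(outDir)) {
  if (!length(arms) || is.null(names(arms)) || any(names(arms) == ""))
    stop("arms must be a non-empty named list")
  results <- list()
  for (arm in names(arms)) {
    x <- arms[[arm]]
    scores <- armStage(arm, "read_scores",
      if (is(x, "ScoreTable")) x else readScores(x, battery))
    est <- armStage(arm, "spearman_matrix", spearmanMatrix(scores))
    net <- armStage(arm, "threshold_network",
      thresholdNetwork(est, scores@battery, alpha = alpha))
    cent <- armStage(arm, "centrality_table",
      centralityTable(net, alpha = centralityAlpha))
    pred <- armStage(arm, "predictability_table",
      predictabilityTable(scores, net, ridge = ridge))
    net <- attachPredictability(net, pred)
    doms <- armStage(arm, "domain_connectivity", domainConnectivity(net))
    lay <- armStage(arm, "layout",
      fruchtermanReingold(net, seed = layoutSeed,
                          iterations = layoutIterations))
    results[[arm]] <- list(scores = scores, network = net,
                           centrality = cent, predictability = pred,
                           domains = doms, layout = lay)
  }
  deltas <- list()
  nms <- names(results)
  if (length(nms) > 1) {
    for (a in seq_len(length(nms) - 1)) for (b in (a + 1):length(nms)) {
      key <- paste(nms[a], nms[b], sep = " vs ")
      deltas[[key]] <- deltaTable(results[[nms[a]]], results[[nms[b]]])
    }
  }
  config <- list(arms = names(arms), alpha = alpha,
                 centrality_alpha = centralityAlpha,
                 layout_seed = layoutSeed,
                 layout_iterations = layoutIterations, ridge = ridge)
  report <- list(arms = results, deltas = deltas, config = config)
  if (!is.null(outDir))
    writeReport(report, outDir, render = render)
  report
}

#' Descriptive deltas between two analysis arms
#'
#' Node-wise differences (b minus a) in each raw centrality measure and
#' predictability, and domain-block differences in edge count and mean
#' absolute weight. Antisymmetric: `delta(a, b) = -delta(b, a)`.
#'
#' @param a,b single-arm results (elements of a `ComparisonReport`'s
#'   `arms` list).
#' @return list with data.frames `nodes` and `domains`.
#' @export
deltaTable <- function(a, b) {
  if (!identical(a$network@battery@items$label,
                 b$network@battery@items$label))
    stop("arms do not share a battery; deltas undefined")
  meas <- c("degree", "strength", "expected_influence", "blended_degree",
            "betweenness", "closeness")
  nodes <- data.frame(label = a$centrality$label,
                      domain = a$centrality$domain,
                      stringsAsFactors = FALSE)
  for (m in meas)
    nodes[[paste0("d_", m)]] <- b$centrality[[m]] - a$centrality[[m]]
  nodes$d_predictability <-
    b$predictability$predictability - a$predictability$predictability
  da <- a$domains$summary; db <- b$domains$summary
  stopifnot(identical(da$block, db$block))
  maw <- function(x) ifelse(is.na(x$mean_abs_weight), 0, x$mean_abs_weight)
  domains <- data.frame(block = da$block, type = da$type,
                        d_edges = db$edges - da$edges,
                        d_mean_abs_weight = maw(db) - maw(da),
                        stringsAsFactors = FALSE)
  list(nodes = nodes, domains = domains)
}

totalEdges <- function(net) {
  w <- networkWeights(net)
  sum(w[upper.tri(w)] != 0)
}

armSummary <- function(res) {
  net <- res$network
  dom <- table(factor(nodeDomains(net), levels = DOMAIN_LEVELS))
  list(n_nodes = length(nodeLabels(net)),
       domain_sizes = as.list(stats::setNames(as.integer(dom), names(dom))),
       n_edges = totalEdges(net),
       predictability_mean =
         round(attr(res$predictability, "cohort_mean"), 12),
       bridge_nodes = res$domains$bridge_nodes)
}

writeReport <- function(report, outDir, render = TRUE) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  for (arm in names(report$arms)) {
    res <- report$arms[[arm]]
    ad <- file.path(outDir, arm)
    dir.create(ad, recursive = TRUE, showWarnings = FALSE)
    writeNetwork(res$network, file.path(ad, "net.graphml"))
    utils::write.csv(res$centrality, file.path(ad, "centrality.csv"),
                     row.names = FALSE, quote = FALSE)
    utils::write.csv(res$predictability, file.path(ad, "predictability.csv"),
                     row.names = FALSE, quote = FALSE)
    utils::write.csv(res$domains$summary, file.path(ad, "domains.csv"),
                     row.names = FALSE, quote = FALSE)
    if (render)
      renderNetwork(res$network, file.path(ad, "network.png"),
                    layout = res$layout)
  }
  if (length(report$deltas)) {
    rows <- lapply(names(report$deltas), function(key) {
      d <- report$deltas[[key]]$nodes
      cbind(comparison = key, d, stringsAsFactors = FALSE)
    })
    utils::write.csv(do.call(rbind, rows), file.path(outDir, "deltas.csv"),
                     row.names = FALSE, quote = FALSE)
  }
  json <- list(
    schema_version = "1.0",
    config = report$config,
    config_hash = configHash(report$config),
    arms = lapply(report$arms, armSummary),
    deltas = lapply(report$deltas, function(d) list(
      predictability_mean_change = round(sum(d$nodes$d_predictability,
                                             na.rm = TRUE) /
                                         nrow(d$nodes), 12),
      edge_count_change = sum(d$domains$d_edges))))
  jsonlite::write_json(json, file.path(outDir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(outDir)
}

configHash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  jsonlite::write_json(config, f, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(f))
}
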