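#' Construct a Battery
#'
#' @param items data.frame with columns `label`, `full_name`, `domain`,
#'   `score_min`, `score_max`, `orientation`.
#' @param name battery name.
#' @return a [Battery-class].
#' @export
Battery <- function(items, name = "battery") {
  items <- as.data.frame(items, stringsAsFactors = FALSE)
  rownames(items) <- NULL
  new("Battery", items = items, name = name)
}

#' The default 17-item neurocognitive/affective/psychosocial battery
#'
#' Nine neurocognitive instruments (global screening plus specific tests),
#' two affective severity scales, and the six psychosocial functioning
#' domains of the FAST. Score ranges are the published ranges of each
#' instrument; orientation records whether higher scores mean better
#' (cognitive tests) or worse (severity and impairment scales)
#' functioning.
#'
#' @return a [Battery-class] with 17 items.
#' @examples
#' b <- defaultBattery()
#' table(nodeDomains(b))
#' @export
defaultBattery <- function() {
  nc <- "neurocognitive"; af <- "affective"; ps <- "psychosocial"
  hb <- "higher_is_better"; hw <- "higher_is_worse"
  items <- data.frame(
    label = c("MCA", "MMS", "FAB", "FAS", "Vcb", "REY", "RDC",
              "SPAN_A", "SPAN_I",
              "BDI", "HDR",
              "Cgn", "Occ", "Atn", "Lsr", "Int", "Fnn"),
    full_name = c("Montreal Cognitive Assessment",
                  "Mini Mental State Examination",
                  "Frontal Assessment Battery",
                  "Phonetic verbal fluency (FAS)",
                  "Vocabulary (WAIS-IV)",
                  "Rey 15 Words immediate recall",
                  "Rey 15 Words deferred recall",
                  "Digit span forward",
                  "Digit span backward",
                  "Beck Depression Inventory II",
                  "Hamilton Depression Rating Scale",
                  "FAST cognitive functioning",
                  "FAST occupational functioning",
                  "FAST autonomy",
                  "FAST leisure time",
                  "FAST interpersonal relationships",
                  "FAST financial issues"),
    domain = c(rep(nc, 9), rep(af, 2), rep(ps, 6)),
    score_min = c(0, 0, 0, 0, 0, 0, 0, 0, 0,  0, 0,  0, 0, 0, 0, 0, 0),
    score_max = c(30, 30, 18, 60, 57, 75, 15, 9, 9,  63, 52,
                  15, 15, 12, 6, 18, 6),
    orientation = c(rep(hb, 9), rep(hw, 2), rep(hw, 6)),
    stringsAsFactors = FALSE
  )
  Battery(items, name = "neuro-affective-psychosocial-17")
}

#' Read / write a Battery as JSON
#'
#' Serialization round-trips exactly: `readBattery(writeBattery(b, f))`
#' equals `b`, preserving item order.
#'
#' @param battery a [Battery-class].
#' @param path file path.
#' @return `writeBattery` returns `path` invisibly; `readBattery` a
#'   [Battery-class].
#' @export
writeBattery <- function(battery, path) {
  stopifnot(is(battery, "Battery"))
  out <- list(name = battery@name, items = battery@items)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}

#' @rdname writeBattery
#' @export
readBattery <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  items <- as.data.frame(x$items, stringsAsFactors = FALSE)
  items$score_min <- as.numeric(items$score_min)
  items$score_max <- as.numeric(items$score_max)
  Battery(items, name = x$name)
}

#' Construct a ScoreTable
#'
#' @param values numeric matrix or data.frame, subjects in rows; column
#'   names must cover the battery labels (any order; extra columns
#'   ignored).
#' @param battery a [Battery-class].
#' @param subjects subject identifiers; defaults to rownames or `S<i>`.
#' @return a [ScoreTable-class] with columns in battery order.
#' @export
ScoreTable <- function(values, battery, subjects = NULL) {
  stopifnot(is(battery, "Battery"))
  values <- as.matrix(as.data.frame(values))
  labels <- battery@items$label
  missing_cols <- setdiff(labels, colnames(values))
  if (length(missing_cols))
    stop("score table is missing battery column(s): ",
         paste(missing_cols, collapse = ", "))
  values <- values[, labels, drop = FALSE]
  storage.mode(values) <- "double"
  if (is.null(subjects)) {
    subjects <- rownames(values)
    if (is.null(subjects))
      subjects <- if (nrow(values)) sprintf("S%03d", seq_len(nrow(values)))
                  else character(0)
  }
  rownames(values) <- NULL
  new("ScoreTable", battery = battery, subjects = as.character(subjects),
      values = values)
}

#' Read a subject x item score table from delimited text
#'
#' The file must have a header row naming every battery label (any column
#' order; alignment is always by label). An optional `subject` column (case
#' insensitive) supplies subject identifiers. Values outside an item's
#' declared score range are rejected with the offending row and column.
#'
#' @param path CSV (or TSV, by extension) file path.
#' @param battery a [Battery-class].
#' @return a [ScoreTable-class].
#' @export
readScores <- function(path, battery) {
  stopifnot(is(battery, "Battery"))
  sep <- if (grepl("\\.tsv$|\\.txt$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  labels <- battery@items$label
  missing_cols <- setdiff(labels, names(df))
  if (length(missing_cols))
    stop(sprintf("score file '%s' is missing required column(s): %s",
                 path, paste(missing_cols, collapse = ", ")))
  subj_col <- which(tolower(names(df)) == "subject")
  subjects <- if (length(subj_col)) as.character(df[[subj_col[1]]]) else NULL
  vals <- as.matrix(df[, labels, drop = FALSE])
  storage.mode(vals) <- "double"
  it <- battery@items
  for (j in seq_along(labels)) {
    x <- vals[, j]
    bad <- which(!is.na(x) & (x < it$score_min[j] | x > it$score_max[j]))
    if (length(bad))
      stop(sprintf(
        "value %g outside range [%g, %g] for item '%s' (file row %d)",
        x[bad[1]], it$score_min[j], it$score_max[j], labels[j], bad[1]))
  }
  ScoreTable(vals, battery, subjects = subjects)
}

#' Write a ScoreTable as CSV
#'
#' @param scores a [ScoreTable-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeScores <- function(scores, path) {
  stopifnot(is(scores, "ScoreTable"))
  df <- data.frame(subject = scores@subjects, scores@values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# edge list of the upper triangle, one row per nonzero edge
edgeTable <- function(net) {
  w <- net@weights
  labels <- nodeLabels(net)
  idx <- which(upper.tri(w) & w != 0, arr.ind = TRUE)
  data.frame(source = labels[idx[, 1]],
             target = labels[idx[, 2]],
             weight = w[idx],
             rho = net@rho[idx],
             p = net@p[idx],
             stringsAsFactors = FALSE)
}

#' Write a SymptomNetwork to GraphML or edge-list CSV
#'
#' GraphML carries node attributes (label, full name, domain, score range,
#' orientation and, when attached, predictability) and edge attributes
#' (weight, sign, rho, p); reading the file back with [readNetwork()]
#' reproduces the weighted adjacency exactly. The edge CSV lists one
#' undirected edge per row (`source,target,weight,rho,p`).
#'
#' @param net a [SymptomNetwork-class].
#' @param path output file path.
#' @param format `"graphml"` or `"edge_csv"`.
#' @return `path`, invisibly.
#' @export
writeNetwork <- function(net, path, format = c("graphml", "edge_csv")) {
  stopifnot(is(net, "SymptomNetwork"))
  format <- match.arg(format)
  if (format == "edge_csv") {
    utils::write.csv(edgeTable(net), path, row.names = FALSE, quote = FALSE)
    return(invisible(path))
  }
  it <- net@battery@items
  doc <- xml2::xml_new_root("graphml",
    xmlns = "http://graphml.graphdrawing.org/xmlns")
  keydefs <- list(
    c("d_dom", "node", "domain", "string"),
    c("d_full", "node", "full_name", "string"),
    c("d_min", "node", "score_min", "double"),
    c("d_max", "node", "score_max", "double"),
    c("d_ori", "node", "orientation", "string"),
    c("d_pred", "node", "predictability", "double"),
    c("e_w", "edge", "weight", "double"),
    c("e_s", "edge", "sign", "int"),
    c("e_rho", "edge", "rho", "double"),
    c("e_p", "edge", "p", "double"))
  for (k in keydefs)
    xml2::xml_add_child(doc, "key", id = k[1], "for" = k[2],
                        attr.name = k[3], attr.type = k[4])
  g <- xml2::xml_add_child(doc, "graph", id = net@battery@name,
                           edgedefault = "undirected",
                           threshold = format(net@threshold, digits = 17))
  has_pred <- length(net@predictability) > 0
  for (i in seq_len(nrow(it))) {
    nd <- xml2::xml_add_child(g, "node", id = it$label[i])
    xml2::xml_add_child(nd, "data", key = "d_dom", it$domain[i])
    xml2::xml_add_child(nd, "data", key = "d_full", it$full_name[i])
    xml2::xml_add_child(nd, "data", key = "d_min",
                        format(it$score_min[i], digits = 17))
    xml2::xml_add_child(nd, "data", key = "d_max",
                        format(it$score_max[i], digits = 17))
    xml2::xml_add_child(nd, "data", key = "d_ori", it$orientation[i])
    if (has_pred)
      xml2::xml_add_child(nd, "data", key = "d_pred",
                          format(net@predictability[i], digits = 17))
  }
  et <- edgeTable(net)
  if (nrow(et)) for (i in seq_len(nrow(et))) {
    ed <- xml2::xml_add_child(g, "edge", source = et$source[i],
                              target = et$target[i])
    xml2::xml_add_child(ed, "data", key = "e_w",
                        format(et$weight[i], digits = 17))
    xml2::xml_add_child(ed, "data", key = "e_s",
                        as.character(sign(et$weight[i])))
    xml2::xml_add_child(ed, "data", key = "e_rho",
                        format(et$rho[i], digits = 17))
    xml2::xml_add_child(ed, "data", key = "e_p",
                        format(et$p[i], digits = 17))
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Read a SymptomNetwork from GraphML
#'
#' @param path GraphML file written by [writeNetwork()].
#' @param battery optional [Battery-class]; when omitted the battery is
#'   reconstructed from the node attributes stored in the file.
#' @return a [SymptomNetwork-class].
#' @export
readNetwork <- function(path, battery = NULL) {
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  g <- xml2::xml_find_first(doc, ".//graph")
  thr <- as.numeric(xml2::xml_attr(g, "threshold"))
  if (is.na(thr)) thr <- 0.05
  nodes <- xml2::xml_find_all(g, "./node")
  nd_attr <- function(nd, key) {
    v <- xml2::xml_find_first(nd, sprintf("./data[@key='%s']", key))
    if (inherits(v, "xml_missing")) NA_character_ else xml2::xml_text(v)
  }
  labels <- xml2::xml_attr(nodes, "id")
  if (is.null(battery)) {
    items <- data.frame(
      label = labels,
      full_name = vapply(nodes, nd_attr, "", key = "d_full"),
      domain = vapply(nodes, nd_attr, "", key = "d_dom"),
      score_min = as.numeric(vapply(nodes, nd_attr, "", key = "d_min")),
      score_max = as.numeric(vapply(nodes, nd_attr, "", key = "d_max")),
      orientation = vapply(nodes, nd_attr, "", key = "d_ori"),
      stringsAsFactors = FALSE)
    battery <- Battery(items, name = xml2::xml_attr(g, "id"))
  }
  pred_txt <- vapply(nodes, nd_attr, "", key = "d_pred")
  n <- length(labels)
  w <- rho <- matrix(0, n, n, dimnames = list(labels, labels))
  p <- matrix(1, n, n, dimnames = list(labels, labels))
  diag(p) <- 0
  npairs <- matrix(0L, n, n, dimnames = list(labels, labels))
  edges <- xml2::xml_find_all(g, "./edge")
  for (ed in edges) {
    i <- match(xml2::xml_attr(ed, "source"), labels)
    j <- match(xml2::xml_attr(ed, "target"), labels)
    wt <- as.numeric(nd_attr(ed, "e_w"))
    r <- as.numeric(nd_attr(ed, "e_rho"))
    pv <- as.numeric(nd_attr(ed, "e_p"))
    w[i, j] <- w[j, i] <- wt
    rho[i, j] <- rho[j, i] <- if (is.na(r)) wt else r
    p[i, j] <- p[j, i] <- if (is.na(pv)) 0 else pv
  }
  diag(rho) <- 1
  pred <- suppressWarnings(as.numeric(pred_txt))
  pred <- if (all(is.na(pred))) numeric(0) else pred
  new("SymptomNetwork", battery = battery, weights = w, rho = rho, p = p,
      nPairs = npairs, threshold = thr, predictability = pred)
}
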