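#' @import methods
NULL

DOMAIN_LEVELS <- c("neurocognitive", "affective", "psychosocial")
ORIENTATION_LEVELS <- c("higher_is_better", "higher_is_worse")

#' Battery: an ordered set of instrument items
#'
#' A `Battery` holds the ordered item metadata defining the nodes of a
#' symptom network: one row per item with its short node label, full
#' instrument name, domain (neurocognitive, affective or psychosocial),
#' admissible score range and orientation.
#'
#' @slot items data.frame with columns `label`, `full_name`, `domain`,
#'   `score_min`, `score_max`, `orientation`, one row per item, in node
#'   order.
#' @slot name character scalar naming the battery.
#'
#' @seealso [defaultBattery()], [readBattery()], [writeBattery()]
#' @export
setClass("Battery", representation(items = "data.frame", name = "character"))

setValidity("Battery", function(object) {
  it <- object@items
  need <- c("label", "full_name", "domain", "score_min", "score_max",
            "orientation")
  if (!all(need %in% names(it)))
    return(paste("items must have columns:", paste(need, collapse = ", ")))
  if (anyDuplicated(it$label))
    return("item labels must be unique")
  if (!all(it$domain %in% DOMAIN_LEVELS))
    return(paste("domain must be one of:", paste(DOMAIN_LEVELS, collapse = ", ")))
  if (!all(it$orientation %in% ORIENTATION_LEVELS))
    return("invalid orientation value")
  if (!all(it$score_min < it$score_max))
    return("score_min must be < score_max for every item")
  if (length(object@name) != 1L)
    return("name must be a single string")
  TRUE
})

#' ScoreTable: subjects x items score matrix bound to a battery
#'
#' @slot battery the [Battery-class] the columns refer to.
#' @slot subjects character vector of subject identifiers (row order).
#' @slot values numeric matrix, subjects in rows, battery items in columns
#'   (battery order); `NA` marks a missing score.
#'
#' @seealso [readScores()], [sampleCohort()]
#' @export
setClass("ScoreTable", representation(battery = "Battery",
                                      subjects = "character",
                                      values = "matrix"))

setValidity("ScoreTable", function(object) {
  it <- object@battery@items
  v <- object@values
  if (ncol(v) != nrow(it))
    return("column count must equal battery item count")
  if (!identical(colnames(v), it$label))
    return("value columns must be named and ordered as the battery labels")
  if (nrow(v) != length(object@subjects))
    return("row count must equal number of subjects")
  if (nrow(v) > 0) {
    for (j in seq_len(ncol(v))) {
      x <- v[, j]
      bad <- which(!is.na(x) & (x < it$score_min[j] | x > it$score_max[j]))
      if (length(bad))
        return(sprintf("value out of range [%g, %g] for item '%s' at row %d",
                       it$score_min[j], it$score_max[j], it$label[j], bad[1]))
    }
  }
  TRUE
})

#' SymptomNetwork: symmetric signed weighted adjacency over a battery
#'
#' Edges carry the Spearman correlation of the incident items when that
#' correlation was significant at the stored threshold; absent edges are 0.
#' The estimation provenance (full rho and p matrices, complete-case counts,
#' threshold) is kept alongside the thresholded weights.
#'
#' @slot battery the [Battery-class] defining the nodes.
#' @slot weights symmetric numeric matrix of signed edge weights, zero
#'   diagonal, 0 meaning "no edge".
#' @slot rho symmetric matrix of all pairwise Spearman correlations.
#' @slot p symmetric matrix of two-sided p-values.
#' @slot nPairs symmetric integer matrix of complete cases per pair.
#' @slot threshold significance level used to retain edges.
#' @slot predictability optional per-node predictability values (numeric,
#'   possibly length 0 when unattached).
#'
#' @seealso [thresholdNetwork()], [writeNetwork()], [readNetwork()]
#' @export
setClass("SymptomNetwork", representation(battery = "Battery",
                                          weights = "matrix",
                                          rho = "matrix",
                                          p = "matrix",
                                          nPairs = "matrix",
                                          threshold = "numeric",
                                          predictability = "numeric"))

setValidity("SymptomNetwork", function(object) {
  n <- nrow(object@battery@items)
  w <- object@weights
  if (!is.numeric(w) || nrow(w) != n || ncol(w) != n)
    return("weights must be a square numeric matrix matching the battery")
  if (max(abs(w - t(w))) > 1e-12)
    return("weights must be symmetric")
  if (any(diag(w) != 0))
    return("weights must have zero diagonal")
  if (length(object@predictability) &&
      length(object@predictability) != n)
    return("predictability must have one value per node when present")
  TRUE
})

# show methods (kept simple, qgraph-style one-liners)
setMethod("show", "Battery", function(object) {
  d <- table(factor(object@items$domain, levels = DOMAIN_LEVELS))
  cat(sprintf("Battery '%s': %d items (%s)\n", object@name,
              nrow(object@items),
              paste(sprintf("%d %s", as.integer(d), names(d)), collapse = ", ")))
  invisible(object)
})

setMethod("show", "ScoreTable", function(object) {
  cat(sprintf("ScoreTable: %d subjects x %d items [battery '%s'], %d missing\n",
              nrow(object@values), ncol(object@values), object@battery@name,
              sum(is.na(object@values))))
  invisible(object)
})

setMethod("show", "SymptomNetwork", function(object) {
  m <- object@weights
  ne <- sum(m[upper.tri(m)] != 0)
  cat(sprintf("SymptomNetwork: %d nodes, %d edges (threshold p < %g)\n",
              nrow(m), ne, object@threshold))
  invisible(object)
})

# ---- accessors ------------------------------------------------------------

#' @rdname accessors
#' @export
setGeneric("nodeLabels", function(x) standardGeneric("nodeLabels"))

#' @rdname accessors
#' @export
setGeneric("nodeDomains", function(x) standardGeneric("nodeDomains"))

#' @rdname accessors
#' @export
setGeneric("batteryItems", function(x) standardGeneric("batteryItems"))

#' @rdname accessors
#' @export
setGeneric("scoreMatrix", function(x) standardGeneric("scoreMatrix"))

#' @rdname accessors
#' @export
setGeneric("subjectIDs", function(x) standardGeneric("subjectIDs"))

#' @rdname accessors
#' @export
setGeneric("networkWeights", function(x) standardGeneric("networkWeights"))

#' @rdname accessors
#' @export
setGeneric("adjacencyMatrix", function(x) standardGeneric("adjacencyMatrix"))

#' @rdname accessors
#' @export
setGeneric("networkBattery", function(x) standardGeneric("networkBattery"))

#' Accessors for SymptomNet objects
#'
#' `nodeLabels()` and `nodeDomains()` return the item labels and domains in
#' node order; `batteryItems()` the full item metadata data.frame;
#' `scoreMatrix()` and `subjectIDs()` the numeric scores and subject ids of
#' a [ScoreTable-class]; `networkWeights()` the signed weighted adjacency,
#' `adjacencyMatrix()` the 0/1 edge indicator, and `networkBattery()` the
#' battery of a [SymptomNetwork-class].
#'
#' @param x a Battery, ScoreTable or SymptomNetwork.
#' @return see details above.
#' @name accessors
#' @rdname accessors
NULL

#' @rdname accessors
setMethod("nodeLabels", "Battery", function(x) x@items$label)
#' @rdname accessors
setMethod("nodeLabels", "ScoreTable", function(x) x@battery@items$label)
#' @rdname accessors
setMethod("nodeLabels", "SymptomNetwork", function(x) x@battery@items$label)
#' @rdname accessors
setMethod("nodeDomains", "Battery", function(x) x@items$domain)
#' @rdname accessors
setMethod("nodeDomains", "SymptomNetwork", function(x) x@battery@items$domain)
#' @rdname accessors
setMethod("batteryItems", "Battery", function(x) x@items)
#' @rdname accessors
setMethod("scoreMatrix", "ScoreTable", function(x) x@values)
#' @rdname accessors
setMethod("subjectIDs", "ScoreTable", function(x) x@subjects)
#' @rdname accessors
setMethod("networkWeights", "SymptomNetwork", function(x) x@weights)
#' @rdname accessors
setMethod("adjacencyMatrix", "SymptomNetwork",
          function(x) (x@weights != 0) * 1L)
#' @rdname accessors
setMethod("networkBattery", "SymptomNetwork", function(x) x@battery)
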