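#' BlockSpec: block-structured target correlations for cohort simulation
#'
#' Describes the latent correlation structure of a simulated cohort as one
#' correlation per domain (within-block), one per unordered domain pair
#' (between-block), and optional per-edge bridge overrides applied last.
#'
#' @slot within named numeric, one entry per domain, each in (-1, 1).
#' @slot between named numeric over unordered domain pairs (names
#'   `"a:b"` with the two domains sorted), each in (-1, 1).
#' @slot bridges data.frame with columns `item1`, `item2`, `rho`
#'   (possibly 0 rows): item-level overrides.
#' @export
setClass("BlockSpec", representation(within = "numeric",
                                     between = "numeric",
                                     bridges = "data.frame"))

setValidity("BlockSpec", function(object) {
  r <- c(object@within, object@between, object@bridges$rho)
  if (length(r) && any(abs(r) >= 1))
    return("all correlations must lie strictly within (-1, 1)")
  if (nrow(object@bridges) &&
      !all(c("item1", "item2", "rho") %in% names(object@bridges)))
    return("bridges must have columns item1, item2, rho")
  TRUE
})

domainPairKey <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = ":")
}

#' Construct a BlockSpec
#'
#' @param within named numeric of within-domain correlations, or a single
#'   number applied to every domain.
#' @param between named numeric of between-domain correlations (names
#'   `"domainA:domainB"`, order-insensitive), or a single number applied to
#'   every pair.
#' @param bridges optional data.frame (`item1`, `item2`, `rho`) of
#'   item-level overrides applied after the block fill.
#' @return a [BlockSpec-class].
#' @export
blockSpec <- function(within = 0, between = 0, bridges = NULL) {
  if (is.null(names(within)) && length(within) == 1)
    within <- stats::setNames(rep(within, length(DOMAIN_LEVELS)), DOMAIN_LEVELS)
  if (is.null(names(between)) && length(between) == 1) {
    prs <- utils::combn(DOMAIN_LEVELS, 2)
    between <- stats::setNames(rep(between, ncol(prs)),
                               domainPairKey(prs[1, ], prs[2, ]))
  } else if (length(between)) {
    parts <- strsplit(names(between), ":", fixed = TRUE)
    names(between) <- vapply(parts, function(p) domainPairKey(p[1], p[2]), "")
  }
  if (is.null(bridges))
    bridges <- data.frame(item1 = character(0), item2 = character(0),
                          rho = numeric(0), stringsAsFactors = FALSE)
  new("BlockSpec", within = within, between = between,
      bridges = as.data.frame(bridges, stringsAsFactors = FALSE))
}

#' CohortConfig: full parameterization of one simulated cohort
#'
#' @slot battery the [Battery-class] items are simulated for.
#' @slot nSubjects number of subjects (>= 2).
#' @slot blockSpec the latent [BlockSpec-class].
#' @slot means named numeric of item means (battery labels).
#' @slot sds named numeric of positive item standard deviations.
#' @slot seed integer seed; the generator is a pure function of the config.
#' @export
setClass("CohortConfig", representation(battery = "Battery",
                                        nSubjects = "numeric",
                                        blockSpec = "BlockSpec",
                                        means = "numeric",
                                        sds = "numeric",
                                        seed = "numeric"))

setValidity("CohortConfig", function(object) {
  it <- object@battery@items
  if (object@nSubjects < 2) return("nSubjects must be >= 2")
  if (!all(it$label %in% names(object@means)))
    return("means must name every battery item")
  if (!all(it$label %in% names(object@sds)))
    return("sds must name every battery item")
  m <- object@means[it$label]
  if (any(m < it$score_min | m > it$score_max))
    return("item means must lie within the item score ranges")
  if (any(object@sds <= 0)) return("sds must be positive")
  TRUE
})

#' Construct a CohortConfig
#'
#' @inheritParams blockSpec
#' @param battery a [Battery-class].
#' @param nSubjects number of subjects.
#' @param spec a [BlockSpec-class].
#' @param means,sds named numerics over battery labels.
#' @param seed integer seed (mandatory; simulation is deterministic in it).
#' @return a [CohortConfig-class].
#' @export
cohortConfig <- function(battery, nSubjects, spec, means, sds, seed) {
  new("CohortConfig", battery = battery, nSubjects = as.numeric(nSubjects),
      blockSpec = spec, means = means, sds = sds, seed = as.numeric(seed))
}

#' PairedDesign: a T0 cohort with a derived post-treatment T1 cohort
#'
#' T1 subjects are a seeded random subset of the T0 subjects
#' (`round(retention * n)` of them); T1 latent correlations are the T0
#' targets multiplied by `attenuation`; `shift` is added to the T1 means.
#'
#' @slot t0,t1 [CohortConfig-class] for the two timepoints.
#' @slot retention fraction of T0 subjects re-assessed at T1, in (0, 1].
#' @slot shift named numeric of additive mean changes at T1.
#' @slot attenuation factor in \[0, 1\] multiplying T0 off-diagonal latent
#'   correlations at T1.
#' @export
setClass("PairedDesign", representation(t0 = "CohortConfig",
                                        t1 = "CohortConfig",
                                        retention = "numeric",
                                        shift = "numeric",
                                        attenuation = "numeric"))

setValidity("PairedDesign", function(object) {
  if (object@retention <= 0 || object@retention > 1)
    return("retention must lie in (0, 1]")
  if (object@attenuation < 0 || object@attenuation > 1)
    return("attenuation must lie in [0, 1]")
  if (round(object@retention * object@t0@nSubjects) < 2)
    return("retention * nSubjects must leave at least 2 T1 subjects")
  TRUE
})

#' Construct a PairedDesign
#'
#' @param t0 the baseline [CohortConfig-class].
#' @param retention fraction of subjects retained at T1.
#' @param shift named numeric of additive mean changes at T1 (labels absent
#'   from the battery are an error; labels omitted shift by 0).
#' @param attenuation latent-correlation attenuation factor at T1.
#' @param t1Seed seed for the T1 draw (defaults to `seed(t0) + 1`).
#' @return a [PairedDesign-class].
#' @export
pairedDesign <- function(t0, retention = 1, shift = numeric(0),
                         attenuation = 1, t1Seed = t0@seed + 1) {
  labels <- t0@battery@items$label
  bad <- setdiff(names(shift), labels)
  if (length(bad))
    stop("treatment shift names unknown item(s): ", paste(bad, collapse = ", "))
  if (round(retention * t0@nSubjects) < 2)
    stop("retention * nSubjects must leave at least 2 T1 subjects")
  full_shift <- stats::setNames(rep(0, length(labels)), labels)
  full_shift[names(shift)] <- shift
  m1 <- t0@means[labels] + full_shift
  it <- t0@battery@items
  m1 <- pmin(pmax(m1, it$score_min), it$score_max)
  t1 <- cohortConfig(t0@battery,
                     nSubjects = round(retention * t0@nSubjects),
                     spec = t0@blockSpec, means = m1, sds = t0@sds,
                     seed = t1Seed)
  new("PairedDesign", t0 = t0, t1 = t1, retention = retention,
      shift = full_shift, attenuation = attenuation)
}

#' Build the block-structured target correlation matrix
#'
#' Fills a symmetric unit-diagonal matrix block-wise from the spec (within
#' each domain, then each domain pair), applies bridge overrides last, and
#' projects the result to the nearest positive-semidefinite correlation
#' matrix by eigenvalue clipping at zero followed by re-standardization to
#' unit diagonal.
#'
#' @param spec a [BlockSpec-class].
#' @param battery a [Battery-class].
#' @return a symmetric PSD correlation matrix with battery labels.
#' @export
buildTargetCorrelation <- function(spec, battery) {
  it <- battery@items
  n <- nrow(it)
  R <- matrix(0, n, n, dimnames = list(it$label, it$label))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    di <- it$domain[i]; dj <- it$domain[j]
    r <- if (di == dj) {
      if (di %in% names(spec@within)) spec@within[[di]] else 0
    } else {
      key <- domainPairKey(di, dj)
      if (key %in% names(spec@between)) spec@between[[key]] else 0
    }
    R[i, j] <- R[j, i] <- r
  }
  if (nrow(spec@bridges)) for (b in seq_len(nrow(spec@bridges))) {
    i <- match(spec@bridges$item1[b], it$label)
    j <- match(spec@bridges$item2[b], it$label)
    if (is.na(i) || is.na(j))
      stop("bridge override references unknown item label: ",
           spec@bridges$item1[b], " / ", spec@bridges$item2[b])
    R[i, j] <- R[j, i] <- spec@bridges$rho[b]
  }
  diag(R) <- 1
  nearestCorrelation(R)
}

# project to the nearest PSD correlation matrix: clip eigenvalues at 0,
# reconstruct, rescale to unit diagonal
nearestCorrelation <- function(R) {
  e <- eigen(R, symmetric = TRUE)
  if (min(e$values) >= 0) return(R)
  lam <- pmax(e$values, 0)
  M <- e$vectors %*% diag(lam) %*% t(e$vectors)
  d <- sqrt(pmax(diag(M), .Machine$double.eps))
  M <- M / tcrossprod(d)
  M <- (M + t(M)) / 2
  diag(M) <- 1
  dimnames(M) <- dimnames(R)
  M
}

# matrix square root factor A with A %*% t(A) == R (PSD input)
psdFactor <- function(R) {
  e <- eigen(R, symmetric = TRUE)
  lam <- pmax(e$values, 0)
  e$vectors %*% diag(sqrt(lam))
}

#' Sample one synthetic cohort
#'
#' Draws a latent multivariate normal with the spec's target correlation
#' (Gaussian copula on the latent scale), maps each column through the
#' item's mean and standard deviation, rounds to integers (the instruments
#' are integer-scored) and clamps to the item's score range. Bitwise
#' reproducible from the config.
#'
#' @param config a [CohortConfig-class].
#' @param target optional precomputed target correlation (used internally
#'   by [samplePaired()]); defaults to `buildTargetCorrelation`.
#' @return a [ScoreTable-class].
#' @examples
#' cfg <- presetCohortConfig("MDD", nSubjects = 50, seed = 1)
#' tab <- sampleCohort(cfg)
#' @export
sampleCohort <- function(config, target = NULL) {
  stopifnot(is(config, "CohortConfig"))
  if (is.null(target))
    target <- buildTargetCorrelation(config@blockSpec, config@battery)
  drawCohort(config, target,
             subjects = sprintf("S%03d", seq_len(config@nSubjects)),
             seed = config@seed)
}

drawCohort <- function(config, target, subjects, seed) {
  it <- config@battery@items
  n <- length(subjects)
  p <- nrow(it)
  A <- psdFactor(target)
  Z <- withr::with_seed(as.integer(seed),
                        matrix(stats::rnorm(n * p), n, p)) %*% t(A)
  m <- config@means[it$label]
  s <- config@sds[it$label]
  X <- sweep(sweep(Z, 2, s, `*`), 2, m, `+`)
  X <- round(X)
  X <- pmin(pmax(X, matrix(it$score_min, n, p, byrow = TRUE)),
            matrix(it$score_max, n, p, byrow = TRUE))
  colnames(X) <- it$label
  ScoreTable(X, config@battery, subjects = subjects)
}

#' Sample a paired T0/T1 cohort
#'
#' @param design a [PairedDesign-class].
#' @return a named list with [ScoreTable-class] elements `t0` and `t1`.
#' @export
samplePaired <- function(design) {
  stopifnot(is(design, "PairedDesign"))
  t0 <- sampleCohort(design@t0)
  target0 <- buildTargetCorrelation(design@t0@blockSpec, design@t0@battery)
  target1 <- design@attenuation * target0
  diag(target1) <- 1
  target1 <- nearestCorrelation(target1)
  n1 <- round(design@retention * design@t0@nSubjects)
  if (n1 < 2) stop("retention leaves fewer than 2 T1 subjects")
  keep <- withr::with_seed(as.integer(design@t1@seed),
                           sort(sample.int(design@t0@nSubjects, n1)))
  subjects1 <- t0@subjects[keep]
  cfg1 <- design@t1
  cfg1@nSubjects <- n1
  t1 <- drawCohort(cfg1, target1, subjects = subjects1,
                   seed = design@t1@seed + 1)
  list(t0 = t0, t1 = t1)
}

# mid-range clinically plausible marginals for the default battery
defaultItemMeans <- function() {
  c(MCA = 20, MMS = 24, FAB = 12, FAS = 28, Vcb = 30, REY = 30, RDC = 7,
    SPAN_A = 5.5, SPAN_I = 4, BDI = 28, HDR = 20,
    Cgn = 8, Occ = 9, Atn = 6, Lsr = 3.5, Int = 9, Fnn = 3)
}

defaultItemSDs <- function() {
  c(MCA = 4, MMS = 3, FAB = 3, FAS = 8, Vcb = 8, REY = 9, RDC = 3,
    SPAN_A = 1.2, SPAN_I = 1.2, BDI = 9, HDR = 6,
    Cgn = 3, Occ = 3.5, Atn = 2.5, Lsr = 1.3, Int = 4, Fnn = 1.3)
}

#' Preset cohort configurations
#'
#' Two illustrative fixtures with qualitatively distinct bridge structure:
#' the MDD-like preset couples the affective and psychosocial blocks with
#' no direct affective-neurocognitive bridges; the BD-like preset has a
#' hyperconnected psychosocial block with neurocognitive bridges running
#' through MCA. These are simulation fixtures, not empirical estimates.
#'
#' @param cohort `"MDD"` or `"BD"`.
#' @param nSubjects cohort size (defaults: 87 MDD-like, 56 BD-like).
#' @param seed integer seed.
#' @param battery battery to simulate (default [defaultBattery()]).
#' @return a [CohortConfig-class].
#' @export
presetCohortConfig <- function(cohort = c("MDD", "BD"), nSubjects = NULL,
                               seed = 1, battery = defaultBattery()) {
  cohort <- match.arg(cohort)
  if (cohort == "MDD") {
    if (is.null(nSubjects)) nSubjects <- 87
    spec <- blockSpec(
      within = c(neurocognitive = 0.6, affective = 0.6, psychosocial = 0.6),
      between = c("affective:psychosocial" = 0.4,
                  "affective:neurocognitive" = 0,
                  "neurocognitive:psychosocial" = 0.1))
  } else {
    if (is.null(nSubjects)) nSubjects <- 56
    spec <- blockSpec(
      within = c(neurocognitive = 0.35, affective = 0.6, psychosocial = 0.7),
      between = c("affective:psychosocial" = 0.3,
                  "affective:neurocognitive" = 0.1,
                  "neurocognitive:psychosocial" = 0.05),
      bridges = data.frame(item1 = c("MCA", "MCA"),
                           item2 = c("Cgn", "Occ"),
                           rho = c(0.5, 0.4), stringsAsFactors = FALSE))
  }
  cohortConfig(battery, nSubjects, spec,
               means = defaultItemMeans(), sds = defaultItemSDs(),
               seed = seed)
}

#' Preset paired T0/T1 designs
#'
#' Wraps [presetCohortConfig()] in a [PairedDesign-class] with the study's
#' T0 to T1 structure: retention 16/87 (MDD-like) or 29/56 (BD-like),
#' latent-correlation attenuation 0.4 (connectivity loss after treatment),
#' and treatment shifts that lower severity/impairment scores and raise
#' cognitive test scores.
#'
#' @inheritParams presetCohortConfig
#' @return a [PairedDesign-class].
#' @export
presetPairedDesign <- function(cohort = c("MDD", "BD"), nSubjects = NULL,
                               seed = 1, battery = defaultBattery()) {
  cohort <- match.arg(cohort)
  t0 <- presetCohortConfig(cohort, nSubjects = nSubjects, seed = seed,
                           battery = battery)
  retention <- if (cohort == "MDD") 16 / 87 else 29 / 56
  shift <- c(MCA = 2, MMS = 1.5, FAB = 1.5, FAS = 3, REY = 4, RDC = 1,
             SPAN_A = 0.5, SPAN_I = 0.5,
             BDI = -10, HDR = -8,
             Cgn = -2, Occ = -2, Atn = -1.5, Lsr = -1, Int = -2, Fnn = -1)
  shift <- shift[names(shift) %in% battery@items$label]
  pairedDesign(t0, retention = retention, shift = shift, attenuation = 0.4)
}
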