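#' Levins niche breadth
#'
#' B = 1 / sum(p_j^2) over the r resource states, where p_j is the proportion
#' of the OTU's reads found in state j. B ranges from 1 (all reads in one
#' state) to r (perfectly uniform across states).
#'
#' @param p non-negative vector over the r states; normalized internally, so
#'   raw per-state counts are accepted.
#' @return numeric B in [1, r].
#' @examples
#' levinsBreadth(c(0.25, 0.25, 0.25, 0.25))  # 4: uniform over 4 states
#' levinsBreadth(c(1, 0, 0, 0))              # 1: single state
#' @export
levinsBreadth <- function(p) {
  if (any(p < 0)) stop("proportions must be non-negative")
  s <- sum(p)
  if (s == 0) stop("all-zero profile: OTU absent from every state")
  p <- p / s
  1 / sum(p^2)
}

#' Null distribution of Levins niche breadth for one OTU
#'
#' The `replacement_multinomial` null (the default) redistributes the OTU's
#' total reads across the r states by a multinomial draw with probabilities
#' proportional to state total reads, i.e. random placement of each read with
#' replacement, and recomputes B on each replicate. The `quasiswap` null
#' recomputes the OTU's B from whole-matrix randomizations preserving both
#' row and column sums (via [vegan::permatswap]). Deterministic given `seed`:
#' the stream is `set.seed(seed)` followed by a single
#' `rmultinom(nPerm, total, stateTotals)` call (or the permatswap sequence).
#'
#' @param x an `OtuExperiment` (states = columns, e.g. from
#'   [aggregateStates()]) or an OTUs-by-states count matrix.
#' @param otuId the OTU (name or index).
#' @param nPerm number of null replicates.
#' @param method `"replacement_multinomial"` or `"quasiswap"`.
#' @param seed integer seed.
#' @return numeric vector of `nPerm` null B values.
#' @export
nullBreadthDistribution <- function(x, otuId, nPerm = 1000L,
                                    method = c("replacement_multinomial",
                                               "quasiswap"),
                                    seed = 1L) {
  method <- match.arg(method)
  m <- if (is(x, "OtuExperiment")) otuCounts(x, "otus_as_rows") else as.matrix(x)
  if (nPerm < 1) stop("nPerm must be >= 1")
  xi <- m[otuId, ]
  total <- sum(xi)
  if (total == 0) stop("OTU absent from every state")
  set.seed(seed)
  if (method == "replacement_multinomial") {
    draws <- stats::rmultinom(nPerm, total, colSums(m))
    prop <- draws / total
    1 / colSums(prop^2)
  } else {
    perm <- vegan::permatswap(m, method = "quasiswap", times = nPerm,
                              mtype = "count", fixedmar = "both")$perm
    row <- if (is.character(otuId)) match(otuId, rownames(m)) else otuId
    vapply(perm, function(pm) levinsBreadth(pm[row, ]), numeric(1))
  }
}

#' Classify one OTU against its niche-breadth null
#'
#' `generalized` if the observed B exceeds the upper null quantile,
#' `specialized` if it falls below the lower one, `neutral` otherwise (ties
#' are neutral). Quantiles are empirical, inclusive (type 7).
#'
#' @param bObs observed Levins breadth.
#' @param null numeric vector of null B values.
#' @param lowerQ,upperQ null quantiles (defaults 0.05 and 0.95).
#' @return `"generalized"`, `"neutral"` or `"specialized"`.
#' @export
classifyNiche <- function(bObs, null, lowerQ = 0.05, upperQ = 0.95) {
  if (!length(null)) stop("empty null distribution")
  if (bObs > .quant(null, upperQ)) "generalized"
  else if (bObs < .quant(null, lowerQ)) "specialized"
  else "neutral"
}

#' Classify all OTUs on the habitat-specialization gradient
#'
#' Computes the observed Levins breadth of every OTU over the resource states
#' (individual samples by default; pass one soil layer via [layerSubset()]),
#' builds the permutation null per OTU and classifies each one with
#' [classifyNiche()]. Each OTU's null stream is seeded
#' `childSeed(seed, otu_id)`, so the result is deterministic given `seed`,
#' independent of OTU order, and any single OTU can be reproduced standalone
#' with [nullBreadthDistribution()].
#'
#' @param x an `OtuExperiment` or OTUs-by-states count matrix.
#' @param nPerm null replicates per OTU (default 1000).
#' @param method null model, see [nullBreadthDistribution()].
#' @param seed integer master seed.
#' @param stateDefinition `"sample"` (default) or `"stand_type"`, see
#'   [aggregateStates()].
#' @param lowerQ,upperQ null quantiles.
#' @param rarefy if TRUE, rarefy all states to the minimum state depth before
#'   analysis (off by default; unequal depths shift the null).
#' @return a [NicheBreadthResult-class]. OTUs absent from every state are
#'   excluded with a message.
#' @export
classifyNicheTable <- function(x, nPerm = 1000L,
                               method = c("replacement_multinomial",
                                          "quasiswap"),
                               seed = 1L,
                               stateDefinition = c("sample", "stand_type"),
                               lowerQ = 0.05, upperQ = 0.95, rarefy = FALSE) {
  method <- match.arg(method)
  stateDefinition <- match.arg(stateDefinition)
  if (is(x, "OtuExperiment")) {
    x <- aggregateStates(x, stateDefinition)
    m <- otuCounts(x, "otus_as_rows")
  } else m <- as.matrix(x)
  if (rarefy) {
    set.seed(childSeed(seed, "rarefy"))
    m <- t(vegan::rrarefy(t(m), min(colSums(m))))
  }
  totals <- rowSums(m)
  absent <- totals == 0
  if (any(absent))
    message(sum(absent), " OTU(s) absent from all states excluded from classification")
  m <- m[!absent, , drop = FALSE]
  totals <- totals[!absent]
  r <- ncol(m)
  depths <- colSums(m)
  prop <- m / totals
  bObs <- 1 / rowSums(prop^2)

  ids <- rownames(m)
  q05 <- q95 <- numeric(length(ids))
  if (method == "replacement_multinomial") {
    for (i in seq_along(ids)) {
      set.seed(childSeed(seed, ids[i]))
      draws <- stats::rmultinom(nPerm, totals[i], depths)
      bNull <- 1 / colSums((draws / totals[i])^2)
      q05[i] <- .quant(bNull, lowerQ)
      q95[i] <- .quant(bNull, upperQ)
    }
  } else {
    set.seed(childSeed(seed, "quasiswap"))
    perm <- vegan::permatswap(m, method = "quasiswap", times = nPerm,
                              mtype = "count", fixedmar = "both")$perm
    bNullMat <- vapply(perm, function(pm)
      1 / rowSums((pm / rowSums(pm))^2), numeric(nrow(m)))
    q05 <- apply(bNullMat, 1, .quant, lowerQ)
    q95 <- apply(bNullMat, 1, .quant, upperQ)
  }
  cls <- ifelse(bObs > q95, "generalized",
                ifelse(bObs < q05, "specialized", "neutral"))
  new("NicheBreadthResult",
      results = S4Vectors::DataFrame(
        otu_id = ids, B_obs = unname(bObs), null_q05 = unname(q05),
        null_q95 = unname(q95), niche_class = unname(cls), row.names = ids),
      nPermutations = as.integer(nPerm), method = method,
      nStates = as.integer(r), seed = as.integer(seed),
      quantiles = c(lower = lowerQ, upper = upperQ),
      nExcluded = as.integer(sum(absent)))
}

#' @rdname classificationTable
#' @export
setMethod("classificationTable", "NicheBreadthResult", function(x) x@results)

#' @rdname subgroupLabels
#' @export
setMethod("subgroupLabels", "NicheBreadthResult", function(x)
  stats::setNames(x@results$niche_class, x@results$otu_id))

setMethod("show", "NicheBreadthResult", function(object) {
  cat("NicheBreadthResult:", nrow(object@results), "OTUs over",
      object@nStates, "states;", object@nPermutations,
      "permutations (", object@method, ", seed", object@seed, ")\n")
  print(table(factor(object@results$niche_class, levels = .NICHE_CLASSES)))
})
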