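#' Shannon-Wiener diversity index
#'
#' H = -sum(P_i ln P_i) with P_i the proportion of reads (or importance) of
#' taxon i; 0 * ln 0 is treated as 0. Natural logarithm, so H is in nats.
#'
#' @param counts non-negative vector with at least one positive entry.
#' @return numeric H >= 0.
#' @examples
#' shannonIndex(c(1, 1, 1, 1))  # log(4)
#' shannonIndex(5)              # 0: a single taxon
#' @export
shannonIndex <- function(counts) {
  if (any(counts < 0)) stop("counts must be non-negative")
  counts <- counts[counts > 0]
  if (!length(counts)) stop("all-zero profile")
  p <- counts / sum(counts)
  -sum(p * log(p))
}

#' Simpson diversity index
#'
#' The default is the unbiased (finite-sample) form on integer read counts:
#' D = 1 - sum(n_i (n_i - 1)) / (N (N - 1)), the probability that two reads
#' drawn without replacement belong to different taxa. For non-integer
#' weights (e.g. plant importance values) use `unbiased = FALSE` to get the
#' plug-in form 1 - sum(P_i^2).
#'
#' @param counts non-negative vector; integers required for the unbiased form.
#' @param unbiased logical.
#' @return numeric D in [0, 1].
#' @examples
#' simpsonIndex(c(2, 1, 1))                    # 1 - 2/12
#' simpsonIndex(c(0.5, 0.5), unbiased = FALSE) # 0.5
#' @export
simpsonIndex <- function(counts, unbiased = TRUE) {
  if (any(counts < 0)) stop("counts must be non-negative")
  counts <- counts[counts > 0]
  if (!length(counts)) stop("all-zero profile")
  if (!unbiased) {
    p <- counts / sum(counts)
    return(1 - sum(p^2))
  }
  if (any(counts != round(counts)))
    stop("unbiased Simpson needs integer counts; use unbiased = FALSE for weights")
  N <- sum(counts)
  if (N < 2) stop("unbiased Simpson needs N >= 2 reads")
  1 - sum(counts * (counts - 1)) / (N * (N - 1))
}

#' Evenness indices
#'
#' Shannon evenness = H / log(m), Simpson evenness = D / log(m), Pielou
#' evenness = H / log(m), with m the observed richness. All logarithms are
#' natural by default, which makes the Shannon and Pielou forms coincide;
#' `logBase = 10` reproduces the base-10 reading. Undefined for m < 2
#' (returned as NA).
#'
#' @param counts non-negative vector.
#' @param unbiased passed to [simpsonIndex()].
#' @param logBase base of the logarithm in the denominators (and in the
#'   Pielou numerator, which keeps Pielou in [0, 1]).
#' @return named numeric: `shannon_evenness`, `simpson_evenness`,
#'   `pielou_evenness`.
#' @export
evennessIndices <- function(counts, unbiased = TRUE, logBase = exp(1)) {
  m <- sum(counts > 0)
  if (m < 2)
    return(c(shannon_evenness = NA_real_, simpson_evenness = NA_real_,
             pielou_evenness = NA_real_))
  H <- shannonIndex(counts)
  D <- simpsonIndex(counts, unbiased = unbiased)
  logm <- log(m, base = logBase)
  c(shannon_evenness = H / log(m),          # H in nats over ln m
    simpson_evenness = D / logm,
    pielou_evenness = (H / log(logBase)) / logm)
}

#' The six plant diversity quantities from importance values
#'
#' Shannon-Wiener, Simpson (plug-in form, since importance values are not
#' counts), Shannon evenness, Simpson evenness, Pielou evenness and species
#' richness, computed from a vector of species importance values P_i.
#'
#' @param importance non-negative importance values, one per species.
#' @return named list of the six quantities.
#' @examples
#' plantDiversityIndices(c(0.25, 0.25, 0.25, 0.25))$shannon  # log(4)
#' @export
plantDiversityIndices <- function(importance) {
  ev <- evennessIndices(importance, unbiased = FALSE)
  list(shannon = shannonIndex(importance),
       simpson = simpsonIndex(importance, unbiased = FALSE),
       shannon_evenness = unname(ev["shannon_evenness"]),
       simpson_evenness = unname(ev["simpson_evenness"]),
       pielou_evenness = unname(ev["pielou_evenness"]),
       richness = sum(importance > 0))
}

#' Per-sample, per-subgroup alpha diversity
#'
#' Restricts each sample's counts to each subgroup's OTUs and computes
#' richness, Shannon, unbiased Simpson and the three evenness indices.
#' Subgroups with zero reads in a sample are reported absent (NA metrics,
#' richness 0); subgroups with a single read give NA Simpson.
#'
#' @param x an `OtuExperiment` or samples-by-OTUs count matrix.
#' @param classification an [AbundanceClassification-class] (collapsed
#'   classes) or [NicheBreadthResult-class] (niche classes); any OTUs not
#'   covered by the classification are ignored.
#' @return data.frame, one row per sample x subgroup, columns `sample_id`,
#'   `subgroup`, `richness`, `shannon`, `simpson`, `shannon_evenness`,
#'   `simpson_evenness`, `pielou_evenness`, `reads`.
#' @export
subgroupAlphaTable <- function(x, classification) {
  counts <- if (is(x, "OtuExperiment")) otuCounts(x) else x
  labels <- subgroupLabels(classification)
  lev <- if (is(classification, "AbundanceClassification"))
    .COLLAPSED_CLASSES else .NICHE_CLASSES
  ids <- intersect(names(labels), colnames(counts))
  out <- vector("list", nrow(counts) * length(lev))
  k <- 0L
  for (s in seq_len(nrow(counts))) for (g in lev) {
    k <- k + 1L
    v <- counts[s, ids[labels[ids] == g]]
    reads <- sum(v)
    if (reads == 0) {
      out[[k]] <- data.frame(sample_id = rownames(counts)[s], subgroup = g,
                             richness = 0L, shannon = NA_real_,
                             simpson = NA_real_, shannon_evenness = NA_real_,
                             simpson_evenness = NA_real_,
                             pielou_evenness = NA_real_, reads = 0)
      next
    }
    ev <- evennessIndices(v)
    out[[k]] <- data.frame(
      sample_id = rownames(counts)[s], subgroup = g,
      richness = sum(v > 0), shannon = shannonIndex(v),
      simpson = if (reads >= 2) simpsonIndex(v) else NA_real_,
      shannon_evenness = ev["shannon_evenness"],
      simpson_evenness = ev["simpson_evenness"],
      pielou_evenness = ev["pielou_evenness"], reads = reads,
      row.names = NULL)
  }
  do.call(rbind, out)
}

#' One-way ANOVA with compact letter display
#'
#' Classical one-way ANOVA followed by Tukey HSD pairwise comparisons at
#' `alpha`, summarized as a compact letter display: groups sharing a letter
#' are not significantly different. Groups with fewer than 2 observations are
#' excluded with a warning. When all values are identical the F statistic is
#' reported as 0 and all groups share one letter.
#'
#' @param values numeric vector.
#' @param groups grouping factor, same length.
#' @param alpha significance level for the letters.
#' @return list with `F`, `p`, `groups` (data.frame: group, n, mean, sd,
#'   letters) and `tukey` (the Tukey HSD table).
#' @examples
#' onewayAnovaLetters(c(1, 2, 1.5, 9, 10, 11), rep(c("a", "b"), each = 3))
#' @export
onewayAnovaLetters <- function(values, groups, alpha = 0.05) {
  groups <- as.factor(as.character(groups))
  keep <- groups %in% names(which(table(groups) >= 2))
  if (!all(keep)) {
    warning("excluding group(s) with < 2 observations: ",
            paste(setdiff(levels(groups), unique(groups[keep])), collapse = ", "))
    values <- values[keep]
    groups <- droplevels(groups[keep])
  }
  if (nlevels(groups) < 2) stop("need >= 2 groups with >= 2 observations")
  means <- tapply(values, groups, mean)
  if (stats::var(values) < .Machine$double.eps * max(1, mean(values)^2)) {
    g <- levels(groups)
    return(list(F = 0, p = 1,
                groups = data.frame(group = g, n = as.integer(table(groups)),
                                    mean = as.numeric(means),
                                    sd = as.numeric(tapply(values, groups, stats::sd)),
                                    letters = rep("a", length(g))),
                tukey = NULL))
  }
  fit <- stats::aov(values ~ groups)
  an <- summary(fit)[[1]]
  tukey <- stats::TukeyHSD(fit, conf.level = 1 - alpha)$groups
  sigPairs <- rownames(tukey)[tukey[, "p adj"] < alpha]
  letters <- .compactLetters(levels(groups), sigPairs, order(means, decreasing = TRUE))
  list(F = an[["F value"]][1], p = an[["Pr(>F)"]][1],
       groups = data.frame(group = levels(groups),
                           n = as.integer(table(groups)),
                           mean = as.numeric(means),
                           sd = as.numeric(tapply(values, groups, stats::sd)),
                           letters = letters[levels(groups)]),
       tukey = tukey)
}

# insert-and-absorb compact letter display
.compactLetters <- function(groups, sigPairs, meanOrder) {
  sets <- list(groups)
  for (pr in sigPairs) {
    ab <- strsplit(pr, "-", fixed = TRUE)[[1]]
    newSets <- list()
    for (s in sets) {
      if (all(ab %in% s)) {
        newSets <- c(newSets, list(setdiff(s, ab[1])), list(setdiff(s, ab[2])))
      } else newSets <- c(newSets, list(s))
    }
    # absorb subsets
    keep <- rep(TRUE, length(newSets))
    for (i in seq_along(newSets)) for (j in seq_along(newSets))
      if (i != j && keep[i] && keep[j] &&
          all(newSets[[i]] %in% newSets[[j]]) &&
          length(newSets[[i]]) < length(newSets[[j]]))
        keep[i] <- FALSE
    sets <- unique(newSets[keep])
  }
  ordered <- groups[meanOrder]
  firstIn <- vapply(sets, function(s) min(match(s, ordered)), numeric(1))
  sets <- sets[order(firstIn)]
  out <- stats::setNames(rep("", length(groups)), groups)
  for (i in seq_along(sets))
    for (g in sets[[i]]) out[g] <- paste0(out[g], letters[i])
  out
}
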