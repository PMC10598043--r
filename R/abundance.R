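#' Classify OTUs on the abundance gradient
#'
#' Assigns every OTU present in the analysed sample set to one of six
#' threshold-defined categories, using its minimum (n) and maximum (m)
#' relative abundance across samples and the thresholds `hi` (1%) and `lo`
#' (0.01%):
#'
#' * **AAT** permanently abundant: n > hi in all samples;
#' * **ART** permanently rare: m < lo in all samples;
#' * **MT** medium: lo <= n and m <= hi in all samples;
#' * **CAT** conditionally abundant: n >= lo everywhere and m > hi somewhere;
#' * **CRT** conditionally rare: n < lo somewhere and never above hi;
#' * **CRAT** conditionally rare and abundant: n < lo somewhere and m > hi
#'   somewhere.
#'
#' "Greater" and "less" are strict, so a value exactly at a threshold falls to
#' the middle rules. The six categories partition all classified OTUs and
#' collapse as AAT,CAT -> abundant; ART,CRT -> rare; MT,CRAT -> medium.
#' Classification is intended per soil layer: pass the relative abundances of
#' one layer's samples (see [layerSubset()]).
#'
#' @param ra samples-by-OTUs relative abundance matrix (from
#'   [relativeAbundance()]) restricted to the analysed sample set, or an
#'   `OtuExperiment`.
#' @param hi,lo relative-abundance thresholds; `lo < hi`.
#' @return an [AbundanceClassification-class]. OTUs absent from every sample
#'   are excluded (their number is reported in a message and the
#'   `nExcluded` slot).
#' @examples
#' m <- matrix(c(200, 150, 300, 1, 1, 1, 799, 849, 699) * 10L, 3,
#'             dimnames = list(paste0("S", 1:3), c("big", "tiny", "rest")))
#' cl <- classifyAbundance(relativeAbundance(m))
#' classificationTable(cl)
#' @export
classifyAbundance <- function(ra, hi = 0.01, lo = 0.0001) {
  if (is(ra, "OtuExperiment")) ra <- relativeAbundance(ra)
  if (lo >= hi) stop("lo must be < hi")
  mn <- apply(ra, 2, min)
  mx <- apply(ra, 2, max)
  present <- colSums(ra) > 0
  nExcluded <- sum(!present)
  if (nExcluded > 0)
    message(nExcluded, " OTU(s) absent from all samples excluded from classification")
  mn <- mn[present]; mx <- mx[present]
  category <- character(length(mn))
  category[mn > hi] <- "AAT"
  category[mx < lo] <- "ART"
  category[category == "" & mn >= lo & mx <= hi] <- "MT"
  category[category == "" & mn >= lo & mx > hi] <- "CAT"
  category[category == "" & mn < lo & mx <= hi] <- "CRT"
  category[category == ""] <- "CRAT"
  collapsed <- c(AAT = "abundant", CAT = "abundant", ART = "rare",
                 CRT = "rare", MT = "medium", CRAT = "medium")[category]
  new("AbundanceClassification",
      results = S4Vectors::DataFrame(
        otu_id = colnames(ra)[present], min_ra = unname(mn), max_ra = unname(mx),
        category = unname(category), collapsed = unname(collapsed),
        row.names = colnames(ra)[present]),
      thresholds = c(hi = hi, lo = lo),
      nExcluded = as.integer(nExcluded),
      sampleIds = rownames(ra))
}

#' @rdname classificationTable
#' @export
setMethod("classificationTable", "AbundanceClassification",
          function(x) x@results)

#' Per-OTU subgroup labels
#'
#' Named character vector mapping otu_id to its subgroup: the collapsed
#' abundant/medium/rare class for an [AbundanceClassification-class]
#' (`level = "category"` gives the six-way category instead), the
#' generalized/neutral/specialized class for a [NicheBreadthResult-class].
#'
#' @param x a classification result.
#' @param ... `level` for abundance classifications.
#' @rdname subgroupLabels
#' @export
setMethod("subgroupLabels", "AbundanceClassification",
  function(x, level = c("collapsed", "category")) {
    level <- match.arg(level)
    stats::setNames(x@results[[level]], x@results$otu_id)
  })

setMethod("show", "AbundanceClassification", function(object) {
  cat("AbundanceClassification:", nrow(object@results), "OTUs over",
      length(object@sampleIds), "samples (hi =", object@thresholds[1],
      ", lo =", object@thresholds[2], ")\n")
  print(table(factor(object@results$category, levels = .ABUNDANCE_CATEGORIES)))
  print(table(factor(object@results$collapsed, levels = .COLLAPSED_CLASSES)))
})

#' Subgroup OTU-count and read-abundance fractions
#'
#' For each subgroup: the fraction of classified OTUs it contains and the
#' fraction of total reads it carries (the "abundance ratio"). Both columns
#' sum to 1; empty subgroups are reported as 0, not omitted.
#'
#' @param x an `OtuExperiment` or samples-by-OTUs count matrix covering the
#'   sample set the classification was derived from.
#' @param classification an [AbundanceClassification-class] or
#'   [NicheBreadthResult-class].
#' @param level for abundance classifications, `"collapsed"` (default) or
#'   `"category"`.
#' @return data.frame with columns `subgroup`, `n_otus`, `otu_fraction`,
#'   `reads`, `read_fraction`.
#' @export
subgroupSummary <- function(x, classification, level = "collapsed") {
  counts <- if (is(x, "OtuExperiment")) otuCounts(x) else x
  labels <- if (is(classification, "AbundanceClassification"))
    subgroupLabels(classification, level = level)
  else subgroupLabels(classification)
  lev <- if (is(classification, "AbundanceClassification")) {
    if (level == "collapsed") .COLLAPSED_CLASSES else .ABUNDANCE_CATEGORIES
  } else .NICHE_CLASSES
  ids <- intersect(names(labels), colnames(counts))
  labels <- factor(labels[ids], levels = lev)
  reads <- colSums(counts[, ids, drop = FALSE])
  nOtus <- as.integer(table(labels))
  readsBy <- as.numeric(tapply(reads, labels, sum, default = 0))
  data.frame(subgroup = lev, n_otus = nOtus,
             otu_fraction = nOtus / sum(nOtus),
             reads = readsBy, read_fraction = readsBy / sum(readsBy))
}
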