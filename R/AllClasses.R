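#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays colData
#'   colData<- rowData
NULL

.STAND_TYPES <- c("S", "CF", "MF", "BF")
.SOIL_LAYERS <- c("topsoil", "subsoil")
.ABUNDANCE_CATEGORIES <- c("AAT", "ART", "MT", "CAT", "CRT", "CRAT")
.COLLAPSED_CLASSES <- c("abundant", "medium", "rare")
.NICHE_CLASSES <- c("generalized", "neutral", "specialized")
.SOIL_VARS <- c("dry_matter", "available_P", "organic_C",
                "NH4_N", "NO3_N", "NO2_N", "pH")

#' Container for an OTU count table with sample metadata
#'
#' `OtuExperiment` extends [SummarizedExperiment::SummarizedExperiment] with a
#' single `counts` assay holding non-negative integer read counts, OTUs as rows
#' and samples as columns (the Bioconductor convention; functions that follow
#' the samples-by-OTUs convention of classic OTU tables transpose internally).
#' Sample metadata (stand type, soil layer, coordinates, soil physicochemical
#' variables, plant diversity indices, species importance values) lives in
#' `colData`.
#'
#' @slot .. see [SummarizedExperiment::SummarizedExperiment].
#' @export
setClass("OtuExperiment", contains = "SummarizedExperiment")

setValidity("OtuExperiment", function(object) {
  msg <- character()
  if (!"counts" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'counts' is required")
  else {
    m <- SummarizedExperiment::assay(object, "counts")
    if (!is.numeric(m))
      msg <- c(msg, "counts must be numeric")
    else {
      if (any(m < 0)) msg <- c(msg, "counts must be non-negative")
      if (any(m != round(m))) msg <- c(msg, "counts must be integers")
    }
  }
  if (anyDuplicated(rownames(object))) msg <- c(msg, "duplicated otu_id")
  if (anyDuplicated(colnames(object))) msg <- c(msg, "duplicated sample_id")
  if (length(msg)) msg else TRUE
})

#' Per-OTU abundance-gradient classification
#'
#' Result of [classifyAbundance()]: one row per classified OTU with its
#' minimum and maximum relative abundance across the analysed sample set, the
#' six-way category (AAT, ART, MT, CAT, CRT, CRAT) and the collapsed
#' abundant/medium/rare class.
#'
#' @slot results `DataFrame` with columns `otu_id`, `min_ra`, `max_ra`,
#'   `category`, `collapsed`.
#' @slot thresholds numeric, the `hi` and `lo` relative-abundance thresholds.
#' @slot nExcluded integer, OTUs absent from every analysed sample.
#' @slot sampleIds character, the sample set the classification used.
#' @export
setClass("AbundanceClassification",
  representation(results = "DataFrame", thresholds = "numeric",
                 nExcluded = "integer", sampleIds = "character"))

setValidity("AbundanceClassification", function(object) {
  msg <- character()
  need <- c("otu_id", "min_ra", "max_ra", "category", "collapsed")
  if (!all(need %in% colnames(object@results)))
    msg <- c(msg, paste("results must have columns:", paste(need, collapse = ", ")))
  else {
    if (!all(object@results$category %in% .ABUNDANCE_CATEGORIES))
      msg <- c(msg, "unknown abundance category")
    if (!all(object@results$collapsed %in% .COLLAPSED_CLASSES))
      msg <- c(msg, "unknown collapsed class")
    if (anyDuplicated(object@results$otu_id))
      msg <- c(msg, "duplicated otu_id in results")
  }
  if (length(object@thresholds) != 2L || object@thresholds[2] >= object@thresholds[1])
    msg <- c(msg, "thresholds must be c(hi, lo) with lo < hi")
  if (length(msg)) msg else TRUE
})

#' Per-OTU habitat-specialization classification
#'
#' Result of [classifyNicheTable()]: observed Levins niche breadth, null
#' quantiles and the generalized/neutral/specialized call for every OTU.
#'
#' @slot results `DataFrame` with columns `otu_id`, `B_obs`, `null_q05`,
#'   `null_q95`, `niche_class`.
#' @slot nPermutations integer, null-model replicates per OTU.
#' @slot method character, `"replacement_multinomial"` or `"quasiswap"`.
#' @slot nStates integer, number of resource states r.
#' @slot seed integer seed that reproduces the null streams.
#' @slot quantiles numeric, lower and upper null quantiles used.
#' @slot nExcluded integer, OTUs absent from every state.
#' @export
setClass("NicheBreadthResult",
  representation(results = "DataFrame", nPermutations = "integer",
                 method = "character", nStates = "integer", seed = "integer",
                 quantiles = "numeric", nExcluded = "integer"))

setValidity("NicheBreadthResult", function(object) {
  msg <- character()
  need <- c("otu_id", "B_obs", "null_q05", "null_q95", "niche_class")
  if (!all(need %in% colnames(object@results)))
    msg <- c(msg, paste("results must have columns:", paste(need, collapse = ", ")))
  else {
    r <- object@results
    tol <- 1e-8
    if (any(r$B_obs < 1 - tol | r$B_obs > object@nStates + tol))
      msg <- c(msg, "B_obs outside [1, r]")
    if (any(r$null_q05 > r$null_q95 + tol))
      msg <- c(msg, "null_q05 > null_q95")
    if (!all(r$niche_class %in% .NICHE_CLASSES))
      msg <- c(msg, "unknown niche class")
  }
  if (length(msg)) msg else TRUE
})

#' Result of a permutation test
#'
#' Statistic, permutation p-value and the reproducibility contract (seed,
#' permutation count, method). For one-sided statistics the p-value follows
#' the convention p = (1 + #\{null >= observed\}) / (1 + n_permutations);
#' exact enumeration (all distinct relabelings, the identity included) is
#' reported with `nPermutations` equal to the enumeration size and
#' p = #\{null >= observed\} / n.
#'
#' @slot statistic numeric.
#' @slot pValue numeric in (0, 1].
#' @slot nPermutations integer.
#' @slot seed integer (NA for exact enumeration).
#' @slot method character description.
#' @export
setClass("PermutationTestResult",
  representation(statistic = "numeric", pValue = "numeric",
                 nPermutations = "integer", seed = "integer",
                 method = "character"))

setValidity("PermutationTestResult", function(object) {
  msg <- character()
  if (!is.na(object@pValue) && (object@pValue <= 0 || object@pValue > 1))
    msg <- c(msg, "pValue must be in (0, 1]")
  if (length(msg)) msg else TRUE
})

#' Result of an NMDS ordination
#'
#' @slot coordinates numeric matrix, samples x k, column-centred.
#' @slot stress numeric, Kruskal stress-1 of the best start.
#' @slot k integer, embedding dimension.
#' @slot converged logical.
#' @slot seed integer.
#' @slot nStarts integer random starts tried.
#' @export
setClass("OrdinationResult",
  representation(coordinates = "matrix", stress = "numeric", k = "integer",
                 converged = "logical", seed = "integer", nStarts = "integer"))

setValidity("OrdinationResult", function(object) {
  msg <- character()
  if (object@stress < 0) msg <- c(msg, "stress must be >= 0")
  if (ncol(object@coordinates) != object@k)
    msg <- c(msg, "coordinates must have k columns")
  if (max(abs(colMeans(object@coordinates))) > 1e-6)
    msg <- c(msg, "coordinates must be column-centred")
  if (length(msg)) msg else TRUE
})

#' Result of a redundancy analysis
#'
#' @slot constrainedEigenvalues,unconstrainedEigenvalues numeric vectors.
#' @slot constrainedFraction numeric in [0, 1]: variance of the community
#'   table explained by the explanatory variables.
#' @slot siteScores numeric matrix, samples x constrained axes.
#' @slot variableScores numeric matrix, explanatory variables x axes
#'   (correlations of variables with site scores).
#' @slot totalVariance numeric.
#' @slot aliased character, dropped collinear columns.
#' @export
setClass("RdaResult",
  representation(constrainedEigenvalues = "numeric",
                 unconstrainedEigenvalues = "numeric",
                 constrainedFraction = "numeric",
                 siteScores = "matrix", variableScores = "matrix",
                 totalVariance = "numeric", aliased = "character"))

setValidity("RdaResult", function(object) {
  msg <- character()
  if (any(object@constrainedEigenvalues < -1e-9) ||
      any(object@unconstrainedEigenvalues < -1e-9))
    msg <- c(msg, "eigenvalues must be non-negative")
  f <- object@constrainedFraction
  if (f < -1e-9 || f > 1 + 1e-9)
    msg <- c(msg, "constrainedFraction must be in [0, 1]")
  tot <- sum(object@constrainedEigenvalues) + sum(object@unconstrainedEigenvalues)
  if (abs(tot - object@totalVariance) > 1e-6 * max(1, object@totalVariance))
    msg <- c(msg, "eigenvalues must sum to the total variance")
  if (length(msg)) msg else TRUE
})

#' Parameters of the synthetic community generator
#'
#' The defaults state the emulated field design: 4 stand types (S, CF, MF, BF)
#' with 3/3/3/11 quadrats, two soil layers per quadrat (40 samples), 1500
#' OTUs, sequencing depths uniform on 46,595-73,284 reads, planted
#' abundant/medium/rare fractions 0.03/0.07/0.90 and planted
#' generalist/neutral/specialist fractions 0.05/0.30/0.65.
#'
#' @slot nStandTypes integer.
#' @slot quadratsPerStand integer vector, one entry per stand type.
#' @slot nLayers integer.
#' @slot nOtus integer.
#' @slot archetypeFractions numeric, proportions over
#'   (generalist, neutral, specialist), summing to 1.
#' @slot abundanceClassFractions numeric, proportions over
#'   (abundant, medium, rare), summing to 1.
#' @slot lognormalSigma numeric, spread of the within-class abundance spectrum.
#' @slot depthRange integer length 2, reads per sample.
#' @slot specialistOccupancy integer, stand types a specialist calls home.
#' @slot habitatEffect numeric >= 1, fold-enrichment of a specialist in its
#'   home stands (and fold-suppression elsewhere).
#' @slot evenGeneralists logical; if TRUE planted generalists receive a
#'   deterministic depth-proportional read allocation ("perfectly even"),
#'   otherwise they are drawn multinomially like every other OTU.
#' @slot coordinateBox numeric, c(lonMin, lonMax, latMin, latMax, elevMin, elevMax).
#' @slot covariateEffect numeric >= 0, scaling of between-stand soil-variable
#'   mean differences (0 = covariates independent of stand type).
#' @slot mediumBand,rareBand numeric length 2, expected relative-abundance
#'   bands of the planted medium and rare classes (the abundant band is solved
#'   from the remaining read mass).
#' @slot seed integer.
#' @export
setClass("SimulationParams",
  representation(nStandTypes = "integer", quadratsPerStand = "integer",
                 nLayers = "integer", nOtus = "integer",
                 archetypeFractions = "numeric",
                 abundanceClassFractions = "numeric",
                 lognormalSigma = "numeric", depthRange = "integer",
                 specialistOccupancy = "integer", habitatEffect = "numeric",
                 evenGeneralists = "logical", coordinateBox = "numeric",
                 covariateEffect = "numeric", mediumBand = "numeric",
                 rareBand = "numeric", seed = "integer"))

setValidity("SimulationParams", function(object) {
  msg <- character()
  if (length(object@quadratsPerStand) != object@nStandTypes)
    msg <- c(msg, "quadratsPerStand must have one entry per stand type")
  if (abs(sum(object@archetypeFractions) - 1) > 1e-9)
    msg <- c(msg, "archetypeFractions must sum to 1")
  if (abs(sum(object@abundanceClassFractions) - 1) > 1e-9)
    msg <- c(msg, "abundanceClassFractions must sum to 1")
  if (any(object@depthRange <= 0) || object@depthRange[1] > object@depthRange[2])
    msg <- c(msg, "depthRange must be positive and increasing")
  if (object@habitatEffect < 1)
    msg <- c(msg, "habitatEffect must be >= 1")
  if (object@specialistOccupancy < 1 ||
      object@specialistOccupancy >= object@nStandTypes)
    msg <- c(msg, "specialistOccupancy must be in [1, nStandTypes)")
  if (length(object@coordinateBox) != 6)
    msg <- c(msg, "coordinateBox must be length 6")
  if (object@mediumBand[1] >= object@mediumBand[2] ||
      object@rareBand[1] >= object@rareBand[2])
    msg <- c(msg, "abundance bands must be increasing")
  if (length(msg)) msg else TRUE
})
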