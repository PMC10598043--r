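#' Create simulation parameters
#'
#' Builds a [SimulationParams-class] object. The defaults state the emulated
#' study design: 20 quadrats over 4 stand types (3 shrub, 3 coniferous,
#' 3 mixed, 11 broad-leaved), two soil layers per quadrat, 1500 OTUs,
#' per-sample sequencing depth uniform on 46,595-73,284 reads, planted
#' abundance-class fractions 0.03/0.07/0.90 (abundant/medium/rare) and
#' habitat-archetype fractions 0.05/0.30/0.65
#' (generalist/neutral/specialist).
#'
#' The expected relative-abundance spectrum is class-banded: medium and rare
#' OTUs are placed log-uniformly (via a lognormal rank transform with spread
#' `lognormalSigma`) inside `mediumBand` and `rareBand`; the abundant class
#' absorbs the remaining read mass, which keeps every sample's expected
#' composition summing to exactly 1 while planted abundant OTUs stay above 1%
#' and planted rare OTUs below 0.01% expected relative abundance.
#'
#' @param nStandTypes,quadratsPerStand,nLayers,nOtus design dimensions.
#' @param archetypeFractions proportions over (generalist, neutral, specialist).
#' @param abundanceClassFractions proportions over (abundant, medium, rare).
#' @param lognormalSigma spread of the within-class abundance spectrum.
#' @param depthRange integer length 2, reads per sample.
#' @param specialistOccupancy number of home stand types per specialist.
#' @param habitatEffect fold-enrichment of specialists in home stands
#'   (and fold-suppression elsewhere).
#' @param evenGeneralists plant generalists with a deterministic
#'   depth-proportional allocation (perfectly even) instead of a multinomial
#'   draw. Multinomial sampling noise is exactly what the niche null model
#'   reproduces, so only sub-multinomial evenness is detectable as
#'   "generalized"; see the methods vignette.
#' @param coordinateBox c(lonMin, lonMax, latMin, latMax, elevMin, elevMax),
#'   decimal degrees and metres.
#' @param covariateEffect scaling of between-stand covariate differences
#'   (0 = covariates independent of stand type, 1 = field-calibrated values).
#' @param mediumBand,rareBand expected relative-abundance bands of the planted
#'   medium and rare classes.
#' @param seed integer seed; the generator is deterministic given the seed.
#' @return a `SimulationParams` object.
#' @export
simulationParams <- function(nStandTypes = 4L,
                             quadratsPerStand = c(3L, 3L, 3L, 11L),
                             nLayers = 2L,
                             nOtus = 1500L,
                             archetypeFractions = c(generalist = 0.05,
                                                    neutral = 0.30,
                                                    specialist = 0.65),
                             abundanceClassFractions = c(abundant = 0.03,
                                                         medium = 0.07,
                                                         rare = 0.90),
                             lognormalSigma = 1,
                             depthRange = c(46595L, 73284L),
                             specialistOccupancy = 1L,
                             habitatEffect = 4,
                             evenGeneralists = TRUE,
                             coordinateBox = c(117.42, 117.57, 36.40, 36.49,
                                               300, 760),
                             covariateEffect = 1,
                             mediumBand = c(0.0015, 0.0026),
                             rareBand = c(0.00004, 0.000095),
                             seed = 1L) {
  new("SimulationParams",
      nStandTypes = as.integer(nStandTypes),
      quadratsPerStand = as.integer(quadratsPerStand),
      nLayers = as.integer(nLayers),
      nOtus = as.integer(nOtus),
      archetypeFractions = archetypeFractions,
      abundanceClassFractions = abundanceClassFractions,
      lognormalSigma = lognormalSigma,
      depthRange = as.integer(depthRange),
      specialistOccupancy = as.integer(specialistOccupancy),
      habitatEffect = habitatEffect,
      evenGeneralists = evenGeneralists,
      coordinateBox = coordinateBox,
      covariateEffect = covariateEffect,
      mediumBand = mediumBand,
      rareBand = rareBand,
      seed = as.integer(seed))
}

# exact integer split of n into groups with the given fractions
.splitCounts <- function(n, fractions) {
  k <- floor(n * fractions)
  rem <- n - sum(k)
  if (rem > 0) {
    extra <- order(n * fractions - k, decreasing = TRUE)[seq_len(rem)]
    k[extra] <- k[extra] + 1L
  }
  as.integer(k)
}

# log-uniform placement inside a band, ranked by a lognormal draw
.bandValues <- function(n, band, sigma) {
  if (n == 0L) return(numeric(0))
  u <- stats::pnorm(stats::rnorm(n, 0, sigma), 0, sigma)
  band[1] * (band[2] / band[1])^u
}

#' Simulate a soil bacterial community with planted ground truth
#'
#' Generates an OTU table over `nLayers` soil layers of the quadrat design,
#' sample metadata (via [simulateCovariates()]) and a truth table recording
#' each OTU's planted habitat archetype, abundance class and home stands.
#'
#' Expected relative abundances follow the class-banded spectrum described in
#' [simulationParams()]. Specialists have their expected abundance multiplied
#' by `habitatEffect` in home stands and divided by it elsewhere; the
#' specialist pool is then rescaled within each sample so its total expected
#' mass is preserved, which keeps the planted abundance bands of all other
#' OTUs exact. Counts are drawn multinomially per sample at a depth drawn
#' uniformly from `depthRange`; planted generalists are allocated
#' deterministically when `evenGeneralists` is TRUE. The two layers share the
#' OTU plan (same expectations, archetypes and homes) with independent
#' sampling noise.
#'
#' @param params a [SimulationParams-class] object.
#' @return a list with elements `experiment` (an [OtuExperiment-class] with
#'   full `colData`) and `truth` (a `DataFrame` with columns `otu_id`,
#'   `archetype`, `abundance_class`, `home_stands`, `expected_ra`).
#' @examples
#' sim <- simulateCommunity(simulationParams(nOtus = 200L, seed = 7L))
#' sim$experiment
#' table(sim$truth$archetype, sim$truth$abundance_class)
#' @export
simulateCommunity <- function(params) {
  stopifnot(is(params, "SimulationParams"))
  p <- params
  set.seed(p@seed)
  stands <- .STAND_TYPES[seq_len(p@nStandTypes)]
  quadStand <- rep(stands, p@quadratsPerStand)
  nq <- length(quadStand)
  quadIds <- sprintf("Q%02d", seq_len(nq))
  layers <- .SOIL_LAYERS[seq_len(p@nLayers)]

  n <- p@nOtus
  otuIds <- sprintf("OTU%04d", seq_len(n))
  clsN <- .splitCounts(n, p@abundanceClassFractions)
  cls <- rep(.COLLAPSED_CLASSES, clsN)
  archN <- .splitCounts(n, p@archetypeFractions)
  arch <- sample(rep(c("generalist", "neutral", "specialist"), archN))

  # expected relative-abundance spectrum, class-banded
  hi <- 0.01
  base <- numeric(n)
  base[cls == "medium"] <- .bandValues(clsN[2], p@mediumBand, p@lognormalSigma)
  base[cls == "rare"] <- .bandValues(clsN[3], p@rareBand, p@lognormalSigma)
  massA <- 1 - sum(base)
  if (clsN[1] > 0L) {
    if (massA / clsN[1] < 1.3 * hi)
      stop("planted abundance classes infeasible: ", clsN[1],
           " OTUs cannot all stay above the ", hi,
           " relative-abundance threshold (available mass ",
           signif(massA, 3), ")")
    a <- .bandValues(clsN[1], c(1 / 1.2, 1.2), p@lognormalSigma)
    base[cls == "abundant"] <- a * massA / sum(a)
  } else {
    base <- base / sum(base)  # no abundant class: renormalize (bands approximate)
  }

  # home stands for specialists
  homes <- vector("list", n)
  isSpec <- arch == "specialist"
  for (i in which(isSpec))
    homes[[i]] <- sample(stands, p@specialistOccupancy)

  # per-stand expected proportions (specialist pool mass preserved per sample)
  e <- p@habitatEffect
  expected <- matrix(base, n, length(stands), dimnames = list(otuIds, stands))
  if (any(isSpec) && e > 1) {
    for (s in seq_along(stands)) {
      w <- base[isSpec]
      home <- vapply(homes[isSpec], function(h) stands[s] %in% h, logical(1))
      w <- w * ifelse(home, e, 1 / e)
      expected[isSpec, s] <- w * sum(base[isSpec]) / sum(w)
    }
  }

  # counts per sample
  isGen <- arch == "generalist" & p@evenGeneralists
  nSamples <- nq * length(layers)
  counts <- matrix(0L, n, nSamples)
  sampleIds <- character(nSamples)
  meta <- data.frame(sample_id = character(nSamples), quadrat = character(nSamples),
                     stand_type = character(nSamples), soil_layer = character(nSamples),
                     stringsAsFactors = FALSE)
  j <- 0L
  for (ly in layers) for (q in seq_len(nq)) {
    j <- j + 1L
    s <- match(quadStand[q], stands)
    depth <- sample(seq(p@depthRange[1], p@depthRange[2]), 1L)
    pv <- expected[, s]
    cg <- integer(n)
    if (any(isGen)) cg[isGen] <- as.integer(round(depth * pv[isGen]))
    rest <- depth - sum(cg)
    if (rest < 0) stop("generalist mass exceeds sample depth; lower archetype fractions")
    ci <- cg
    if (any(!isGen) && rest > 0)
      ci[!isGen] <- as.integer(stats::rmultinom(1L, rest, pv[!isGen]))
    counts[, j] <- ci
    sampleIds[j] <- paste0(quadIds[q], "_", substr(ly, 1, 3))
    meta[j, ] <- list(sampleIds[j], quadIds[q], quadStand[q], ly)
  }
  dimnames(counts) <- list(otuIds, sampleIds)

  cd <- simulateCovariates(p, meta, .continueStream = TRUE)
  exp <- OtuExperiment(counts, sampleData = cd)
  S4Vectors::metadata(exp)$simulation <- list(seed = p@seed, nOtus = n,
                                              habitatEffect = e)
  truth <- S4Vectors::DataFrame(
    otu_id = otuIds, archetype = arch, abundance_class = cls,
    home_stands = vapply(homes, function(h)
      if (is.null(h)) NA_character_ else paste(h, collapse = ","), character(1)),
    expected_ra = base, row.names = otuIds)
  list(experiment = exp, truth = truth)
}

# stand x layer default means/sds of the seven soil variables
# (field-calibrated values for dry matter, available P, organic C,
#  NH4-N, NO3-N, NO2-N, pH)
.soilPlan <- function() {
  vars <- .SOIL_VARS
  mk <- function(...) matrix(c(...), nrow = 4, byrow = TRUE,
                             dimnames = list(c("S", "CF", "MF", "BF"), vars))
  list(
    topsoil = list(
      mean = mk(0.987, 8.341, 2.641, 11.637, 7.614, 4.628, 5.010,
                0.982, 3.273, 4.032, 11.551, 8.443, 4.221, 4.693,
                0.983, 3.923, 3.943, 12.692, 7.240, 4.561, 4.727,
                0.978, 2.614, 3.496, 14.121, 7.304, 3.970, 5.274),
      sd = mk(0.002, 1.069, 0.688, 1.212, 0.934, 3.044, 0.157,
              0.005, 1.627, 0.757, 0.703, 2.375, 0.919, 0.257,
              0.003, 2.370, 0.576, 0.514, 1.709, 1.276, 0.340,
              0.009, 1.535, 1.065, 4.760, 1.848, 1.008, 0.492)),
    subsoil = list(
      mean = mk(0.988, 2.523, 1.539, 8.986, 5.655, 2.874, 5.017,
                0.986, 3.005, 2.568, 11.970, 7.101, 3.683, 4.767,
                0.986, 1.903, 1.778, 10.633, 5.767, 3.292, 4.837,
                0.984, 3.294, 2.060, 11.658, 7.136, 3.928, 5.285),
      sd = mk(0.001, 1.887, 0.779, 1.076, 1.747, 0.464, 0.068,
              0.003, 2.564, 0.680, 3.779, 1.729, 0.252, 0.328,
              0.003, 0.662, 0.505, 1.320, 0.363, 0.800, 0.188,
              0.005, 1.314, 0.789, 3.992, 2.916, 2.020, 0.416)))
}

.TREE_POOLS <- list(S = c("T09", "T10"), CF = c("T01", "T02"),
                    MF = c("T01", "T02", "T03", "T04"),
                    BF = c("T03", "T04", "T05", "T06", "T07", "T08"))
.SHRUB_POOLS <- list(S = c("U01", "U02", "U03", "U04"), CF = c("U01", "U05"),
                     MF = c("U02", "U05", "U06"), BF = c("U03", "U04", "U05", "U06"))

.dirichlet <- function(k) { g <- stats::rgamma(k, 1); g / sum(g) }

#' Simulate sample covariates
#'
#' Fills per-sample metadata: quadrat coordinates uniform in the coordinate
#' box (shared by the two layers of a quadrat), soil physicochemical
#' variables drawn normally around stand-and-layer-specific means
#' (field-calibrated defaults; `covariateEffect` scales the between-stand
#' mean differences -- at 0 the stand-specific standard deviations are pooled
#' too, so covariates are fully independent of stand type -- and
#' `soilOffsets` can shift individual stand means), species
#' importance-value vectors for the tree and shrub layers (Dirichlet weights
#' over stand-specific species pools) and the six plant diversity indices
#' computed from them via [plantDiversityIndices()].
#'
#' @param params a [SimulationParams-class] object.
#' @param samples data.frame with columns `sample_id`, `quadrat`,
#'   `stand_type`, `soil_layer`.
#' @param soilOffsets optional named list: stand type -> named numeric vector
#'   added to that stand's soil-variable means (e.g.
#'   `list(BF = c(pH = 0.5))`).
#' @param .continueStream internal: continue the caller's RNG stream instead
#'   of seeding from `params@seed`.
#' @return a `DataFrame`, one row per sample.
#' @export
simulateCovariates <- function(params, samples, soilOffsets = NULL,
                               .continueStream = FALSE) {
  p <- params
  if (!.continueStream) set.seed(childSeed(p@seed, "covariates"))
  quads <- unique(samples$quadrat)
  nq <- length(quads)
  box <- p@coordinateBox
  coord <- data.frame(
    quadrat = quads,
    longitude_deg = stats::runif(nq, box[1], box[2]),
    latitude_deg = stats::runif(nq, box[3], box[4]),
    elevation_m = stats::runif(nq, box[5], box[6]))

  plan <- .soilPlan()
  eff <- p@covariateEffect
  soil <- matrix(NA_real_, nrow(samples), length(.SOIL_VARS),
                 dimnames = list(samples$sample_id, .SOIL_VARS))
  for (ly in unique(samples$soil_layer)) {
    pl <- plan[[ly]]
    grand <- colMeans(pl$mean)
    grandSd <- colMeans(pl$sd)
    for (st in unique(samples$stand_type)) {
      mu <- grand + eff * (pl$mean[st, ] - grand)
      sdv <- grandSd + min(eff, 1) * (pl$sd[st, ] - grandSd)
      if (!is.null(soilOffsets[[st]])) {
        off <- soilOffsets[[st]]
        mu[names(off)] <- mu[names(off)] + off
      }
      idx <- which(samples$soil_layer == ly & samples$stand_type == st)
      for (v in seq_along(.SOIL_VARS))
        soil[idx, v] <- stats::rnorm(length(idx), mu[v], sdv[v])
    }
  }

  treeSpp <- sort(unique(unlist(.TREE_POOLS)))
  shrubSpp <- sort(unique(unlist(.SHRUB_POOLS)))
  treeImp <- matrix(0, nq, length(treeSpp), dimnames = list(quads, treeSpp))
  shrubImp <- matrix(0, nq, length(shrubSpp), dimnames = list(quads, shrubSpp))
  qStand <- samples$stand_type[match(quads, samples$quadrat)]
  for (q in seq_len(nq)) {
    tp <- if (eff > 0) .TREE_POOLS[[qStand[q]]] else treeSpp
    sp <- if (eff > 0) .SHRUB_POOLS[[qStand[q]]] else shrubSpp
    tk <- sample(seq(min(2L, length(tp)), length(tp)), 1L)
    treeImp[q, sample(tp, tk)] <- .dirichlet(tk)
    sk <- sample(seq(min(2L, length(sp)), length(sp)), 1L)
    shrubImp[q, sample(sp, sk)] <- .dirichlet(sk)
  }
  plantDiv <- t(vapply(seq_len(nq), function(q) {
    imp <- c(treeImp[q, ], shrubImp[q, ])
    unlist(plantDiversityIndices(imp[imp > 0]))
  }, numeric(6)))
  rownames(plantDiv) <- quads

  qi <- match(samples$quadrat, quads)
  out <- S4Vectors::DataFrame(
    sample_id = samples$sample_id,
    quadrat = samples$quadrat,
    stand_type = factor(samples$stand_type, levels = .STAND_TYPES),
    soil_layer = factor(samples$soil_layer, levels = .SOIL_LAYERS),
    longitude_deg = coord$longitude_deg[qi],
    latitude_deg = coord$latitude_deg[qi],
    elevation_m = coord$elevation_m[qi],
    row.names = samples$sample_id)
  for (v in .SOIL_VARS) out[[v]] <- soil[, v]
  for (v in colnames(plantDiv)) out[[paste0("plant_", v)]] <- plantDiv[qi, v]
  out$tree_importance <- treeImp[qi, , drop = FALSE]
  out$shrub_importance <- shrubImp[qi, , drop = FALSE]
  out
}

setMethod("show", "SimulationParams", function(object) {
  cat("SimulationParams:", object@nOtus, "OTUs,",
      sum(object@quadratsPerStand), "quadrats x", object@nLayers, "layers\n")
  cat("  archetypes (gen/neu/spec):",
      paste(object@archetypeFractions, collapse = "/"), "\n")
  cat("  abundance classes (A/M/R):",
      paste(object@abundanceClassFractions, collapse = "/"), "\n")
  cat("  habitatEffect:", object@habitatEffect, " seed:", object@seed, "\n")
})
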