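#' Run the full dual-gradient analysis
#'
#' Orchestrates the pipeline from one configuration: simulate (or ingest) an
#' OTU table and metadata, classify every OTU on the abundance and
#' habitat-specialization gradients per soil layer, compute per-subgroup
#' summaries and alpha diversity with one-way ANOVA letters by stand type,
#' and run the community-structure battery (NMDS, ANOSIM by stand, Mantel
#' against soil chemistry / plant diversity / spatial distance / tree and
#' shrub species composition, RDA with model and per-variable permutation
#' tests) for each subgroup. All randomized stages draw their seeds
#' deterministically from the master seed via [childSeed()], so any stage run
#' standalone with the same derived seed reproduces its in-pipeline output.
#'
#' @param config a list with elements:
#'   * `params` (a [SimulationParams-class]) **or** `otuTable` +
#'     `metadata` (file paths, read via [readOtuTable()] /
#'     [readSampleMetadata()]);
#'   * `seed` (mandatory master seed);
#'   * optional `layers` (default both), `hi`, `lo` (abundance thresholds),
#'     `nichePerm` (default 1000), `nicheMethod`, `testPerm` (default 999),
#'     `tests` (subset of `c("nmds", "anosim", "mantel", "rda")`),
#'     `outDir` (directory for TSV outputs + manifest; NULL = no files).
#' @return (invisibly) a nested list of per-layer results.
#' @export
runPipeline <- function(config) {
  cfg <- .validateConfig(config)
  res <- list(config = cfg[setdiff(names(cfg), "params")])

  if (!is.null(cfg$params)) {
    p <- cfg$params
    p@seed <- childSeed(cfg$seed, "simulate")
    sim <- simulateCommunity(p)
    exp <- sim$experiment
    res$truth <- sim$truth
  } else {
    exp <- readOtuTable(cfg$otuTable, orientation = cfg$orientation)
    meta <- readSampleMetadata(cfg$metadata)
    exp <- OtuExperiment(otuCounts(exp, "otus_as_rows"), sampleData = meta)
  }
  res$experiment <- exp

  for (layer in cfg$layers) {
    lx <- layerSubset(exp, layer, dropEmpty = TRUE)
    meta <- sampleData(lx)
    ra <- relativeAbundance(lx)
    abund <- classifyAbundance(ra, hi = cfg$hi, lo = cfg$lo)
    niche <- classifyNicheTable(lx, nPerm = cfg$nichePerm,
                                method = cfg$nicheMethod,
                                seed = childSeed(cfg$seed, paste0("niche_", layer)))
    lr <- list(abundance = abund, niche = niche,
               summary_abundance = subgroupSummary(lx, abund),
               summary_niche = subgroupSummary(lx, niche),
               alpha_abundance = subgroupAlphaTable(lx, abund),
               alpha_niche = subgroupAlphaTable(lx, niche))

    # niche width and alpha diversity by stand, with ANOVA letters
    lr$niche_by_stand <- .nicheByStand(lx, niche, meta)
    lr$alpha_anova <- rbind(
      .alphaAnova(lr$alpha_abundance, meta, "abundance"),
      .alphaAnova(lr$alpha_niche, meta, "niche"))

    lr$comparisons <- .subgroupComparisons(lx, abund, niche, meta, cfg, layer)
    res[[layer]] <- lr
  }

  if (!is.null(cfg$outDir)) .writeBundle(res, cfg)
  invisible(res)
}

.validateConfig <- function(config) {
  cfg <- config
  if (is.null(cfg$seed)) stop("config$seed is mandatory")
  if (is.null(cfg$params)) {
    if (is.null(cfg$otuTable))
      stop("config needs either 'params' or 'otuTable' + 'metadata'")
    if (!file.exists(cfg$otuTable))
      stop("otuTable path does not exist: ", cfg$otuTable)
    if (is.null(cfg$metadata) || !file.exists(cfg$metadata))
      stop("metadata path missing or nonexistent (required for layer split, ",
           "ANOSIM groups and Mantel covariates)")
  }
  cfg$layers <- cfg$layers %||% .SOIL_LAYERS
  cfg$hi <- cfg$hi %||% 0.01
  cfg$lo <- cfg$lo %||% 0.0001
  cfg$nichePerm <- cfg$nichePerm %||% 1000L
  cfg$nicheMethod <- cfg$nicheMethod %||% "replacement_multinomial"
  cfg$testPerm <- cfg$testPerm %||% 999L
  cfg$tests <- cfg$tests %||% c("nmds", "anosim", "mantel", "rda")
  cfg$orientation <- cfg$orientation %||% "otus_as_rows"
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.nicheByStand <- function(lx, niche, meta) {
  tab <- classificationTable(niche)
  labels <- subgroupLabels(niche)
  counts <- otuCounts(lx)
  out <- list()
  for (g in .NICHE_CLASSES) {
    ids <- names(labels)[labels == g]
    if (!length(ids)) next
    # per-sample mean breadth of the subgroup's OTUs present in that sample
    for (s in rownames(counts)) {
      present <- ids[counts[s, ids] > 0]
      if (!length(present)) next
      out[[length(out) + 1L]] <- data.frame(
        sample_id = s, stand_type = as.character(meta[s, "stand_type"]),
        subgroup = g, mean_B = mean(tab[present, "B_obs"]),
        n_otus = length(present))
    }
  }
  do.call(rbind, out)
}

.alphaAnova <- function(alpha, meta, gradient) {
  out <- list()
  for (g in unique(alpha$subgroup)) for (metric in c("shannon", "richness")) {
    sub <- alpha[alpha$subgroup == g & !is.na(alpha[[metric]]), ]
    if (nrow(sub) < 4) next
    st <- as.character(meta[sub$sample_id, "stand_type"])
    if (length(unique(st)) < 2) next
    av <- tryCatch(onewayAnovaLetters(sub[[metric]], st),
                   error = function(e) NULL)
    if (is.null(av)) next
    out[[length(out) + 1L]] <- data.frame(
      gradient = gradient, subgroup = g, metric = metric,
      F = av$F, p = av$p,
      letters = paste(av$groups$group, av$groups$letters,
                      sep = ":", collapse = " "))
  }
  do.call(rbind, out)
}

.subgroupComparisons <- function(lx, abund, niche, meta, cfg, layer) {
  counts <- otuCounts(lx)
  groups <- meta$stand_type
  envSets <- c("soil_vars", "plant_diversity", "tree_importance",
               "shrub_importance")
  envD <- lapply(stats::setNames(envSets, envSets), function(vs)
    suppressWarnings(environmentDistance(meta, vs)))
  envD$spatial <- tryCatch(spatialDistance(meta), error = function(e) NULL)
  subgroups <- c(lapply(stats::setNames(.COLLAPSED_CLASSES, .COLLAPSED_CLASSES),
                        function(g) names(which(subgroupLabels(abund) == g))),
                 lapply(stats::setNames(.NICHE_CLASSES, .NICHE_CLASSES),
                        function(g) names(which(subgroupLabels(niche) == g))))
  out <- list()
  for (gname in names(subgroups)) {
    ids <- intersect(subgroups[[gname]], colnames(counts))
    sub <- counts[, ids, drop = FALSE]
    keep <- rowSums(sub) > 0
    if (sum(keep) < nrow(sub)) next  # subgroup absent from some sample: skip tests
    d <- brayCurtis(sub)
    item <- list(subgroup = gname, n_otus = length(ids))
    if ("nmds" %in% cfg$tests)
      item$nmds <- nmdsOrdination(d, seed = childSeed(cfg$seed,
        paste("nmds", layer, gname)))
    if ("anosim" %in% cfg$tests)
      item$anosim <- anosimTest(d, groups, nPerm = cfg$testPerm,
        seed = childSeed(cfg$seed, paste("anosim", layer, gname)))
    if ("mantel" %in% cfg$tests)
      item$mantel <- lapply(stats::setNames(names(envD), names(envD)),
        function(f) if (is.null(envD[[f]])) NULL else
          mantelTest(d, envD[[f]], nPerm = cfg$testPerm,
                     seed = childSeed(cfg$seed, paste("mantel", layer, gname, f))))
    if ("rda" %in% cfg$tests) {
      xs <- list(
        soil_vars = as.data.frame(meta)[, intersect(.SOIL_VARS, colnames(meta))],
        plant_diversity = as.data.frame(meta)[
          , grep("^plant_", colnames(meta), value = TRUE)])
      item$rda <- lapply(xs, function(x) {
        if (!ncol(x) || anyNA(x)) return(NULL)
        x <- x[, apply(x, 2, stats::sd) > 0, drop = FALSE]
        list(fit = suppressWarnings(rdaAnalysis(sub, x)),
             model = suppressWarnings(rdaPermutationTest(sub, x,
               nPerm = cfg$testPerm,
               seed = childSeed(cfg$seed, paste("rda", layer, gname)))),
             variables = fitVariables(
               suppressWarnings(rdaAnalysis(sub, x))@siteScores, x,
               nPerm = cfg$testPerm,
               seed = childSeed(cfg$seed, paste("envfit", layer, gname))))
      })
    }
    out[[gname]] <- item
  }
  out
}

.writeBundle <- function(res, cfg) {
  dir.create(cfg$outDir, recursive = TRUE, showWarnings = FALSE)
  pars <- list(seed = cfg$seed, hi = cfg$hi, lo = cfg$lo,
               nichePerm = cfg$nichePerm, nicheMethod = cfg$nicheMethod,
               testPerm = cfg$testPerm)
  writeOtuTable(res$experiment, file.path(cfg$outDir, "otu_table.tsv"), pars)
  utils::write.table(as.data.frame(sampleData(res$experiment))[
    , setdiff(colnames(sampleData(res$experiment)),
              c("tree_importance", "shrub_importance"))],
    file.path(cfg$outDir, "metadata.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(res$truth))
    .writeTsvWithHeader(as.data.frame(res$truth),
                        file.path(cfg$outDir, "truth.tsv"), pars)
  for (layer in cfg$layers) {
    lr <- res[[layer]]
    wr <- function(df, name)
      .writeTsvWithHeader(df, file.path(cfg$outDir,
                                        paste0(name, "_", layer, ".tsv")), pars)
    wr(as.data.frame(classificationTable(lr$abundance)), "abundance_classes")
    wr(as.data.frame(classificationTable(lr$niche)), "niche_classes")
    wr(rbind(cbind(gradient = "abundance", lr$summary_abundance),
             cbind(gradient = "niche", lr$summary_niche)), "subgroup_summary")
    wr(rbind(cbind(gradient = "abundance", lr$alpha_abundance),
             cbind(gradient = "niche", lr$alpha_niche)), "alpha_diversity")
    if (!is.null(lr$alpha_anova)) wr(lr$alpha_anova, "alpha_anova")
    if (!is.null(lr$niche_by_stand)) wr(lr$niche_by_stand, "niche_by_stand")
    tests <- list()
    for (gname in names(lr$comparisons)) {
      it <- lr$comparisons[[gname]]
      if (!is.null(it$anosim))
        tests[[length(tests) + 1L]] <- data.frame(
          subgroup = gname, test = "anosim", factor = "stand_type",
          statistic = statistic(it$anosim), p = pValue(it$anosim))
      for (f in names(it$mantel)) if (!is.null(it$mantel[[f]]))
        tests[[length(tests) + 1L]] <- data.frame(
          subgroup = gname, test = "mantel", factor = f,
          statistic = statistic(it$mantel[[f]]), p = pValue(it$mantel[[f]]))
      for (vs in names(it$rda)) if (!is.null(it$rda[[vs]]))
        tests[[length(tests) + 1L]] <- data.frame(
          subgroup = gname, test = "rda", factor = vs,
          statistic = it$rda[[vs]]$fit@constrainedFraction,
          p = pValue(it$rda[[vs]]$model))
      if (!is.null(it$nmds))
        wr(data.frame(sample_id = rownames(ordinationScores(it$nmds)),
                      subgroup = gname, ordinationScores(it$nmds),
                      stress = it$nmds@stress),
           paste0("nmds_", gname))
    }
    if (length(tests)) wr(do.call(rbind, tests), "community_tests")
  }
  manifest <- list(package = "NicheGradients",
                   version = as.character(utils::packageVersion("NicheGradients")),
                   date = format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                   parameters = pars, layers = cfg$layers, tests = cfg$tests)
  jsonlite::write_json(manifest, file.path(cfg$outDir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(NULL)
}
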