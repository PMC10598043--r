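test_that("the generator is deterministic given the seed", {
  p <- simulationParams(nOtus = 120L, seed = 33L)
  a <- simulateCommunity(p)
  b <- simulateCommunity(p)
  expect_identical(otuCounts(a$experiment), otuCounts(b$experiment))
  expect_identical(as.data.frame(a$truth), as.data.frame(b$truth))
  expect_identical(as.data.frame(sampleData(a$experiment)),
                   as.data.frame(sampleData(b$experiment)))
  c <- simulateCommunity(simulationParams(nOtus = 120L, seed = 34L))
  expect_false(identical(otuCounts(a$experiment), otuCounts(c$experiment)))
})

test_that("the design matches the stated field layout", {
  sim <- simulateCommunity(simulationParams(nOtus = 100L, seed = 2L))
  cd <- sampleData(sim$experiment)
  expect_equal(ncol(sim$experiment), 40L)  # 20 quadrats x 2 layers
  expect_equal(as.integer(table(cd$stand_type)[c("S", "CF", "MF", "BF")]) / 2L,
               c(3L, 3L, 3L, 11L))
  depths <- colSums(otuCounts(sim$experiment, "otus_as_rows"))
  expect_true(all(depths >= 46595 & depths <= 73284))
  # coordinates shared by the two layers of a quadrat
  top <- cd[cd$soil_layer == "topsoil", ]
  sub <- cd[cd$soil_layer == "subsoil", ]
  expect_equal(top$longitude_deg[match(sub$quadrat, top$quadrat)],
               sub$longitude_deg)
})

test_that("pure specialists concentrate their reads in home stands", {
  for (seed in 1:20) {
    p <- simulationParams(nOtus = 60L, archetypeFractions = c(0, 0, 1),
                          habitatEffect = 100, seed = seed)
    sim <- simulateCommunity(p)
    counts <- otuCounts(sim$experiment, "otus_as_rows")
    stand <- as.character(sampleData(sim$experiment)$stand_type)
    homeShare <- vapply(seq_len(nrow(counts)), function(i) {
      home <- strsplit(sim$truth$home_stands[i], ",")[[1]]
      sum(counts[i, stand %in% home]) / max(1, sum(counts[i, ]))
    }, numeric(1))
    expect_gt(mean(homeShare), 0.90)
  }
})

test_that("realized abundant fraction tracks the planted fraction", {
  frac <- vapply(1:10, function(seed) {
    sim <- simulateCommunity(simulationParams(seed = seed))
    lx <- layerSubset(sim$experiment, "topsoil", dropEmpty = TRUE)
    ra <- relativeAbundance(lx)
    mean(colMeans(ra) > 0.01)
  }, numeric(1))
  expect_true(all(abs(frac - 0.03) <= 0.02))
})

test_that("infeasible planted classes error before sampling", {
  p <- simulationParams(nOtus = 150L,
                        abundanceClassFractions = c(0.9, 0.05, 0.05))
  expect_error(simulateCommunity(p), "infeasible")
})

test_that("zero covariate effect decouples soil variables from stand type", {
  p <- simulationParams(nOtus = 10L, covariateEffect = 0, seed = 1L)
  samples <- data.frame(
    sample_id = paste0("Q", 1:20), quadrat = paste0("Q", 1:20),
    stand_type = rep(c("S", "CF", "MF", "BF"), c(3, 3, 3, 11)),
    soil_layer = "topsoil")
  pvals <- vapply(1:200, function(i) {
    set.seed(i)
    cov <- simulateCovariates(p, samples, .continueStream = TRUE)
    summary(aov(cov$pH ~ samples$stand_type))[[1]][["Pr(>F)"]][1]
  }, numeric(1))
  expect_lt(abs(mean(pvals < 0.05) - 0.05), 0.04)
  expect_gt(ks.test(pvals, "punif")$p.value, 0.01)
})

test_that("a 2-SD stand pH offset is recovered by ANOVA with power > 0.8", {
  p <- simulationParams(nOtus = 10L, covariateEffect = 0, seed = 1L)
  samples <- data.frame(
    sample_id = paste0("Q", 1:20), quadrat = paste0("Q", 1:20),
    stand_type = rep(c("S", "CF", "MF", "BF"), c(3, 3, 3, 11)),
    soil_layer = "topsoil")
  # pooled topsoil pH sd is ~0.31, so a 2-SD offset is ~0.62
  hits <- vapply(1:200, function(i) {
    set.seed(1000 + i)
    cov <- simulateCovariates(p, samples, soilOffsets = list(BF = c(pH = 0.62)),
                              .continueStream = TRUE)
    summary(aov(cov$pH ~ samples$stand_type))[[1]][["Pr(>F)"]][1] < 0.05
  }, logical(1))
  expect_gt(mean(hits), 0.8)
})

test_that("plant diversity of a uniform importance vector is ln 4", {
  expect_equal(plantDiversityIndices(rep(0.25, 4))$shannon, log(4),
               tolerance = 1e-12)
  sim <- simulateCommunity(simulationParams(nOtus = 50L, seed = 3L))
  cd <- sampleData(sim$experiment)
  expect_true(all(is.finite(cd$plant_shannon)))
  expect_true(all(cd$plant_richness >= 2))
})
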