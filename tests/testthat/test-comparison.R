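test_that("Bray-Curtis hand values and bounds", {
  m <- rbind(s1 = c(1, 0), s2 = c(0, 1))
  expect_equal(as.numeric(brayCurtis(m, relative = FALSE)), 1)
  m2 <- rbind(s1 = c(2, 2), s2 = c(2, 2))
  expect_equal(as.numeric(brayCurtis(m2, relative = FALSE)), 0)
  m3 <- rbind(s1 = c(2, 2), s2 = c(1, 3))
  expect_equal(as.numeric(brayCurtis(m3, relative = FALSE)), 0.25)
  set.seed(6)
  d <- brayCurtis(randomCounts(8, 25))
  dm <- as.matrix(d)
  expect_true(all(dm >= 0 & dm <= 1))
  expect_equal(dm, t(dm))
  expect_true(all(diag(dm) == 0))
})

test_that("3-D spatial distance follows the stated projection", {
  meta <- data.frame(longitude_deg = c(117.4, 117.4),
                     latitude_deg = c(36.43, 36.43),
                     elevation_m = c(500, 600),
                     row.names = c("a", "b"))
  expect_equal(as.numeric(spatialDistance(meta)), 100)       # elevation only
  meta2 <- meta
  meta2$elevation_m <- 500
  meta2$longitude_deg <- c(117.40, 117.41)
  expect_equal(as.numeric(spatialDistance(meta2)),
               111320 * cos(36.43 * pi / 180) * 0.01, tolerance = 1e-9)
  expect_equal(as.numeric(spatialDistance(meta2)), 895.7, tolerance = 1e-3)
  meta3 <- meta; meta3$latitude_deg[2] <- NA
  expect_error(spatialDistance(meta3), "missing coordinate.*b")
})

test_that("environment distance standardizes and falls back gracefully", {
  meta <- data.frame(dry_matter = c(0, 1, 2), available_P = c(5, 5, 5),
                     organic_C = c(1, 1, 1), NH4_N = 1, NO3_N = 1, NO2_N = 1,
                     pH = 5, row.names = paste0("s", 1:3))
  d <- suppressWarnings(environmentDistance(meta, "soil_vars"))
  v <- as.numeric(d)  # distances for values (0,1,2): proportional to (1,2,1)
  expect_equal(v / min(v), c(1, 2, 1), tolerance = 1e-9)
  # affine rescaling of a raw variable leaves z-distances unchanged
  meta2 <- meta; meta2$dry_matter <- meta2$dry_matter * 100 + 7
  expect_equal(as.numeric(suppressWarnings(environmentDistance(meta2, "soil_vars"))),
               v, tolerance = 1e-9)
  expect_warning(res <- environmentDistance(meta, "tree_importance"), "absent")
  expect_null(res)
})

test_that("NMDS recovers exact configurations and ranks", {
  sq <- dist(matrix(c(0, 0, 1, 0, 1, 1, 0, 1), 4, 2, byrow = TRUE))
  fit <- nmdsOrdination(sq, k = 2, nStarts = 10, seed = 1)
  expect_lt(fit@stress, 1e-3)
  expect_equal(colMeans(ordinationScores(fit)), c(NMDS1 = 0, NMDS2 = 0),
               tolerance = 1e-9)
  tri <- dist(rbind(c(0, 0), c(1, 0), c(0.5, sqrt(3) / 2)))
  expect_lt(nmdsOrdination(tri, k = 2, nStarts = 10, seed = 1)@stress, 1e-3)

  # generator-default community: embedded distances track the input ranks
  sim <- simulateCommunity(simulationParams(seed = 31L))
  d <- brayCurtis(layerSubset(sim$experiment, "topsoil", dropEmpty = TRUE))
  f2 <- nmdsOrdination(d, k = 2, nStarts = 10, seed = 2)
  emb <- dist(ordinationScores(f2))
  expect_gt(cor(as.numeric(d), as.numeric(emb), method = "spearman"), 0.9)
  # more dimensions cannot fit worse
  set.seed(44)
  dr <- brayCurtis(randomCounts(10, 40))
  expect_lte(nmdsOrdination(dr, k = 9, nStarts = 10, seed = 2)@stress,
             nmdsOrdination(dr, k = 2, nStarts = 10, seed = 2)@stress + 1e-8)
})

test_that("ANOSIM statistic, exact enumeration, and vegan cross-check", {
  # maximal separation: R = 1
  m <- as.matrix(dist(c(0, 0.05, 10, 10.2)))
  rownames(m) <- colnames(m) <- paste0("s", 1:4)
  g <- c("a", "a", "b", "b")
  res <- anosimTest(m, g, exact = TRUE)
  expect_equal(statistic(res), 1, tolerance = 1e-12)
  expect_equal(pValue(res), oracleAnosimExactP(m), tolerance = 1e-12)

  set.seed(17)
  for (i in 1:20) {
    mm <- as.matrix(dist(rnorm(4)))
    ex <- anosimTest(mm, g, exact = TRUE)
    expect_equal(statistic(ex), oracleAnosimR(mm, g), tolerance = 1e-9)
    expect_equal(pValue(ex), oracleAnosimExactP(mm), tolerance = 1e-9)
  }

  # exact p is the large-n_perm limit of the sampled p
  mm <- as.matrix(dist(c(0, 2, 9, 12)))
  ex <- anosimTest(mm, g, exact = TRUE)
  smp <- anosimTest(mm, g, nPerm = 9999, seed = 5)
  expect_lt(abs(pValue(smp) - pValue(ex)), 0.03)

  # statistic agrees with the independent community-ecology implementation
  set.seed(23)
  counts <- randomCounts(12, 30)
  grp <- rep(c("x", "y", "z"), each = 4)
  d <- brayCurtis(counts)
  mine <- anosimTest(d, grp, nPerm = 99, seed = 1)
  veg <- vegan::anosim(d, grp, permutations = 99)
  expect_equal(statistic(mine), unname(veg$statistic), tolerance = 1e-9)
  expect_true(abs(statistic(mine)) <= 1)

  expect_error(anosimTest(d, c(rep("x", 11), "y")), "singleton")
})

test_that("Mantel statistic, errors, invariances, and vegan cross-check", {
  set.seed(41)
  pts <- matrix(rnorm(24), 12)
  d1 <- dist(pts)
  expect_equal(statistic(mantelTest(d1, d1, nPerm = 9)), 1, tolerance = 1e-12)
  dConst <- as.dist(matrix(1, 12, 12) - diag(12))
  expect_error(mantelTest(d1, dConst, nPerm = 9), "degenerate")

  d2 <- dist(matrix(rnorm(24), 12))
  r12 <- statistic(mantelTest(d1, d2, nPerm = 9))
  # joint reordering of both matrices leaves r unchanged
  ix <- sample(12)
  m1 <- as.matrix(d1)[ix, ix]; m2 <- as.matrix(d2)[ix, ix]
  expect_equal(statistic(mantelTest(m1, m2, nPerm = 9)), r12, tolerance = 1e-12)
  veg <- vegan::mantel(d1, d2, permutations = 99)
  expect_equal(r12, unname(veg$statistic), tolerance = 1e-9)
  # spearman option
  rs <- statistic(mantelTest(d1, d2, nPerm = 9, method = "spearman"))
  vegS <- vegan::mantel(d1, d2, method = "spearman", permutations = 0)
  expect_equal(rs, unname(vegS$statistic), tolerance = 1e-9)

  m3 <- as.matrix(d2); rownames(m3) <- colnames(m3) <- letters[1:12]
  m1n <- as.matrix(d1); rownames(m1n) <- colnames(m1n) <- LETTERS[1:12]
  expect_error(mantelTest(m1n, m3, nPerm = 9), "mismatched")
})
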