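test_that("Levins breadth closed forms and invariants", {
  expect_equal(levinsBreadth(c(0.25, 0.25, 0.25, 0.25)), 4, tolerance = 1e-12)
  expect_equal(levinsBreadth(c(1, 0, 0, 0)), 1, tolerance = 1e-12)
  expect_equal(levinsBreadth(c(0.5, 0.5, 0, 0)), 2, tolerance = 1e-12)
  expect_error(levinsBreadth(c(0, 0)), "all-zero")
  set.seed(3)
  for (i in 1:20) {
    x <- rpois(sample(2:12, 1), 5) + c(1, rep(0, 0))
    if (sum(x) == 0) x[1] <- 1
    b <- levinsBreadth(x)
    expect_equal(b, oracleLevins(x), tolerance = 1e-12)
    expect_gte(b, 1 - 1e-12)
    expect_lte(b, length(x) + 1e-12)
    expect_equal(levinsBreadth(sample(x)), b, tolerance = 1e-12)  # order invariance
  }
  # B = r iff exactly uniform
  expect_equal(levinsBreadth(rep(7, 5)), 5, tolerance = 1e-12)
  expect_lt(levinsBreadth(c(7, 7, 7, 7, 8)), 5)
})

test_that("replacement-multinomial null matches its seed-policy oracle", {
  set.seed(20)
  m <- randomCounts(20, 15, depth = 2000)
  x <- t(m)  # OTUs x states
  nullB <- nullBreadthDistribution(x, "OTU3", nPerm = 1000, seed = 99L)
  # independent oracle: same documented stream
  set.seed(99L)
  draws <- rmultinom(1000, sum(x["OTU3", ]), colSums(x))
  oracle <- apply(draws, 2, oracleLevins)
  expect_equal(nullB, oracle, tolerance = 1e-12)
  expect_equal(quantile(nullB, c(.05, .95), type = 7),
               quantile(oracle, c(.05, .95), type = 7), tolerance = 1e-12)
})

test_that("degenerate and limiting null distributions", {
  x <- matrix(0L, 2, 6, dimnames = list(c("a", "b"), paste0("s", 1:6)))
  x["a", 3] <- 1L; x["b", ] <- 50L
  expect_equal(unique(nullBreadthDistribution(x, "a", nPerm = 200, seed = 1)), 1)
  # huge total over equal depths: null B concentrates at r
  y <- matrix(1000L, 2, 10); rownames(y) <- c("big", "pad")
  y["big", ] <- 100000L
  nb <- nullBreadthDistribution(y, "big", nPerm = 100, seed = 2)
  expect_true(all(abs(nb - 10) < 0.01))
})

test_that("niche classification rules and ties", {
  expect_equal(classifyNiche(5, c(1, 2, 3)), "generalized")
  expect_equal(classifyNiche(0.5, c(1, 2, 3)), "specialized")
  expect_equal(classifyNiche(2, rep(2, 100)), "neutral")  # tie -> neutral
  expect_error(classifyNiche(2, numeric(0)), "empty null")
})

test_that("classifyNicheTable agrees with a brute-force reimplementation on small tables", {
  set.seed(40)
  for (rep in 1:5) {
    m <- matrix(rpois(25, 30) + 1L, 5, 5,
                dimnames = list(paste0("o", 1:5), paste0("s", 1:5)))
    res <- classifyNicheTable(m, nPerm = 200, seed = 7L)
    tab <- classificationTable(res)
    depths <- colSums(m)
    for (i in rownames(m)) {
      bObs <- oracleLevins(m[i, ])
      set.seed(childSeed(7L, i))
      draws <- rmultinom(200, sum(m[i, ]), depths)
      bNull <- apply(draws, 2, oracleLevins)
      q <- quantile(bNull, c(.05, .95), type = 7, names = FALSE)
      want <- if (bObs > q[2]) "generalized"
              else if (bObs < q[1]) "specialized" else "neutral"
      expect_equal(tab[i, "B_obs"], bObs, tolerance = 1e-12)
      expect_equal(tab[i, "null_q05"], q[1], tolerance = 1e-12)
      expect_equal(tab[i, "niche_class"], want)
    }
  }
})

test_that("a perfectly uniform high-count OTU is generalized under equal depths", {
  m <- matrix(50L, 30, 10,
              dimnames = list(paste0("o", 1:30), paste0("s", 1:10)))
  m[1, ] <- 5000L  # uniform, high count
  set.seed(8); m[2:30, ] <- matrix(rpois(29 * 10, 50), 29, 10)
  res <- classifyNicheTable(m, nPerm = 500, seed = 3L)
  expect_equal(classificationTable(res)["o1", "niche_class"], "generalized")
  expect_equal(classificationTable(res)["o1", "B_obs"], 10, tolerance = 1e-12)
})

test_that("aggregation to stand types conserves reads and the classes partition", {
  sim <- simulateCommunity(simulationParams(nOtus = 150L, seed = 4L))
  lx <- layerSubset(sim$experiment, "topsoil", dropEmpty = TRUE)
  agg <- aggregateStates(lx, "stand_type")
  expect_equal(sum(otuCounts(agg)), sum(otuCounts(lx)))
  expect_equal(ncol(agg), 4L)
  expect_equal(unname(rowSums(otuCounts(agg, "otus_as_rows"))),
               unname(rowSums(otuCounts(lx, "otus_as_rows"))))
  idAgg <- aggregateStates(lx, "sample")
  expect_identical(otuCounts(idAgg), otuCounts(lx))

  res <- classifyNicheTable(lx, nPerm = 50, seed = 2L)
  tab <- classificationTable(res)
  expect_equal(nrow(tab) + res@nExcluded, nrow(lx))
  expect_true(all(table(tab$niche_class) >= 0))
  expect_true(all(tab$B_obs >= 1 - 1e-9 & tab$B_obs <= res@nStates + 1e-9))
})

test_that("quasiswap null is available and deterministic given seed", {
  # sparse table with checkerboard units, as the swap algorithm requires
  m <- rbind(o1 = c(3L, 0L, 2L, 1L, 4L), o2 = c(0L, 5L, 1L, 3L, 0L),
             o3 = c(2L, 1L, 0L, 4L, 1L), o4 = c(1L, 2L, 3L, 0L, 2L),
             o5 = c(0L, 3L, 2L, 2L, 1L), o6 = c(4L, 0L, 1L, 2L, 3L))
  colnames(m) <- paste0("s", 1:5)
  a <- nullBreadthDistribution(m, "o2", nPerm = 20, method = "quasiswap", seed = 5)
  b <- nullBreadthDistribution(m, "o2", nPerm = 20, method = "quasiswap", seed = 5)
  expect_identical(a, b)
  expect_true(all(a >= 1 & a <= 5))
  expect_error(nullBreadthDistribution(m, "o2", method = "nope"), "arg")
})
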