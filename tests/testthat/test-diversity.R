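test_that("diversity index closed forms", {
  expect_equal(shannonIndex(c(1, 1, 1, 1)), log(4), tolerance = 1e-12)
  expect_equal(shannonIndex(5), 0, tolerance = 1e-12)
  expect_equal(shannonIndex(c(2, 1, 1)), 1.039721, tolerance = 1e-6)
  expect_equal(simpsonIndex(c(7)), 0, tolerance = 1e-12)         # monoculture
  expect_equal(simpsonIndex(c(2, 1, 1)), 1 - 2 / 12, tolerance = 1e-12)
  expect_equal(simpsonIndex(rep(1, 9)), 1, tolerance = 1e-12)    # all singletons
  expect_error(simpsonIndex(c(1)), "N >= 2")
  expect_error(simpsonIndex(c(0.5, 0.5)), "integer")
  expect_equal(simpsonIndex(c(0.5, 0.5), unbiased = FALSE), 0.5)
})

test_that("evenness suite: uniform cases and hand values", {
  ev <- evennessIndices(c(3, 3, 3, 3))
  expect_equal(unname(ev["pielou_evenness"]), 1, tolerance = 1e-12)
  expect_equal(unname(ev["shannon_evenness"]), 1, tolerance = 1e-12)
  ev2 <- evennessIndices(c(2, 1, 1))
  expect_equal(unname(ev2["pielou_evenness"]), 0.946395, tolerance = 1e-6)
  # natural logs make Shannon evenness and Pielou coincide
  expect_equal(unname(ev2["shannon_evenness"]), unname(ev2["pielou_evenness"]))
  # base-10 switch keeps Pielou in [0,1] and identical (ratio of logs)
  ev10 <- evennessIndices(c(2, 1, 1), logBase = 10)
  expect_equal(unname(ev10["pielou_evenness"]),
               unname(ev2["pielou_evenness"]), tolerance = 1e-12)
  expect_true(is.na(evennessIndices(c(5, 0))["pielou_evenness"]))
})

test_that("shannon is bounded by log richness, uniform importance gives ln 4", {
  set.seed(2)
  for (i in 1:20) {
    v <- rpois(8, 4) + 1
    expect_lte(shannonIndex(v), log(sum(v > 0)) + 1e-12)
  }
  expect_equal(plantDiversityIndices(c(.25, .25, .25, .25))$shannon, log(4),
               tolerance = 1e-12)
})

test_that("subgroup alpha table: identity, single-OTU subgroup, read conservation", {
  set.seed(9)
  m <- randomCounts(4, 30)
  ra <- relativeAbundance(m)
  cl <- classifyAbundance(ra)
  tab <- subgroupAlphaTable(m, cl)
  # reads decompose: sum over subgroups equals sample depth
  agg <- tapply(tab$reads, tab$sample_id, sum)
  expect_equal(agg[rownames(m)], rowSums(m)[rownames(m)],
               ignore_attr = TRUE)
  # a single subgroup containing all OTUs reproduces whole-sample indices
  one <- new("AbundanceClassification",
             results = S4Vectors::DataFrame(
               otu_id = colnames(m), min_ra = 0, max_ra = 1,
               category = "CAT", collapsed = "abundant",
               row.names = colnames(m)),
             thresholds = c(hi = .01, lo = 1e-4), nExcluded = 0L,
             sampleIds = rownames(m))
  t1 <- subgroupAlphaTable(m, one)
  t1 <- t1[t1$subgroup == "abundant", ]
  expect_equal(t1$shannon, apply(m, 1, shannonIndex), ignore_attr = TRUE)
  expect_equal(t1$richness, unname(rowSums(m > 0)))
  # single present OTU: shannon 0, richness 1
  m2 <- cbind(m[, 1, drop = FALSE], solo = c(5L, 0L, 0L, 0L))
  lone <- new("AbundanceClassification",
              results = S4Vectors::DataFrame(
                otu_id = "solo", min_ra = 0, max_ra = 1,
                category = "CRT", collapsed = "rare", row.names = "solo"),
              thresholds = c(hi = .01, lo = 1e-4), nExcluded = 0L,
              sampleIds = rownames(m2))
  t2 <- subgroupAlphaTable(m2, lone)
  s1 <- t2[t2$sample_id == "S1" & t2$subgroup == "rare", ]
  expect_equal(s1$shannon, 0)
  expect_equal(s1$richness, 1L)
  s2 <- t2[t2$sample_id == "S2" & t2$subgroup == "rare", ]
  expect_equal(s2$richness, 0L)       # absent subgroup reported, with NA metrics
  expect_true(is.na(s2$shannon))
})

test_that("one-way ANOVA F matches the textbook oracle; letters behave", {
  set.seed(11)
  for (i in 1:20) {
    k <- sample(2:5, 1)
    n <- sample(3:8, 1)
    values <- rnorm(k * n, mean = rep(runif(k, 0, 3), each = n))
    groups <- rep(letters[1:k], each = n)
    av <- onewayAnovaLetters(values, groups)
    expect_equal(av$F, oracleAnovaF(values, groups), tolerance = 1e-9)
  }
  # identical values: F reported 0, single shared letter
  av0 <- onewayAnovaLetters(rep(2, 8), rep(c("a", "b"), 4))
  expect_equal(av0$F, 0)
  expect_true(all(av0$groups$letters == "a"))
  # forced separation: distinct letters
  av1 <- onewayAnovaLetters(c(rnorm(5, 0, .1), rnorm(5, 10, .1)),
                            rep(c("lo", "hi"), each = 5))
  expect_false(av1$groups$letters[1] == av1$groups$letters[2])
  # singleton group excluded with warning
  expect_warning(onewayAnovaLetters(c(1, 2, 3, 4, 9), c("a", "a", "b", "b", "c")),
                 "excluding")
})
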