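test_that("forced abundance categories match the threshold rules", {
  ra <- rbind(S1 = c(a = 0.020, b = 0.00005, c = 0.00005, d = 0.979900),
              S2 = c(a = 0.015, b = 0.00005, c = 0.02000, d = 0.964950),
              S3 = c(a = 0.030, b = 0.00005, c = 0.00500, d = 0.964950))
  cl <- classifyAbundance(ra)
  cats <- setNames(classificationTable(cl)$category,
                   classificationTable(cl)$otu_id)
  expect_equal(cats[["a"]], "AAT")    # > 1% in all samples
  expect_equal(cats[["b"]], "ART")    # < 0.01% in all samples
  expect_equal(cats[["c"]], "CRAT")   # below lo somewhere, above hi elsewhere
  expect_equal(cats[["d"]], "AAT")
  expect_equal(setNames(subgroupLabels(cl)[c("a", "b", "c")], NULL),
               c("abundant", "rare", "medium"))
})

test_that("threshold equality falls to the middle rules", {
  ra <- rbind(S1 = c(x = 0.01, y = 0.0001, z = 0.9899),
              S2 = c(x = 0.01, y = 0.0001, z = 0.9899))
  cats <- setNames(classificationTable(classifyAbundance(ra))$category,
                   c("x", "y", "z"))
  expect_equal(cats[["x"]], "MT")  # exactly at hi: not "greater than"
  expect_equal(cats[["y"]], "MT")  # exactly at lo: not "less than"
})

test_that("classification matches the brute-force rule oracle on random tables", {
  set.seed(101)
  for (rep in 1:20) {
    m <- randomCounts(sample(4:10, 1), sample(20:60, 1))
    ra <- relativeAbundance(m)
    cl <- classifyAbundance(ra)
    got <- setNames(classificationTable(cl)$category,
                    classificationTable(cl)$otu_id)
    want <- oracleAbundance(ra)
    expect_identical(got[names(want)], want)
    # partition: every classified OTU in exactly one category
    expect_equal(length(got) + cl@nExcluded, ncol(ra))
  }
})

test_that("raising hi only moves OTUs out of AAT/CAT, and classification is depth-scale invariant", {
  set.seed(7)
  m <- randomCounts(8, 40)
  ra <- relativeAbundance(m)
  lowHi <- classificationTable(classifyAbundance(ra, hi = 0.005))
  highHi <- classificationTable(classifyAbundance(ra, hi = 0.02))
  inA <- function(tab) tab$otu_id[tab$category %in% c("AAT", "CAT")]
  expect_true(all(inA(highHi) %in% inA(lowHi)))

  m2 <- m; m2[1, ] <- m2[1, ] * 13L
  expect_identical(classificationTable(classifyAbundance(relativeAbundance(m2))),
                   classificationTable(classifyAbundance(ra)))
})

test_that("subgroup summary fractions behave and sum to 1", {
  # one OTU holds 99% of reads, 99 OTUs share 1%
  m <- matrix(c(99000L, rep(10L, 99)), 1,
              dimnames = list("S1", paste0("o", 1:100)))
  m <- rbind(S1 = m[1, ], S2 = m[1, ])
  cl <- classifyAbundance(relativeAbundance(m))
  s <- subgroupSummary(m, cl)
  expect_equal(s$otu_fraction[s$subgroup == "abundant"], 0.01)
  expect_gte(s$read_fraction[s$subgroup == "abundant"], 0.99)
  expect_equal(sum(s$otu_fraction), 1, tolerance = 1e-12)
  expect_equal(sum(s$read_fraction), 1, tolerance = 1e-12)
  # empty category reported as 0, not omitted
  s6 <- subgroupSummary(m, cl, level = "category")
  expect_setequal(s6$subgroup, c("AAT", "ART", "MT", "CAT", "CRT", "CRAT"))
  expect_true(any(s6$n_otus == 0))
})

test_that("planted abundance-class fractions are recovered on simulated data", {
  for (seed in 1:3) {
    sim <- simulateCommunity(simulationParams(seed = seed))
    lx <- layerSubset(sim$experiment, "topsoil", dropEmpty = TRUE)
    cl <- classifyAbundance(relativeAbundance(lx))
    s <- subgroupSummary(lx, cl)
    expect_lt(abs(s$otu_fraction[s$subgroup == "abundant"] - 0.03), 0.02)
    expect_lt(abs(s$otu_fraction[s$subgroup == "rare"] - 0.90), 0.02)
  }
})
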