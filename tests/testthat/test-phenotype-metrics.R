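test_that("relative abundances normalize and handle extinction", {
  expect_equal(relativeAbundances(c(1, 1, 1, 1)), rep(0.25, 4))
  expect_equal(relativeAbundances(c(2, 0)), c(1, 0))
  expect_equal(relativeAbundances(c(0, 0, 0)), c(0, 0, 0))
  expect_error(relativeAbundances(c(1, -1)), "non-negative")
  set.seed(3)
  for (i in 1:200) {
    p <- relativeAbundances(runif(sample(2:10, 1), 0, 5))
    expect_equal(sum(p), 1, tolerance = 1e-12)
  }
})

test_that("Shannon entropy has its closed-form values and extremes", {
  expect_equal(shannonEntropy(rep(0.25, 4)), 2)
  expect_equal(shannonEntropy(c(1, 0, 0)), 0)
  expect_equal(shannonEntropy(c(0.5, 0.25, 0.25)), 1.5)
  set.seed(4)
  for (i in 1:50) {
    p <- relativeAbundances(runif(6))
    expect_equal(shannonEntropy(p), shannonEntropy(sample(p)))  # permutation
    expect_lte(shannonEntropy(p), log2(6) + 1e-12)              # uniform max
  }
  expect_equal(shannonEntropy(rep(1 / 6, 6)), log2(6))
})

test_that("species richness counts presences above the threshold", {
  expect_equal(speciesRichness(c(0.5, 0.5, 0), 0), 2)
  expect_equal(speciesRichness(rep(1 / 13, 13), 0), 13)
  expect_equal(speciesRichness(c(0.99, 0.009, 0.001), 0.005), 2)
  expect_error(speciesRichness(c(1), -0.1), ">= 0")
})

test_that("exchange counting collapses duplicates and respects the cap", {
  rec <- data.frame(donor = c("A", "A"), receiver = c("B", "B"),
                    metabolite = c("m", "m"), amount_mmol = c(0.1, 0.2))
  expect_equal(countExchanges(rec), 1L)
  expect_equal(countExchanges(rec[0, ]), 0L)
  bidir <- data.frame(donor = c("A", "B"), receiver = c("B", "A"),
                      metabolite = "m", amount_mmol = 0.1)
  expect_equal(countExchanges(bidir), 2L)
  expect_equal(countExchanges(bidir, directed = FALSE), 1L)

  expect_equal(maxPossibleExchanges(13, 737), 57486)
  expect_equal(maxPossibleExchanges(2, 1), 1)
  expect_equal(maxPossibleExchanges(3, 10), 30)
  expect_equal(maxPossibleExchanges(1, 10), 0)
})

test_that("directed flux and secretion totals sum correctly", {
  rec <- data.frame(donor = c("A", "C"), receiver = c("B", "B"),
                    metabolite = c("m", "k"), amount_mmol = c(0.1, 0.2))
  expect_equal(fluxToOrganism(rec, "B"), 0.3)
  expect_equal(fluxToOrganism(rec, "A", organisms = c("A", "B", "C")), 0)
  expect_error(fluxToOrganism(rec, "Z"), "unknown organism")
  # partition: summed incoming flux equals total exchanged amount
  orgs <- c("A", "B", "C")
  expect_equal(sum(vapply(orgs, function(o)
    fluxToOrganism(rec, o, orgs), numeric(1))), sum(rec$amount_mmol))

  tot <- c(m = 0.35, k = 0)
  expect_equal(secretionTotal(tot, "m"), 0.35)
  expect_equal(secretionTotal(tot, "k"), 0)
  expect_error(secretionTotal(tot, "q"), "unknown")
})

test_that("PhenotypeSummary assembles consistent metrics", {
  rec <- data.frame(donor = "A", receiver = "B", metabolite = "m",
                    amount_mmol = 0.1)
  s <- PhenotypeSummary(c(A = 3, B = 1), exchanges = rec,
                        secretionTotals = c(m = 0.2))
  expect_equal(abundances(s), c(A = 0.75, B = 0.25))
  expect_equal(s@richness, 2L)
  expect_equal(s@entropy, shannonEntropy(c(0.75, 0.25)))
  expect_equal(s@nExchanges, 1L)
  expect_equal(s@fluxTo, c(A = 0, B = 0.1))
  expect_identical(exchangeRecords(s), rec)
})
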