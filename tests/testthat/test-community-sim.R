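test_that("inoculum arithmetic reproduces the OD-calibrated amounts", {
  ia <- inoculumAmounts(1.6e7, 2.8e-13, 13)
  expect_equal(ia$total, 4.48e-6)
  expect_equal(signif(ia$per_organism, 3), 3.45e-7)
  expect_equal(inoculumAmounts(1e6, 1e-13, 1)$per_organism, 1e-7)
  expect_error(inoculumAmounts(1e6, 1e-13, 0), "n_organisms")
})

test_that("death-only dynamics follow the exponential closed form", {
  pool <- NutrientPool("glc", carbon_atoms = 6)
  org <- OrganismSpec("solo",
                      uptake = data.frame(substrate = "glc", vmax = 10, km = 1),
                      yield = c(glc = 0.1))
  com <- CommunityModel(list(org), byproducts = c(m = 2), pool = pool)
  cfg <- SimulationConfig(duration = 24, timestep = 0.01, deathRate = 0.1,
                          inoculumPerOrganism = 1e-6)
  res <- simulateCommunity(com, setNames(numeric(0), character(0)), cfg)
  expect_equal(unname(finalBiomass(res)), 1e-6 * exp(-0.1 * 24),
               tolerance = 5e-3)

  # with no death and nothing to eat the state is exactly constant
  cfg0 <- SimulationConfig(deathRate = 0, inoculumPerOrganism = 1e-6)
  res0 <- simulateCommunity(com, setNames(numeric(0), character(0)), cfg0)
  expect_true(all(res0@biomassTraj == 1e-6))
})

test_that("growth respects the yield mass-balance bound", {
  pool <- NutrientPool("glc", carbon_atoms = 6)
  yield <- 6 / 40                       # all carbon to biomass, no secretion
  org <- OrganismSpec("solo",
                      uptake = data.frame(substrate = "glc", vmax = 10, km = 1e-6),
                      yield = c(glc = yield))
  com <- CommunityModel(list(org), byproducts = setNames(numeric(0), character(0)),
                        pool = pool)
  medium <- c(glc = 3e-3)
  cfg <- SimulationConfig(duration = 48, timestep = 0.01, deathRate = 0,
                          inoculumPerOrganism = 1e-6)
  final <- unname(finalBiomass(simulateCommunity(com, medium, cfg)))
  bound <- 1e-6 + yield * medium[["glc"]]
  expect_lte(final, bound + 1e-12)
  # with tiny Km and long duration the bound is nearly attained
  expect_equal(final, bound, tolerance = 0.01)
})

test_that("cross-feeding produces the expected exchange and auxotrophy gate", {
  com <- crossFeedPair()
  medium <- c(glc = 2e-3)
  cfg <- SimulationConfig(duration = 24, timestep = 0.01, deathRate = 0,
                          inoculumPerOrganism = 1e-6)
  res <- simulateCommunity(com, medium, cfg)
  rec <- res@exchanges
  expect_equal(nrow(rec), 1L)
  expect_identical(rec$donor, "A")
  expect_identical(rec$receiver, "B")
  expect_identical(rec$metabolite, "m")
  expect_gt(rec$amount_mmol, 0)
  expect_gt(finalBiomass(res)[["B"]], 1e-6)   # B grew on A's byproduct

  # without the donor, B never grows (nothing it can eat)
  onlyB <- CommunityModel(com@organisms[2], byproducts = com@byproducts,
                          pool = com@pool)
  resB <- simulateCommunity(onlyB, medium, cfg)
  expect_equal(unname(finalBiomass(resB)), 1e-6)
  expect_false(everGrew(resB@biomassTraj[1, ]))

  # the cofactor gate alone blocks growth the same way
  gated <- crossFeedPair(bRequiresCofactor = TRUE)
  onlyBGated <- CommunityModel(gated@organisms[2], byproducts = gated@byproducts,
                               pool = gated@pool)
  resG <- simulateCommunity(onlyBGated, medium, cfg)
  expect_equal(unname(finalBiomass(resG)), 1e-6)
})

test_that("carbon is conserved and states stay non-negative across seeds", {
  for (seed in 1:100) {
    s <- randomSmallSetup(seed)
    res <- simulateCommunity(s$community, s$medium, s$config)
    expect_equal(finalCarbon(res), initialCarbon(s), tolerance = 1e-6)
    expect_true(all(res@biomassTraj >= 0))
    expect_true(all(res@metaboliteTraj >= 0))
  }
})

test_that("halving the timestep barely changes the outcome", {
  fx <- getFixture()
  med <- buildMedium(c("glucose", "citrate"), fx$mediumSpec, fx$pool)
  coarse <- finalBiomass(simulateCommunity(fx$community, med, fx$simConfig))
  cfgFine <- SimulationConfig(duration = 24, timestep = 0.005, deathRate = 0.1,
                              inoculumPerOrganism = fx$simConfig@inoculumPerOrganism)
  fine <- finalBiomass(simulateCommunity(fx$community, med, cfgFine))
  expect_equal(sum(coarse), sum(fine), tolerance = 0.01)
  expect_equal(coarse / sum(coarse), fine / sum(fine), tolerance = 0.01)
})

test_that("simulation is deterministic", {
  s <- randomSmallSetup(5)
  r1 <- simulateCommunity(s$community, s$medium, s$config)
  r2 <- simulateCommunity(s$community, s$medium, s$config)
  expect_identical(r1@biomassTraj, r2@biomassTraj)
  expect_identical(r1@exchanges, r2@exchanges)
})

test_that("the growth-cessation rule applies both clauses", {
  rise_plateau <- c(1, 2, 3, 3, 3)
  expect_true(growthStopped(rise_plateau))
  still_rising <- c(1, 2, 3, 4, 5)
  expect_false(growthStopped(still_rising))
  never_grew <- 5 * exp(-0.1 * 0:10)
  expect_false(growthStopped(never_grew))   # first clause unmet
  expect_false(everGrew(never_grew))
  expect_error(growthStopped(1), "2 points")
})

test_that("random communities are reproducible and respect archetypes", {
  pool <- fixturePool()
  set.seed(99); a <- generateRandomCommunity(13, pool)
  set.seed(99); b <- generateRandomCommunity(13, pool)
  expect_equal(a, b)

  ids <- organismIds(a)
  for (prefix in c("sp", "ge", "au", "cr"))
    expect_true(any(startsWith(ids, prefix)))

  # every auxotroph's cofactor is secretable by another organism
  for (o in a@organisms) {
    for (cof in o@requiredCofactors) {
      donors <- vapply(a@organisms, function(d)
        d@id != o@id && cof %in% d@secretion$product, logical(1))
      expect_true(any(donors))
    }
  }

  set.seed(1)
  spOnly <- generateRandomCommunity(5, pool,
                                    archetype_mix = c(specialist = 1))
  for (o in spOnly@organisms)
    expect_true(all(o@uptake$substrate %in% nutrientIds(pool)))
})

test_that("exhaustive mappings have canonical shape and are deterministic", {
  pool <- NutrientPool(c("a", "b"), carbon_atoms = c(3, 4))
  set.seed(2)
  com <- generateRandomCommunity(3, pool)
  space <- EnvironmentSpace(pool, 2)
  cfg <- SimulationConfig(duration = 2, timestep = 0.02,
                          inoculumPerOrganism = 1e-6)
  mp <- generateMapping(com, space, MediumSpec(), cfg)
  expect_equal(ncol(mp), 4L)
  expect_identical(colnames(mp)[1], "empty")
  mp2 <- generateMapping(com, space, MediumSpec(), cfg)
  expect_identical(SummarizedExperiment::assay(mp, "biomass"),
                   SummarizedExperiment::assay(mp2, "biomass"))
})

test_that("the packaged fixture reproduces the dataset structure", {
  fx <- getFixture()
  mp <- getMapping()
  expect_equal(ncol(mp), 176L)
  ab <- SummarizedExperiment::assay(mp, "abundance")
  # at least one environment with a dominant (>50%) organism
  expect_true(any(apply(ab, 2, max) > 0.5))
  # every organism fails to grow in at least one environment
  bm <- SummarizedExperiment::assay(mp, "biomass")
  inoc <- fx$simConfig@inoculumPerOrganism
  expect_true(all(rowSums(bm <= inoc + 1e-15) >= 1))
  # exchange networks are dense and variable
  cd <- as.data.frame(SummarizedExperiment::colData(mp))
  expect_gt(max(cd$n_exchanges), 20)
  expect_gt(sd(cd$n_exchanges), 2)
})
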