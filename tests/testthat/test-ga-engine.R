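smallSpace <- function(n = 10, N = 3) {
  EnvironmentSpace(NutrientPool(sprintf("n%02d", seq_len(n)),
                                carbon_atoms = rep(3, n)),
                   maxNutrients = N, includeEmpty = FALSE)
}

test_that("population initialization is admissible and reproducible", {
  space <- smallSpace(20, 4)
  set.seed(10)
  pop <- initializePopulation(space, 10)
  expect_length(pop, 10L)
  set.seed(10)
  expect_identical(initializePopulation(space, 10), pop)
  set.seed(20)
  sizes <- lengths(unlist(replicate(100, initializePopulation(space, 10),
                                    simplify = FALSE), recursive = FALSE))
  expect_true(all(sizes >= 1 & sizes <= 4))
  expect_length(initializePopulation(space, 1), 1L)
})

test_that("parent selection keeps the ranked order", {
  pop <- list("a", "b", "c")
  expect_identical(selectParents(pop, 2), list("a", "b"))
  expect_identical(selectParents(pop, 3), pop)
  expect_error(selectParents(pop, 4), "sigma")
})

test_that("crossover offspring come from the parent nutrient pool", {
  space <- smallSpace()
  parents <- list(c("n01", "n02"), c("n03", "n04"))
  set.seed(5)
  for (i in 1:50) {
    off <- makeOffspring(parents, P = 10, sigma = 2, pC = 1, space)
    expect_length(off, 8L)
    expect_true(all(unlist(off) %in% c("n01", "n02", "n03", "n04")))
    expect_true(all(lengths(off) >= 1 & lengths(off) <= 3))
  }
  # identical singleton parents force identical offspring
  off <- makeOffspring(list("n05", "n05"), P = 5, sigma = 2, pC = 1, space)
  expect_true(all(vapply(off, identical, logical(1), "n05")))
  # pC = 0 falls back to fresh random draws over the full pool
  set.seed(6)
  off0 <- makeOffspring(parents, P = 10, sigma = 2, pC = 0, space)
  expect_true(all(unlist(off0) %in% nutrientIds(space@pool)))
})

test_that("mutation spares the top-ranked environment and avoids duplicates", {
  space <- smallSpace()
  set.seed(12)
  for (i in 1:100) {
    pop <- initializePopulation(space, 6)
    mutated <- mutatePopulation(pop, pM = 1, space)
    expect_identical(mutated[[1L]], pop[[1L]])
    for (j in 2:6) {
      expect_length(mutated[[j]], length(pop[[j]]))
      expect_false(anyDuplicated(mutated[[j]]) > 0)
      expect_true(all(mutated[[j]] %in% nutrientIds(space@pool)))
      # pM = 1 touches every slot; at least one nutrient is new to the set
      # (an early replacement may vacate a slot a later one refills)
      expect_gte(length(setdiff(mutated[[j]], pop[[j]])), 1L)
    }
  }
  pop <- initializePopulation(space, 4)
  expect_identical(mutatePopulation(pop, pM = 0, space), pop)
})

test_that("the convergence detector fires only on genuinely stalled runs", {
  P <- 10
  # identical fitness for 11 generations: all three criteria hold
  stalled <- matrix(5, nrow = 11, ncol = P)
  res <- checkConvergence(stalled, ConvergenceCriteria())
  expect_true(res$converged)
  expect_true(all(res$flags))

  # strictly improving: criterion 3 must fail
  set.seed(30)
  improving <- t(sapply(1:12, function(g) rnorm(P, mean = 2 * g, sd = 0.01)))
  res2 <- checkConvergence(improving, ConvergenceCriteria())
  expect_false(res2$converged)
  expect_false(res2$flags[["no_improvement"]])

  # best stalled but spread above 10% of the mean: criterion 1 fails
  spread <- matrix(rep(c(10, rep(5, P - 1)), 11), nrow = 11, byrow = TRUE)
  res3 <- checkConvergence(spread, ConvergenceCriteria())
  expect_false(res3$flags[["internal_consistency"]])
  expect_false(res3$converged)

  # zero/negative fitness is handled through shifting, not division blowup
  zeros <- matrix(0, nrow = 11, ncol = P)
  expect_true(checkConvergence(zeros, ConvergenceCriteria())$converged)
})

test_that("GA runs are reproducible and obey elitism and closure", {
  space <- gaSearchSpace()
  ev <- lookupEvaluator(getMapping())
  obj <- Objective("entropy")
  cfg <- GAConfig(G = 15, seed = 123)
  h1 <- runGA(space, ev, obj, cfg)
  h2 <- runGA(space, ev, obj, cfg)
  expect_identical(h1@generations, h2@generations)
  expect_identical(fitnessTrace(h1), fitnessTrace(h2))

  for (seed in 1:20) {
    h <- runGA(space, ev, obj, GAConfig(G = 10, seed = seed), criteria = NULL)
    expect_true(all(diff(fitnessTrace(h)) >= 0))          # elitism
    envs <- strsplit(do.call(rbind, h@generations)$nutrients, ";")
    expect_true(all(lengths(envs) >= 1 & lengths(envs) <= 3))   # closure
    expect_true(all(unlist(envs) %in% nutrientIds(space@pool)))
    expect_lte(uniqueEvaluations(h), 10 * nGenerations(h))
  }
})

test_that("sigma = P with pM = 0 freezes the population after ranking", {
  space <- gaSearchSpace()
  ev <- lookupEvaluator(getMapping())
  h <- runGA(space, ev, Objective("entropy"),
             GAConfig(P = 6, sigma = 6, pM = 0, G = 8, seed = 4),
             criteria = NULL)
  first <- h@generations[[2L]]$env_id
  for (g in 3:nGenerations(h))
    expect_identical(h@generations[[g]]$env_id, first)
})

test_that("evaluator failures demote the environment instead of aborting", {
  space <- gaSearchSpace()
  base <- lookupEvaluator(getMapping())
  poisoned <- function(env) {
    if ("glucose" %in% env) stop("boom")
    base(env)
  }
  h <- runGA(space, poisoned, Objective("entropy"),
             GAConfig(G = 10, seed = 2), criteria = NULL)
  expect_equal(nGenerations(h), 10L)
  log <- do.call(rbind, h@generations)
  bad <- grepl("glucose", log$nutrients)
  expect_true(any(bad))
  expect_true(all(log$fitness[bad] == -Inf))
  expect_false("glucose" %in% bestEnvironment(h))
})

test_that("the random baseline shares bookkeeping and reproducibility", {
  space <- gaSearchSpace()
  ev <- lookupEvaluator(getMapping())
  obj <- Objective("entropy")
  cfg <- GAConfig(G = 12, seed = 77)
  r1 <- runRandomSearch(space, ev, obj, cfg, criteria = NULL)
  r2 <- runRandomSearch(space, ev, obj, cfg, criteria = NULL)
  expect_identical(r1@generations, r2@generations)
  expect_true(all(diff(fitnessTrace(r1)) >= 0))

  # at G = 1 both methods are just the seeded random initialization
  g1 <- runGA(space, ev, obj, GAConfig(G = 1, seed = 55), criteria = NULL)
  rnd1 <- runRandomSearch(space, ev, obj, GAConfig(G = 1, seed = 55),
                          criteria = NULL)
  expect_identical(g1@generations[[1L]], rnd1@generations[[1L]])
})

test_that("lookup evaluators reject environments outside the table", {
  ev <- lookupEvaluator(getMapping())
  expect_error(ev(c("glucose", "fructose", "xylose", "ribose")),
               "not in lookup table")
  s <- ev(c("glucose", "citrate"))
  expect_s4_class(s, "PhenotypeSummary")
})

test_that("GA configuration validity enforces the documented bounds", {
  expect_error(GAConfig(pM = 0.5), "pM")
  expect_error(GAConfig(sigma = 11, P = 10), "sigma")
  expect_error(GAConfig(G = 0), "G")
  expect_silent(validObject(GAConfig(sigma = 10, P = 10)))
})
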