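# A minimal GAHistory with a prescribed best-so-far trace, for metric tests.
traceHistory <- function(trace) {
  P <- 3L
  new("GAHistory",
      generations = lapply(seq_along(trace), function(g)
        data.frame(generation = g, env_id = "x", nutrients = "x",
                   raw = trace[g], fitness = trace[g])),
      fitnessMatrix = matrix(rep(trace, each = P), ncol = P, byrow = TRUE),
      bestTrace = cummax(trace), bestEnv = "x",
      bestFitness = max(trace), bestRaw = max(trace),
      uniqueEvaluations = length(trace), converged = FALSE,
      criterionFlags = matrix(NA, length(trace), 3),
      stopReason = "max_generations", config = GAConfig(), method = "ga")
}

test_that("percentile thresholds use linear interpolation", {
  expect_equal(percentileThreshold(1:100, 99), 99.01)
  expect_equal(percentileThreshold(rep(7, 50), 42), 7)
  expect_equal(percentileThreshold(1:100, 100), 100)
  expect_error(percentileThreshold(1:10, 101), "\\[0, 100\\]")
  expect_error(percentileThreshold(numeric(0), 50), "empty")
})

test_that("percentile ranks put the enumerated maximum at 100", {
  ref <- c(1, 2, 3, 4, 5)
  expect_equal(percentileRank(ref, 5), 100)
  expect_equal(percentileRank(ref, 3), 60)
  expect_equal(percentileRank(ref, 0), 0)
  expect_equal(percentileRank(c(1, 2, 2, 3), 2, ties = "midrank"), 50)
})

test_that("run metrics find the first strict crossing of the threshold", {
  ref <- as.numeric(1:100)
  immediate <- computeMetrics(traceHistory(c(100, 100, 100)), ref)
  expect_equal(immediate$G99, 1)
  expect_equal(immediate$Prend, 100)

  late <- computeMetrics(traceHistory(c(50, 80, 99.5, 99.5)), ref)
  expect_equal(late$G99, 3)

  never <- computeMetrics(traceHistory(c(10, 20, 30)), ref)
  expect_false(never$crossed)
  expect_identical(never$G99, Inf)
  expect_lt(never$Prend, 99)
})

test_that("the performance score spans exactly [0, 2]", {
  expect_equal(computeS(0, 1), 2)
  expect_equal(computeS(1, 0), 0)
  expect_equal(computeS(0.5, 0.5), 1)
  expect_error(computeS(-0.1, 0.5), "\\[0, 1\\]")
  expect_error(computeS(0.5, 1.1), "\\[0, 1\\]")
  # monotone: decreasing in G99~, increasing in Prend~
  g <- seq(0, 1, 0.25)
  expect_true(all(diff(computeS(g, 0.5)) < 0))
  expect_true(all(diff(computeS(0.5, g)) > 0))
})

test_that("aggregation reports mean, s.e.m. and never-crossed counts", {
  runs <- data.frame(G99 = c(2, 4), Prend = c(90, 100), S = c(1, 1.5))
  a <- aggregateRuns(runs)
  expect_equal(a$mean[["G99"]], 3)
  expect_equal(a$sem[["G99"]], 1)
  expect_equal(a$mean[["Prend"]], 95)
  expect_equal(a$n_never_crossed, 0)

  same <- data.frame(G99 = c(3, 3, 3), Prend = c(99, 99, 99), S = c(2, 2, 2))
  expect_equal(unname(aggregateRuns(same)$sem), c(0, 0, 0))

  lost <- data.frame(G99 = c(Inf, Inf), Prend = c(10, 20))
  a3 <- aggregateRuns(lost)
  expect_true(is.na(a3$mean[["G99"]]))
  expect_equal(a3$n_never_crossed, 2)
})

test_that("best-pair averaging reproduces the shipped operating point logic", {
  pairs <- data.frame(pC = c(0.7, 1, 1), pM = c(0.25, 0.45, 0.4))
  avg <- averageBestPairs(pairs)
  expect_equal(avg[["pC"]], 0.9)
  expect_equal(avg[["pM"]], 1.1 / 3, tolerance = 1e-12)
})

test_that("a reduced grid search runs and is seed-reproducible", {
  space <- gaSearchSpace()
  ev <- lookupEvaluator(getMapping())
  obj <- Objective("entropy")
  ref <- searchReference(obj)
  g1 <- gridSearch(space, ev, list(obj), list(ref),
                   pC_grid = c(0.5, 0.9), pM_grid = c(0.1, 0.35),
                   n_seeds = 3, config = GAConfig(G = 10, seed = 1))
  expect_equal(nrow(g1@table), 4L)
  expect_true(all(g1@table$mean_S >= 0 & g1@table$mean_S <= 2))
  expect_true(g1@bestPairs$pC %in% c(0.5, 0.9))
  g2 <- gridSearch(space, ev, list(obj), list(ref),
                   pC_grid = c(0.5, 0.9), pM_grid = c(0.1, 0.35),
                   n_seeds = 3, config = GAConfig(G = 10, seed = 1))
  expect_identical(g1@table, g2@table)
  # a 1x1 grid trivially selects its only cell
  g3 <- gridSearch(space, ev, list(obj), list(ref), pC_grid = 0.9,
                   pM_grid = 0.35, n_seeds = 2, config = GAConfig(G = 5))
  expect_equal(g3@bestPairs$pC, 0.9)
  expect_equal(g3@bestPairs$pM, 0.35)
})

test_that("reference distributions cover the space with one value per env", {
  mp <- getMapping()
  ref <- referenceDistribution(mp, Objective("entropy"))
  expect_length(ref, ncol(mp))
  cd <- as.data.frame(SummarizedExperiment::colData(mp))
  expect_equal(unname(ref), cd$entropy)
})
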