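#' @include env-space.R objectives.R mapping.R
NULL

#' GA configuration
#'
#' Search parameters of the elitist genetic algorithm. Defaults are the
#' shipped operating point: an experimentally tractable population of P = 10
#' environments, sigma = 2 parents, crossover probability 0.9 and per-nutrient
#' mutation probability 0.35. Mutation probabilities are kept below 0.5 so
#' excessive mutation cannot drive the search away from optima.
#'
#' @slot P population size.
#' @slot sigma number of top-ranked parent environments carried over.
#' @slot N maximum nutrients per environment (taken from the space when
#'   running).
#' @slot pC per-offspring crossover probability.
#' @slot pM per-nutrient mutation probability (< 0.5).
#' @slot G maximum number of generations.
#' @slot seed RNG seed for the run.
#' @name GAConfig-class
#' @exportClass GAConfig
setClass("GAConfig", representation(
  P = "integer", sigma = "integer", N = "integer", pC = "numeric",
  pM = "numeric", G = "integer", seed = "integer"))

setValidity("GAConfig", function(object) {
  if (object@P < 1) return("P must be >= 1")
  if (object@sigma < 1 || object@sigma > object@P)
    return("sigma must satisfy 1 <= sigma <= P")
  if (object@pC < 0 || object@pC > 1) return("pC must lie in [0,1]")
  if (object@pM < 0 || object@pM >= 0.5) return("pM must lie in [0, 0.5)")
  if (object@G < 1) return("G must be >= 1")
  TRUE
})

#' @rdname GAConfig-class
#' @param P,sigma,N,pC,pM,G,seed see slots.
#' @export
GAConfig <- function(P = 10, sigma = 2, N = 4, pC = 0.9, pM = 0.35,
                     G = 50, seed = 1) {
  new("GAConfig", P = as.integer(P), sigma = as.integer(sigma),
      N = as.integer(N), pC = pC, pM = pM, G = as.integer(G),
      seed = as.integer(seed))
}

setMethod("show", "GAConfig", function(object) {
  cat(sprintf("GAConfig: P=%d sigma=%d pC=%g pM=%g G=%d seed=%d\n",
              object@P, object@sigma, object@pC, object@pM, object@G,
              object@seed))
})

#' Convergence criteria
#'
#' Three conditions, all of which must hold for the search to be declared
#' converged: (1) populations are internally consistent — the gap between the
#' best and the average fitness of the current generation is below `relGap`
#' of the average; (2) solutions have reached a maximum — the scaled
#' difference between the current generation's best and the best ever found
#' is below `bestTol`; (3) no further improvement — for each of the last
#' `stallGenerations` generations, a one-tailed two-sample (Welch) t-test
#' finds no significant fitness increase over its predecessor at level
#' `alpha`. Fitness scores that touch zero or go negative (e.g. negated SSE
#' at its optimum) are shifted by `|min| + 1` before the ratio criteria are
#' evaluated.
#'
#' @slot relGap fraction for criterion 1 (default 0.10).
#' @slot bestTol scaled difference for criterion 2 (default 0.01).
#' @slot stallGenerations window for criterion 3 (default 10).
#' @slot alpha significance level of the t-test (default 0.05).
#' @name ConvergenceCriteria-class
#' @exportClass ConvergenceCriteria
setClass("ConvergenceCriteria", representation(
  relGap = "numeric", bestTol = "numeric", stallGenerations = "integer",
  alpha = "numeric"))

setValidity("ConvergenceCriteria", function(object) {
  if (object@relGap <= 0 || object@bestTol <= 0 ||
      object@stallGenerations < 1 || object@alpha <= 0 || object@alpha >= 1)
    return("all criteria parameters must be positive (alpha in (0,1))")
  TRUE
})

#' @rdname ConvergenceCriteria-class
#' @param relGap,bestTol,stallGenerations,alpha see slots.
#' @export
ConvergenceCriteria <- function(relGap = 0.10, bestTol = 0.01,
                                stallGenerations = 10, alpha = 0.05) {
  new("ConvergenceCriteria", relGap = relGap, bestTol = bestTol,
      stallGenerations = as.integer(stallGenerations), alpha = alpha)
}

#' GA run histories
#'
#' Everything recorded over one search run: the ranked population of every
#' generation with raw objective values and fitness, the best-so-far trace,
#' the number of unique environment evaluations (repeat proposals are served
#' from a memo, supporting "unique in silico experiments" accounting),
#' per-generation convergence flags and the terminating condition.
#'
#' @slot generations list of per-generation `data.frame`s (ranked best
#'   first) with columns generation, env_id, nutrients, raw, fitness.
#' @slot fitnessMatrix generations x P matrix of fitness values (ranked
#'   within each row).
#' @slot bestTrace best-ever fitness after each generation (non-decreasing
#'   under a deterministic evaluator).
#' @slot bestEnv,bestFitness,bestRaw the best environment found.
#' @slot uniqueEvaluations number of distinct environments evaluated.
#' @slot converged,criterionFlags,stopReason convergence bookkeeping;
#'   `criterionFlags` is a generations x 3 logical matrix.
#' @slot config the [GAConfig-class] used; `method` is `"ga"` or `"random"`.
#' @slot method search method label.
#' @name GAHistory-class
#' @exportClass GAHistory
setClass("GAHistory", representation(
  generations = "list", fitnessMatrix = "matrix", bestTrace = "numeric",
  bestEnv = "character", bestFitness = "numeric", bestRaw = "numeric",
  uniqueEvaluations = "integer", converged = "logical",
  criterionFlags = "matrix", stopReason = "character", config = "GAConfig",
  method = "character"))

setMethod("show", "GAHistory", function(object) {
  cat(sprintf(
    "GAHistory (%s): %d generations, best fitness %.4g in env {%s}, %d unique evaluations, %s\n",
    object@method, length(object@generations), object@bestFitness,
    paste(object@bestEnv, collapse = ", "), object@uniqueEvaluations,
    object@stopReason))
})

#' @describeIn GAHistory Number of generations actually run.
#' @param history a [GAHistory-class].
#' @export
nGenerations <- function(history) length(history@generations)

#' @describeIn GAHistory Best environment found (character vector of ids).
#' @export
bestEnvironment <- function(history) history@bestEnv

#' @describeIn GAHistory Best-ever fitness trace, one entry per generation.
#' @export
fitnessTrace <- function(history) history@bestTrace

#' @describeIn GAHistory Count of unique environments evaluated.
#' @export
uniqueEvaluations <- function(history) history@uniqueEvaluations

#' Initialize a random population
#'
#' P admissible, non-empty environments with sizes uniform on 1..N
#' (duplicates permitted).
#'
#' @param space an [EnvironmentSpace-class].
#' @param P population size.
#' @return list of environments.
#' @export
initializePopulation <- function(space, P) {
  lapply(seq_len(P), function(i) randomEnvironment(space))
}

#' Select the top parents of a ranked population
#'
#' @param population list of environments ranked best-first.
#' @param sigma number of parents.
#' @return the first `sigma` environments, order preserved.
#' @export
selectParents <- function(population, sigma) {
  if (sigma > length(population)) stop("sigma exceeds population size")
  population[seq_len(sigma)]
}

#' Generate offspring by pooled-nutrient crossover
#'
#' Each of the P - sigma offspring is, with probability `pC`, a random
#' assortment drawn without replacement from the linearized multiset of the
#' parents' nutrients (so nutrients shared by several parents are
#' proportionally more likely to be inherited), deduplicated per offspring;
#' the assortment size is uniform on 1..N, capped at the number of parental
#' slots. Otherwise the offspring is a fresh random environment from the
#' whole pool, which keeps exploration alive at low `pC`.
#'
#' @param parents list of parent environments.
#' @param P,sigma population size and parent count.
#' @param pC per-offspring crossover probability.
#' @param space the [EnvironmentSpace-class].
#' @return list of `P - sigma` environments.
#' @export
makeOffspring <- function(parents, P, sigma, pC, space) {
  if (length(parents) == 0L) stop("no parents supplied")
  parentVector <- unlist(parents)            # linearized, duplicates kept
  nDistinct <- length(unique(parentVector))
  N <- space@maxNutrients
  lapply(seq_len(P - sigma), function(i) {
    if (runif(1) < pC) {
      k <- min(sample.int(N, 1L), nDistinct)
      # draw parental slots without replacement until k distinct nutrients
      shuffled <- parentVector[sample.int(length(parentVector))]
      sort(unique(shuffled)[seq_len(k)])
    } else {
      randomEnvironment(space)
    }
  })
}

#' Mutate a ranked population (top-1 protected)
#'
#' Every nutrient slot of every environment except the top-ranked one is,
#' independently with probability `pM`, replaced by a uniformly drawn
#' nutrient not currently present in that environment. If the environment
#' already contains the whole pool the slot is left unchanged. Environment
#' sizes are preserved, so admissibility is too.
#'
#' @param population list of environments ranked best-first.
#' @param pM per-nutrient mutation probability.
#' @param space the [EnvironmentSpace-class].
#' @return the mutated population.
#' @export
mutatePopulation <- function(population, pM, space) {
  if (pM == 0 || length(population) <= 1L) return(population)
  ids <- nutrientIds(space@pool)
  out <- population
  for (j in seq_along(out)[-1L]) {
    env <- out[[j]]
    for (k in seq_along(env)) {
      if (runif(1) < pM) {
        cand <- setdiff(ids, env)
        if (length(cand)) env[k] <- cand[sample.int(length(cand), 1L)]
      }
    }
    out[[j]] <- sort(env)
  }
  out
}

# One-tailed Welch test that `curr` improved over `prev`; returns TRUE when
# the increase is significant at `alpha`. Degenerate (constant) samples fall
# back to a deterministic mean comparison.
significantIncrease <- function(curr, prev, alpha) {
  curr <- curr[is.finite(curr)]; prev <- prev[is.finite(prev)]
  if (!length(curr) || !length(prev)) return(FALSE)
  if (sd(curr) < 1e-14 && sd(prev) < 1e-14)
    return(mean(curr) > mean(prev) + 1e-12)
  p <- tryCatch(
    t.test(curr, prev, alternative = "greater")$p.value,
    error = function(e) if (mean(curr) > mean(prev)) 0 else 1)
  is.finite(p) && p < alpha
}

#' Test the three convergence criteria
#'
#' @param fitness a generations x P matrix of fitness values (or a
#'   [GAHistory-class], whose fitness matrix is used), oldest generation
#'   first; convergence is assessed at the last row.
#' @param criteria a [ConvergenceCriteria-class].
#' @return list with `converged` (all three hold) and `flags`, a named
#'   logical vector for the individual criteria.
#' @export
checkConvergence <- function(fitness, criteria = ConvergenceCriteria()) {
  if (is(fitness, "GAHistory")) fitness <- fitness@fitnessMatrix
  g <- nrow(fitness)
  cur <- fitness[g, ]
  shift <- function(x) if (min(x) <= 0) x + abs(min(x)) + 1 else x

  sCur <- shift(cur)
  crit1 <- (max(sCur) - mean(sCur)) / mean(sCur) < criteria@relGap

  bests <- apply(fitness, 1, max)
  sBests <- shift(bests)
  bestEver <- max(sBests)
  crit2 <- abs(bestEver - sBests[g]) / abs(bestEver) < criteria@bestTol

  w <- criteria@stallGenerations
  crit3 <- FALSE
  if (g >= w + 1L) {
    crit3 <- TRUE
    for (gen in seq.int(g - w + 1L, g)) {
      if (significantIncrease(fitness[gen, ], fitness[gen - 1L, ],
                              criteria@alpha)) {
        crit3 <- FALSE
        break
      }
    }
  }
  flags <- c(internal_consistency = crit1, at_maximum = crit2,
             no_improvement = crit3)
  list(converged = all(flags), flags = flags)
}

#' Evaluators
#'
#' An evaluator is a function mapping an environment (character vector of
#' nutrient ids) to a [PhenotypeSummary-class]. `lookupEvaluator` serves
#' phenotypes from a precomputed exhaustive mapping (errors on environments
#' outside it); `simulatorEvaluator` runs the consumer-resource simulator on
#' demand, the mode used for spaces too large to enumerate.
#'
#' @param mapping a mapping `SummarizedExperiment`.
#' @return a function `f(env) -> PhenotypeSummary`.
#' @export
lookupEvaluator <- function(mapping) {
  summaries <- mappingSummaries(mapping)
  function(env) {
    key <- environmentId(env)
    s <- summaries[[key]]
    if (is.null(s)) stop(sprintf("environment '%s' not in lookup table", key))
    s
  }
}

#' @rdname lookupEvaluator
#' @param community a [CommunityModel-class].
#' @param mediumSpec a [MediumSpec-class].
#' @param config a [SimulationConfig-class].
#' @param presenceThreshold see [speciesRichness()].
#' @export
simulatorEvaluator <- function(community, mediumSpec = MediumSpec(),
                               config = SimulationConfig(),
                               presenceThreshold = 0) {
  function(env) {
    medium <- buildMedium(env, mediumSpec, community@pool)
    summarizePhenotype(simulateCommunity(community, medium, config),
                       presenceThreshold)
  }
}

# Shared engine behind runGA and runRandomSearch. `propagate` builds the next
# population from the current ranked one.
runSearch <- function(space, evaluator, objective, config, criteria,
                      method, propagate) {
  set.seed(config@seed)
  memo <- new.env(hash = TRUE, parent = emptyenv())
  nUnique <- 0L
  evalEnv <- function(env) {
    key <- environmentId(env)
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    sc <- tryCatch(scoreSummary(objective, evaluator(env)),
                   error = function(e) c(raw = NA_real_, fitness = -Inf))
    nUnique <<- nUnique + 1L
    memo[[key]] <- sc
    sc
  }

  pop <- initializePopulation(space, config@P)
  proposed <- new.env(hash = TRUE, parent = emptyenv()) # random baseline pool
  generations <- list()
  fitnessMatrix <- matrix(NA_real_, 0, config@P)
  bestTrace <- numeric(0)
  flagRows <- list()
  bestFitness <- -Inf; bestRaw <- NA_real_; bestEnv <- character(0)
  stopReason <- "max_generations"; converged <- FALSE

  for (gen in seq_len(config@G)) {
    scores <- vapply(pop, evalEnv, numeric(2))
    keys <- vapply(pop, function(e) canonicalKey(e, space@pool), character(1))
    ord <- order(-scores["fitness", ], keys)
    pop <- pop[ord]
    fit <- scores["fitness", ord]
    raw <- scores["raw", ord]
    for (e in pop) proposed[[environmentId(e)]] <- e

    if (fit[1L] > bestFitness) {
      bestFitness <- fit[1L]; bestRaw <- raw[1L]; bestEnv <- pop[[1L]]
    }
    generations[[gen]] <- data.frame(
      generation = gen,
      env_id = vapply(pop, environmentId, character(1)),
      nutrients = vapply(pop, paste, character(1), collapse = ";"),
      raw = raw, fitness = fit, stringsAsFactors = FALSE)
    fitnessMatrix <- rbind(fitnessMatrix, fit)
    bestTrace <- c(bestTrace, bestFitness)

    flags <- c(internal_consistency = NA, at_maximum = NA,
               no_improvement = NA)
    if (!is.null(criteria)) {
      conv <- checkConvergence(fitnessMatrix, criteria)
      flags <- conv$flags
      if (conv$converged) {
        flagRows[[gen]] <- flags
        converged <- TRUE
        stopReason <- "converged"
        break
      }
    }
    flagRows[[gen]] <- flags
    if (gen == config@G) break
    pop <- propagate(pop, proposed)
  }

  rownames(fitnessMatrix) <- NULL
  criterionFlags <- do.call(rbind, flagRows)
  new("GAHistory", generations = generations, fitnessMatrix = fitnessMatrix,
      bestTrace = bestTrace, bestEnv = bestEnv, bestFitness = bestFitness,
      bestRaw = bestRaw, uniqueEvaluations = nUnique, converged = converged,
      criterionFlags = criterionFlags, stopReason = stopReason,
      config = config, method = method)
}

#' Run the genetic algorithm
#'
#' The elitist loop: rank the evaluated population, carry the top `sigma`
#' environments over as parents, fill the remaining P - sigma slots by
#' pooled-nutrient crossover (probability `pC` each, otherwise a fresh random
#' environment), then mutate every environment except the top-ranked one with
#' per-nutrient probability `pM`. The loop stops when all three convergence
#' criteria hold or after `G` generations. Already-proposed environments are
#' served from a memo, so `uniqueEvaluations(history)` counts distinct
#' experiments. Runs are reproducible: the same seed and a deterministic
#' evaluator give identical histories.
#'
#' @param space an [EnvironmentSpace-class].
#' @param evaluator an evaluator function, see [lookupEvaluator()].
#' @param objective an [Objective-class].
#' @param config a [GAConfig-class].
#' @param criteria a [ConvergenceCriteria-class], or `NULL` to always run the
#'   full `G` generations.
#' @return a [GAHistory-class].
#' @export
runGA <- function(space, evaluator, objective, config = GAConfig(),
                  criteria = ConvergenceCriteria()) {
  runSearch(space, evaluator, objective, config, criteria, "ga",
            propagate = function(rankedPop, proposed) {
              parents <- selectParents(rankedPop, config@sigma)
              offspring <- makeOffspring(parents, config@P, config@sigma,
                                         config@pC, space)
              mutatePopulation(c(parents, offspring), config@pM, space)
            })
}

#' Run the random-search baseline
#'
#' Identical bookkeeping to [runGA()], but with selection pressure and
#' recombination removed: each new generation keeps `sigma` environments
#' drawn uniformly (with replacement) from everything proposed so far and
#' fills the remaining P - sigma slots with fresh random environments. Used
#' as the seed-matched control when benchmarking the GA.
#'
#' @inheritParams runGA
#' @return a [GAHistory-class].
#' @export
runRandomSearch <- function(space, evaluator, objective, config = GAConfig(),
                            criteria = ConvergenceCriteria()) {
  runSearch(space, evaluator, objective, config, criteria, "random",
            propagate = function(rankedPop, proposed) {
              seen <- as.list(proposed)
              carried <- seen[sample.int(length(seen), config@sigma,
                                         replace = TRUE)]
              fresh <- lapply(seq_len(config@P - config@sigma),
                              function(i) randomEnvironment(space))
              c(unname(carried), fresh)
            })
}
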