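#' @include ga.R
NULL

#' Reference fitness distribution of an enumerated space
#'
#' The fitness of every environment in an exhaustive mapping under one
#' objective (always-maximize convention), in the mapping's canonical order.
#' This is the known distribution against which search runs are scored:
#' its 99th percentile defines G99 and its ranks define Prend.
#'
#' @param mapping a mapping `SummarizedExperiment`.
#' @param objective an [Objective-class].
#' @return named numeric vector of fitness values (names are `env_id`s).
#' @export
referenceDistribution <- function(mapping, objective) {
  summaries <- mappingSummaries(mapping)
  vapply(summaries, function(s) scoreSummary(objective, s)[["fitness"]],
         numeric(1))
}

#' Percentile threshold of a reference distribution
#'
#' The q-th percentile by linear interpolation over the sorted reference
#' values (`stats::quantile` type 7); e.g. the 99th percentile of the values
#' 1..100 is 99.01.
#'
#' @param ref numeric reference distribution.
#' @param q percentile in `[0, 100]`.
#' @return fitness threshold.
#' @export
percentileThreshold <- function(ref, q) {
  if (length(ref) == 0L) stop("empty reference distribution")
  if (q < 0 || q > 100) stop("percentile must lie in [0, 100]")
  quantile(ref, q / 100, type = 7, names = FALSE)
}

#' Percentile rank of a value within a reference distribution
#'
#' The default `"le"` convention reports the fraction of reference values at
#' or below `v` (x100), so a run that attains the enumerated maximum sits at
#' exactly the 100th percentile. `"midrank"` (strictly-below plus half the
#' ties) is offered for tie-heavy distributions.
#'
#' @param ref numeric reference distribution.
#' @param v the value to rank.
#' @param ties `"le"` or `"midrank"`.
#' @return percentile in `[0, 100]`.
#' @export
percentileRank <- function(ref, v, ties = c("le", "midrank")) {
  ties <- match.arg(ties)
  n <- length(ref)
  if (ties == "le") 100 * sum(ref <= v) / n
  else 100 * (sum(ref < v) + 0.5 * sum(ref == v)) / n
}

#' Score one run against a reference distribution
#'
#' G99 is the first generation whose best fitness strictly exceeds the 99th
#' percentile of the reference (`Inf` if the run never crosses); Prend is the
#' percentile rank of the best-ever fitness at the final generation.
#'
#' @param history a [GAHistory-class].
#' @param ref the reference distribution (same objective as the run).
#' @param q crossing percentile (default 99).
#' @return `data.frame` with columns `G99`, `Prend`, `crossed`.
#' @export
computeMetrics <- function(history, ref, q = 99) {
  thr <- percentileThreshold(ref, q)
  trace <- fitnessTrace(history)
  hit <- which(trace > thr)
  g99 <- if (length(hit)) hit[1L] else Inf
  data.frame(G99 = g99, Prend = percentileRank(ref, trace[length(trace)]),
             crossed = is.finite(g99))
}

#' Combined performance score
#'
#' S = (1 - G99~) + Prend~, with both terms normalized to `[0, 1]`, so S
#' ranges from 0 (worst corner) to 2 (best corner: immediate crossing and
#' top final percentile).
#'
#' @param G99_norm normalized generations-to-threshold, in `[0, 1]`.
#' @param Prend_norm normalized final percentile, in `[0, 1]`.
#' @return S in `[0, 2]`.
#' @examples
#' computeS(0, 1)   # 2
#' computeS(1, 0)   # 0
#' @export
computeS <- function(G99_norm, Prend_norm) {
  if (any(G99_norm < 0 | G99_norm > 1) || any(Prend_norm < 0 | Prend_norm > 1))
    stop("normalized inputs must lie in [0, 1]")
  (1 - G99_norm) + Prend_norm
}

# Min-max normalization; a degenerate (constant) range maps to 0.
minMax <- function(x) {
  r <- range(x)
  if (r[2] - r[1] < 1e-15) return(rep(0, length(x)))
  (x - r[1]) / (r[2] - r[1])
}

#' Aggregate run metrics
#'
#' Mean and standard error of the mean (sd/sqrt(n)) per metric over a set of
#' runs. Runs that never crossed the threshold are excluded from the G99
#' mean and counted separately.
#'
#' @param metrics `data.frame` with columns `G99` and `Prend` (and optionally
#'   `S`), one row per run.
#' @return list with `mean`, `sem` (named vectors) and `n_never_crossed`.
#' @export
aggregateRuns <- function(metrics) {
  sem <- function(x) if (length(x) >= 2L) sd(x) / sqrt(length(x)) else NA_real_
  fin <- metrics$G99[is.finite(metrics$G99)]
  cols <- intersect(c("Prend", "S"), names(metrics))
  means <- c(G99 = if (length(fin)) mean(fin) else NA_real_,
             vapply(metrics[cols], mean, numeric(1)))
  sems <- c(G99 = sem(fin), vapply(metrics[cols], sem, numeric(1)))
  list(mean = means, sem = sems,
       n_never_crossed = sum(!is.finite(metrics$G99)))
}

#' Grid-search results
#'
#' @slot table per-cell summary `data.frame` with columns `pC`, `pM`,
#'   `objective`, `mean_S`, `sem_S`, `mean_G99`, `mean_Prend`,
#'   `n_never_crossed`.
#' @slot bestPairs one row per objective: the `(pC, pM)` cell with the
#'   highest mean S.
#' @slot averagedBest the across-objective average of the best pairs.
#' @name GridSearchResult-class
#' @exportClass GridSearchResult
setClass("GridSearchResult", representation(
  table = "data.frame", bestPairs = "data.frame", averagedBest = "numeric"))

setMethod("show", "GridSearchResult", function(object) {
  cat(sprintf("GridSearchResult: %d cells x %d objectives\n",
              nrow(unique(object@table[c("pC", "pM")])),
              length(unique(object@table$objective))))
  print(object@bestPairs)
  cat(sprintf("averaged best pair: pC=%g pM=%g\n",
              object@averagedBest[["pC"]], object@averagedBest[["pM"]]))
})

#' Average the per-objective best (pC, pM) pairs
#'
#' @param bestPairs `data.frame` with columns `pC` and `pM`, one row per
#'   objective.
#' @return named numeric `c(pC = , pM = )` of arithmetic means.
#' @examples
#' averageBestPairs(data.frame(pC = c(0.7, 1, 1), pM = c(0.25, 0.45, 0.4)))
#' @export
averageBestPairs <- function(bestPairs) {
  c(pC = mean(bestPairs$pC), pM = mean(bestPairs$pM))
}

#' Crossover/mutation probability grid search
#'
#' For every `(pC, pM)` cell and objective, runs the GA `n_seeds` times with
#' shared seed sets and scores each run by S. Within an objective, G99
#' (never-crossed runs mapped to the generation cap G) and Prend are min-max
#' normalized across all runs of the grid before combining into S. The full
#' grid defaults to pC in 0..1 by 0.1 and pM in 0..0.45 by 0.05.
#'
#' @param space an [EnvironmentSpace-class].
#' @param evaluator an evaluator function (see [lookupEvaluator()]).
#' @param objectives list of [Objective-class].
#' @param refs list of reference distributions, parallel to `objectives`
#'   (see [referenceDistribution()]).
#' @param pC_grid,pM_grid numeric grids.
#' @param n_seeds GA runs per cell; run i uses seed `config@seed + i - 1`.
#' @param config base [GAConfig-class]; its `pC`/`pM` are overridden per cell.
#' @param criteria convergence criteria, or `NULL` (default) to run all runs
#'   to the full `G` for comparable G99 accounting.
#' @return a [GridSearchResult-class].
#' @export
gridSearch <- function(space, evaluator, objectives, refs,
                       pC_grid = seq(0, 1, by = 0.1),
                       pM_grid = seq(0, 0.45, by = 0.05),
                       n_seeds = 50, config = GAConfig(), criteria = NULL) {
  stopifnot(length(objectives) == length(refs))
  objNames <- vapply(objectives, function(o) o@family, character(1))
  objNames <- make.unique(objNames)
  cells <- expand.grid(pC = pC_grid, pM = pM_grid, KEEP.OUT.ATTRS = FALSE)

  rows <- list()
  for (oi in seq_along(objectives)) {
    runs <- list()
    for (ci in seq_len(nrow(cells))) {
      cfg <- config
      cfg@pC <- cells$pC[ci]
      cfg@pM <- cells$pM[ci]
      for (s in seq_len(n_seeds)) {
        cfg@seed <- as.integer(config@seed + s - 1L)
        hist <- runGA(space, evaluator, objectives[[oi]], cfg, criteria)
        m <- computeMetrics(hist, refs[[oi]])
        runs[[length(runs) + 1L]] <- cbind(cell = ci, m)
      }
    }
    runs <- do.call(rbind, runs)
    g99m <- ifelse(is.finite(runs$G99), runs$G99, config@G)
    S <- computeS(minMax(g99m), minMax(runs$Prend))
    for (ci in seq_len(nrow(cells))) {
      sel <- runs$cell == ci
      rows[[length(rows) + 1L]] <- data.frame(
        pC = cells$pC[ci], pM = cells$pM[ci], objective = objNames[oi],
        mean_S = mean(S[sel]),
        sem_S = if (sum(sel) >= 2) sd(S[sel]) / sqrt(sum(sel)) else NA_real_,
        mean_G99 = if (any(sel & is.finite(runs$G99)))
          mean(runs$G99[sel & is.finite(runs$G99)]) else NA_real_,
        mean_Prend = mean(runs$Prend[sel]),
        n_never_crossed = sum(sel & !is.finite(runs$G99)),
        stringsAsFactors = FALSE)
    }
  }
  table <- do.call(rbind, rows)
  bestPairs <- do.call(rbind, lapply(unique(table$objective), function(obj) {
    sub <- table[table$objective == obj, ]
    sub <- sub[order(-sub$mean_S, sub$pC, sub$pM), ]
    sub[1L, c("objective", "pC", "pM", "mean_S")]
  }))
  rownames(bestPairs) <- NULL
  new("GridSearchResult", table = table, bestPairs = bestPairs,
      averagedBest = averageBestPairs(bestPairs))
}
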