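#' @include benchmark.R fixture.R
NULL

readConfigFile <- function(file) {
  if (grepl("\\.json$", file)) jsonlite::read_json(file, simplifyVector = TRUE)
  else yaml::read_yaml(file)
}

objectiveFromConfig <- function(cfg) {
  if (is.null(cfg$family))
    stop("objective block needs a 'family'; valid families: ",
         paste(objectiveFamilies, collapse = ", "))
  if (!cfg$family %in% objectiveFamilies)
    stop(sprintf("unknown objective family '%s'; valid families: %s",
                 cfg$family, paste(objectiveFamilies, collapse = ", ")))
  Objective(cfg$family, direction = cfg$direction, organism = cfg$organism,
            metabolite = cfg$metabolite,
            target = if (!is.null(cfg$target)) unlist(cfg$target))
}

gaConfigFromConfig <- function(cfg, seed = NULL) {
  base <- GAConfig()
  args <- list(P = cfg$P, sigma = cfg$sigma, N = cfg$N, pC = cfg$pC,
               pM = cfg$pM, G = cfg$G, seed = if (!is.null(seed)) seed
               else cfg$seed)
  defaults <- list(P = base@P, sigma = base@sigma, N = base@N, pC = base@pC,
                   pM = base@pM, G = base@G, seed = base@seed)
  for (nm in names(defaults)) if (is.null(args[[nm]])) args[[nm]] <- defaults[[nm]]
  do.call(GAConfig, args)
}

criteriaFromConfig <- function(cfg) {
  if (isFALSE(cfg)) return(NULL)
  if (is.null(cfg)) return(ConvergenceCriteria())
  ConvergenceCriteria(
    relGap = if (!is.null(cfg$rel_gap)) cfg$rel_gap else 0.10,
    bestTol = if (!is.null(cfg$best_tol)) cfg$best_tol else 0.01,
    stallGenerations = if (!is.null(cfg$stall_generations))
      cfg$stall_generations else 10,
    alpha = if (!is.null(cfg$alpha)) cfg$alpha else 0.05)
}

# Resolve the evaluator block: either a lookup mapping CSV or a community
# spec YAML run through the simulator.
evaluatorFromConfig <- function(cfg) {
  if (!is.null(cfg$mapping_csv)) {
    mapping <- readMapping(cfg$mapping_csv, cfg$exchanges_csv)
    list(evaluator = lookupEvaluator(mapping), mapping = mapping,
         inputs = c(cfg$mapping_csv, cfg$exchanges_csv))
  } else if (!is.null(cfg$community_yaml)) {
    community <- readCommunitySpec(cfg$community_yaml)
    med <- cfg$medium
    mediumSpec <- MediumSpec(
      totalCarbonMM = if (!is.null(med$total_carbon_mM)) med$total_carbon_mM else 50,
      volumeUl = if (!is.null(med$volume_ul)) med$volume_ul else 400,
      overrideMmol = if (!is.null(med$per_nutrient_mmol)) med$per_nutrient_mmol
      else NA_real_)
    sim <- cfg$simulation
    simConfig <- SimulationConfig(
      duration = if (!is.null(sim$duration)) sim$duration else 24,
      timestep = if (!is.null(sim$timestep)) sim$timestep else 0.01,
      deathRate = if (!is.null(sim$death_rate)) sim$death_rate else 0.1,
      inoculumPerOrganism = if (!is.null(sim$inoculum_gdw))
        sim$inoculum_gdw else 3.45e-7,
      volumeUl = if (!is.null(med$volume_ul)) med$volume_ul else 400)
    list(evaluator = simulatorEvaluator(community, mediumSpec, simConfig),
         community = community, pool = community@pool,
         inputs = cfg$community_yaml)
  } else {
    stop("evaluator block needs either 'mapping_csv' or 'community_yaml'")
  }
}

# Search over a lookup table needs only nutrient identities; when the mapping
# came from a CSV without an accompanying pool file, reconstruct ids from the
# nutrient strings (carbon counts are irrelevant to lookup-backed search).
poolFromMapping <- function(mapping) {
  tab <- metadata(mapping)$pool
  if (!is.null(tab)) return(NutrientPool(tab$id, tab$name, tab$carbon_atoms))
  cd <- as.data.frame(colData(mapping))
  ids <- sort(unique(unlist(strsplit(cd$nutrients, ";", fixed = TRUE))))
  NutrientPool(ids, carbon_atoms = rep(1, length(ids)))
}

spaceFromConfig <- function(cfg, pool) {
  if (!is.null(cfg$pool_csv)) pool <- readNutrientPool(cfg$pool_csv)
  if (is.null(pool)) stop("space block needs a 'pool_csv' (or a simulator evaluator)")
  EnvironmentSpace(pool,
                   maxNutrients = if (!is.null(cfg$max_nutrients))
                     cfg$max_nutrients else 4,
                   sizeRule = if (!is.null(cfg$size_rule)) cfg$size_rule
                   else "upto",
                   includeEmpty = !isFALSE(cfg$include_empty))
}

writeManifest <- function(out_dir, config, inputs, outputs, seed) {
  manifest <- list(
    package = "MediaGA",
    version = as.character(packageVersion("MediaGA")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed,
    config = config,
    input_digests = as.list(md5sum(inputs[file.exists(inputs)])),
    outputs = as.list(outputs))
  path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  path
}

#' Run a search from a configuration file
#'
#' Executes one GA (or random-search) run described by a YAML/JSON config
#' with blocks `space` (pool CSV, max nutrients, size rule), `evaluator`
#' (lookup `mapping_csv` + optional `exchanges_csv`, or `community_yaml`
#' with `medium`/`simulation` sub-blocks), `objective`, `ga` and
#' `convergence` (`false` disables early stopping), plus optional `method`
#' (`"ga"` or `"random"`). Writes a manifest (before any other output), a
#' per-generation run log CSV and a JSON summary into `out_dir`.
#'
#' @param config_file path to the config file.
#' @param out_dir output directory.
#' @param seed optional seed overriding the config's.
#' @return the [GAHistory-class], invisibly; outputs land in `out_dir`.
#' @export
runFromConfig <- function(config_file, out_dir, seed = NULL) {
  cfg <- readConfigFile(config_file)
  ev <- evaluatorFromConfig(cfg$evaluator)
  pool <- if (!is.null(ev$pool)) ev$pool else poolFromMapping(ev$mapping)
  space <- spaceFromConfig(cfg$space, pool)
  objective <- objectiveFromConfig(cfg$objective)
  gaCfg <- gaConfigFromConfig(cfg$ga, seed)
  criteria <- criteriaFromConfig(cfg$convergence)
  method <- if (!is.null(cfg$method)) cfg$method else "ga"

  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  outputs <- c(log = file.path(out_dir, "runlog.csv"),
               summary = file.path(out_dir, "summary.json"))
  writeManifest(out_dir, cfg, inputs = c(config_file, unlist(ev$inputs)),
                outputs = outputs, seed = gaCfg@seed)

  history <- if (method == "random")
    runRandomSearch(space, ev$evaluator, objective, gaCfg, criteria)
  else runGA(space, ev$evaluator, objective, gaCfg, criteria)

  log <- do.call(rbind, history@generations)
  write.csv(log, outputs[["log"]], row.names = FALSE)
  summary <- list(
    method = history@method,
    best_env_id = environmentId(bestEnvironment(history)),
    best_nutrients = bestEnvironment(history),
    best_fitness = history@bestFitness,
    best_raw = history@bestRaw,
    generations = nGenerations(history),
    unique_evaluations = uniqueEvaluations(history),
    converged = history@converged,
    stop_reason = history@stopReason)
  jsonlite::write_json(summary, outputs[["summary"]], auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(history)
}

#' Benchmark GA against the random baseline from a configuration file
#'
#' Runs both methods (or a subset) over `n_seeds` shared seed sets against a
#' lookup evaluator, scores every run (G99, Prend), and writes a per-run
#' metrics CSV plus an aggregate CSV (mean and s.e.m. per method) into
#' `out_dir`.
#'
#' @param config_file config as in [runFromConfig()], with an extra optional
#'   `benchmark` block (`n_seeds`, `methods`).
#' @param out_dir output directory.
#' @param seed optional base seed override.
#' @return invisibly, the per-run metrics `data.frame`.
#' @export
benchmarkFromConfig <- function(config_file, out_dir, seed = NULL) {
  cfg <- readConfigFile(config_file)
  ev <- evaluatorFromConfig(cfg$evaluator)
  if (is.null(ev$mapping))
    stop("benchmarking needs a lookup evaluator (enumerable space)")
  space <- spaceFromConfig(cfg$space, poolFromMapping(ev$mapping))
  objective <- objectiveFromConfig(cfg$objective)
  gaCfg <- gaConfigFromConfig(cfg$ga, seed)
  nSeeds <- if (!is.null(cfg$benchmark$n_seeds)) cfg$benchmark$n_seeds else 50
  methods <- if (!is.null(cfg$benchmark$methods)) cfg$benchmark$methods
             else c("ga", "random")
  ref <- referenceDistribution(ev$mapping, objective)

  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  outputs <- c(runs = file.path(out_dir, "benchmark_runs.csv"),
               aggregate = file.path(out_dir, "benchmark_aggregate.csv"))
  writeManifest(out_dir, cfg, inputs = c(config_file, unlist(ev$inputs)),
                outputs = outputs, seed = gaCfg@seed)

  rows <- list()
  for (method in methods) {
    runFun <- if (method == "random") runRandomSearch else runGA
    for (s in seq_len(nSeeds)) {
      cfgS <- gaCfg
      cfgS@seed <- as.integer(gaCfg@seed + s - 1L)
      hist <- runFun(space, ev$evaluator, objective, cfgS, criteria = NULL)
      m <- computeMetrics(hist, ref)
      rows[[length(rows) + 1L]] <- cbind(
        method = method, seed = cfgS@seed, m,
        unique_evaluations = uniqueEvaluations(hist))
    }
  }
  runs <- do.call(rbind, rows)
  write.csv(runs, outputs[["runs"]], row.names = FALSE)
  agg <- do.call(rbind, lapply(methods, function(method) {
    a <- aggregateRuns(runs[runs$method == method, ])
    data.frame(method = method, mean_G99 = a$mean[["G99"]],
               sem_G99 = a$sem[["G99"]], mean_Prend = a$mean[["Prend"]],
               sem_Prend = a$sem[["Prend"]],
               n_never_crossed = a$n_never_crossed,
               stringsAsFactors = FALSE)
  }))
  write.csv(agg, outputs[["aggregate"]], row.names = FALSE)
  invisible(runs)
}
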