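#' @include random-community.R mapping.R simulate.R
NULL

#' The packaged benchmark fixture
#'
#' A self-contained, fully enumerable benchmark: a 13-organism synthetic
#' community (all four archetypes represented) on a 10-nutrient pool of
#' common carbon sources, searched over environments of up to 3 nutrients
#' with the empty environment included — 176 environments in total, small
#' enough that the exhaustive environment-phenotype mapping, multi-seed
#' benchmarking and a reduced grid search all run in minutes while preserving
#' benchmarking against a known optimum. Growth conditions follow the
#' benchmark setting: equimolar carbon totalling 50 mM C in 400 ul, equal
#' inocula of 3.45e-7 gDW per organism (1.6e7 cells x 2.8e-13 gDW split 13
#' ways), 24 h at dt = 0.01 h with death rate 0.1 h^-1.
#'
#' @param seed RNG seed for the community draw.
#' @return list with elements `pool`, `community`, `space`, `mediumSpec`,
#'   `simConfig`.
#' @export
communityFixture <- function(seed = 1) {
  pool <- fixturePool()
  set.seed(seed)
  community <- generateRandomCommunity(13, pool)
  inoc <- inoculumAmounts(1.6e7, 2.8e-13, 13)
  list(pool = pool,
       community = community,
       space = EnvironmentSpace(pool, maxNutrients = 3, sizeRule = "upto",
                                includeEmpty = TRUE),
       mediumSpec = MediumSpec(totalCarbonMM = 50, volumeUl = 400),
       simConfig = SimulationConfig(duration = 24, timestep = 0.01,
                                    deathRate = 0.1,
                                    inoculumPerOrganism = inoc$per_organism))
}

# The fixture's 10-nutrient pool: sugars, a sugar alcohol and organic acids
# with their carbon counts. Ids are disjoint from the byproduct metabolites.
fixturePool <- function() {
  NutrientPool(
    id = c("glucose", "fructose", "sucrose", "maltose", "xylose",
           "glycerol", "citrate", "pyruvate", "ribose", "mannose"),
    carbon_atoms = c(6, 6, 12, 12, 5, 3, 6, 3, 5, 6))
}

#' @rdname communityFixture
#' @param fixture a fixture list from [communityFixture()].
#' @param cap enumeration guard (the fixture space holds 176 environments).
#' @return `fixtureMapping` returns the exhaustive mapping
#'   `SummarizedExperiment` (176 columns).
#' @export
fixtureMapping <- function(fixture = communityFixture(), cap = 100000) {
  generateMapping(fixture$community, fixture$space, fixture$mediumSpec,
                  fixture$simConfig, cap = cap)
}

#' A small target-composition fixture
#'
#' Three organisms in the exploratory growth setting: each carbon source
#' supplied at a fixed 5e-4 mmol, inocula of 1e-6 gDW per organism and no
#' death rate — the configuration used when searching for environments that
#' drive the community to a target abundance profile such as
#' `[0.90, 0.05, 0.05]`.
#'
#' @param seed RNG seed for the community draw.
#' @return list with elements `pool`, `community`, `space`, `mediumSpec`,
#'   `simConfig`.
#' @export
targetFixture <- function(seed = 1) {
  pool <- fixturePool()
  set.seed(seed)
  community <- generateRandomCommunity(
    3, pool, archetype_mix = c(specialist = 2 / 3, generalist = 1 / 3,
                               auxotroph = 0, crossfeeder = 0))
  list(pool = pool,
       community = community,
       space = EnvironmentSpace(pool, maxNutrients = 3, sizeRule = "upto",
                                includeEmpty = TRUE),
       mediumSpec = MediumSpec(overrideMmol = 5e-4),
       simConfig = SimulationConfig(duration = 24, timestep = 0.01,
                                    deathRate = 0,
                                    inoculumPerOrganism = 1e-6))
}

#' Write the packaged fixture to files
#'
#' Writes the community spec (YAML), the nutrient pool (CSV) and the full
#' 176-environment mapping with all phenotype metrics (CSV plus exchange
#' companion CSV) into a directory. Deterministic per seed: two invocations
#' with the same seed produce identical files.
#'
#' @param out_dir output directory (created if missing).
#' @param seed fixture seed.
#' @return invisibly, the named vector of file paths written.
#' @export
writeFixture <- function(out_dir, seed = 1) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  fx <- communityFixture(seed)
  paths <- c(pool = file.path(out_dir, "pool.csv"),
             community = file.path(out_dir, "community.yaml"),
             mapping = file.path(out_dir, "mapping.csv"),
             exchanges = file.path(out_dir, "exchanges.csv"))
  writeNutrientPool(fx$pool, paths[["pool"]])
  writeCommunitySpec(fx$community, paths[["community"]])
  mapping <- fixtureMapping(fx)
  writeMapping(mapping, paths[["mapping"]], paths[["exchanges"]])
  invisible(paths)
}
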