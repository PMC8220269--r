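# Session-level cache for the packaged fixture and its exhaustive mapping,
# so the 176 simulations run once per test session.
.cache <- new.env(parent = emptyenv())

getFixture <- function() {
  if (is.null(.cache$fx)) .cache$fx <- communityFixture(seed = 1)
  .cache$fx
}

getMapping <- function() {
  if (is.null(.cache$mp)) .cache$mp <- fixtureMapping(getFixture())
  .cache$mp
}

# The space the GA actually searches: non-empty environments of up to 3
# nutrients (the empty base-medium environment is in the mapping but is never
# proposable by the search).
gaSearchSpace <- function() {
  EnvironmentSpace(getFixture()$pool, maxNutrients = 3, sizeRule = "upto",
                   includeEmpty = FALSE)
}

# The six objective families on the packaged fixture. Focal parameters follow
# the selection logic used for representative examples: the abundance organism
# grows in about a third of environments, the flux organism is the community's
# largest byproduct receiver, the secretion metabolite is the most highly
# secreted one.
fixtureObjectives <- function() {
  fx <- getFixture()
  list(
    entropy = Objective("entropy"),
    organism_abundance = Objective("organism_abundance", organism = "sp_02"),
    total_exchanges = Objective("total_exchanges"),
    flux_to_organism = Objective("flux_to_organism", organism = "cr_03"),
    metabolite_secretion = Objective("metabolite_secretion",
                                     metabolite = "glycine"),
    target_composition = Objective(
      "target_composition",
      target = setNames(c(0.9, rep(0.1 / 12, 12)),
                        organismIds(fx$community))))
}

# Reference fitness distribution over the searchable (non-empty) space.
searchReference <- function(objective) {
  ref <- referenceDistribution(getMapping(), objective)
  ref[setdiff(names(ref), "empty")]
}

# A tiny deterministic two-member cross-feeding community: A eats glc and
# secretes metabolite m; B can only eat m.
crossFeedPair <- function(bRequiresCofactor = FALSE) {
  pool <- NutrientPool("glc", carbon_atoms = 6)
  A <- OrganismSpec("A",
    uptake = data.frame(substrate = "glc", vmax = 10, km = 0.5),
    yield = c(glc = 6 * 0.6 / 40),
    secretion = data.frame(substrate = "glc", product = "m", fraction = 0.4))
  B <- OrganismSpec("B",
    uptake = data.frame(substrate = "m", vmax = 10, km = 0.5),
    yield = c(m = 3 / 40),
    requiredCofactors = if (bRequiresCofactor) "m" else character(0))
  CommunityModel(list(A, B), byproducts = c(m = 3), pool = pool)
}

# Random small community + medium used by conservation/property sweeps.
randomSmallSetup <- function(seed) {
  set.seed(seed)
  pool <- NutrientPool(paste0("n", 1:6), carbon_atoms = sample(2:8, 6, TRUE))
  com <- generateRandomCommunity(4, pool)
  env <- sort(sample(nutrientIds(pool), sample(1:3, 1)))
  medium <- buildMedium(env, MediumSpec(), pool)
  config <- SimulationConfig(duration = 4, timestep = 0.02, deathRate = 0.1,
                             inoculumPerOrganism = 1e-6)
  list(pool = pool, community = com, medium = medium, config = config)
}

# Initial carbon (mmol C) of a setup, for conservation checks.
initialCarbon <- function(setup) {
  atoms <- carbonAtoms(setup$pool, names(setup$medium))
  nOrg <- length(setup$community@organisms)
  sum(setup$medium * atoms) +
    nOrg * setup$config@inoculumPerOrganism * setup$config@carbonPerGDW
}

finalCarbon <- function(result) sum(result@carbonAudit)
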