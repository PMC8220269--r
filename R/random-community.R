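#' @include community.R
NULL

# Default byproduct metabolites (carbon atoms per molecule): the organic
# acids, amino acids and alcohols most commonly cross-fed by fermenting
# communities.
defaultByproducts <- function()
  c(acetate = 2, formate = 1, lactate = 3, succinate = 4,
    glycine = 2, ethanol = 2)

# Deterministic apportionment of n organisms over archetype proportions,
# guaranteeing one organism per requested (positive-share) archetype when n
# permits.
apportionArchetypes <- function(n, mix) {
  mix <- mix / sum(mix)
  counts <- diff(c(0L, floor(cumsum(mix) * n + 1e-9)))
  names(counts) <- names(mix)
  short <- names(counts)[counts == 0L & mix > 0]
  for (a in short) {
    if (n < sum(counts > 0L) + 1L) break
    donor <- names(counts)[which.max(counts)]
    counts[donor] <- counts[donor] - 1L
    counts[a] <- 1L
  }
  counts
}

#' Generate a random synthetic community
#'
#' Builds a seedable community of metabolic archetypes emulating the
#' structure of dense cross-feeding consortia: *specialists* consume a few
#' nutrients fast and secrete byproducts heavily; *generalists* consume most
#' of the pool at modest rates; *cross-feeders* rely largely on byproducts
#' secreted by others; *auxotrophs* grow competitively but only once a
#' required cofactor metabolite (secretable by at least one other community
#' member) is present. Yields are derived from the secretion fractions so
#' that consumed carbon exactly partitions into biomass carbon and secreted
#' carbon (no respiratory loss), which makes the simulator's carbon audit
#' close to machine precision. Randomness uses R's global RNG: fix the seed
#' with `set.seed()` for reproducible communities.
#'
#' @param n_organisms number of organisms.
#' @param pool a [NutrientPool-class].
#' @param archetype_mix named proportions for specialist / generalist /
#'   auxotroph / crossfeeder (summing to 1).
#' @param byproducts named numeric of byproduct carbon atoms.
#' @param carbonPerGDW mmol C per gDW, must match the simulation config for
#'   exact carbon closure.
#' @return a [CommunityModel-class].
#' @export
generateRandomCommunity <- function(n_organisms, pool,
                                    archetype_mix = c(specialist = 0.3,
                                                      generalist = 0.25,
                                                      auxotroph = 0.25,
                                                      crossfeeder = 0.2),
                                    byproducts = defaultByproducts(),
                                    carbonPerGDW = 40) {
  stopifnot(abs(sum(archetype_mix) - 1) < 1e-9)
  full <- setNames(rep(0, 4), c("specialist", "generalist", "auxotroph", "crossfeeder"))
  stopifnot(all(names(archetype_mix) %in% names(full)))
  full[names(archetype_mix)] <- archetype_mix
  archetype_mix <- full
  nutr <- nutrientIds(pool)
  atoms <- c(carbonAtoms(pool), byproducts)
  counts <- apportionArchetypes(n_organisms, archetype_mix)
  kinds <- rep(names(counts), counts)

  makeOrganism <- function(kind, idx, secretableByOthers) {
    id <- sprintf("%s_%02d", substr(kind, 1, 2), idx)
    prods <- names(byproducts)
    if (kind == "specialist") {
      subs <- sample(nutr, sample(2:3, 1))
      vmax <- runif(length(subs), 8, 15)
      km <- runif(length(subs), 0.5, 2)
      myProds <- sample(prods, sample(1:2, 1))
      frac <- runif(length(subs), 0.2, 0.5)
      sec <- data.frame(substrate = subs,
                        product = sample(myProds, length(subs), replace = TRUE),
                        fraction = frac, stringsAsFactors = FALSE)
      cof <- character(0)
    } else if (kind == "generalist") {
      subs <- sample(nutr, max(2L, round(length(nutr) * runif(1, 0.6, 0.8))))
      vmax <- runif(length(subs), 3, 7)
      km <- runif(length(subs), 0.5, 2)
      myProds <- sample(prods, 2)
      sec <- data.frame(substrate = subs,
                        product = sample(myProds, length(subs), replace = TRUE),
                        fraction = runif(length(subs), 0.1, 0.3),
                        stringsAsFactors = FALSE)
      cof <- character(0)
    } else if (kind == "crossfeeder") {
      nsubs <- sample(nutr, sample(1:2, 1))
      bsubs <- sample(prods, sample(2:4, 1))
      subs <- c(nsubs, bsubs)
      vmax <- c(runif(length(nsubs), 4, 8), runif(length(bsubs), 8, 15))
      km <- c(runif(length(nsubs), 0.5, 2), runif(length(bsubs), 0.1, 1))
      myProd <- sample(setdiff(prods, bsubs), 1)
      sec <- data.frame(substrate = nsubs, product = myProd,
                        fraction = runif(length(nsubs), 0.1, 0.3),
                        stringsAsFactors = FALSE)
      cof <- character(0)
    } else { # auxotroph
      subs <- sample(nutr, sample(2:4, 1))
      vmax <- runif(length(subs), 8, 15)
      km <- runif(length(subs), 0.5, 2)
      myProd <- sample(prods, 1)
      sec <- data.frame(substrate = subs, product = myProd,
                        fraction = runif(length(subs), 0.2, 0.4),
                        stringsAsFactors = FALSE)
      cof <- sample(secretableByOthers, 1)
      # auxotrophs also consume their required cofactor once available
      subs <- c(subs, cof)
      vmax <- c(vmax, runif(1, 6, 12))
      km <- c(km, runif(1, 0.1, 1))
    }
    fracPerSub <- tapply(sec$fraction, sec$substrate, sum)
    totalFrac <- setNames(rep(0, length(subs)), subs)
    totalFrac[names(fracPerSub)] <- fracPerSub
    yield <- atoms[subs] * (1 - totalFrac) / carbonPerGDW
    OrganismSpec(id,
                 uptake = data.frame(substrate = subs, vmax = vmax, km = km,
                                     stringsAsFactors = FALSE),
                 yield = setNames(as.numeric(yield), subs),
                 secretion = sec, requiredCofactors = cof)
  }

  # Secretors first so auxotroph cofactors can point at real products.
  order <- c("specialist", "generalist", "crossfeeder", "auxotroph")
  organisms <- list()
  for (kind in order) {
    for (idx in seq_len(counts[[kind]])) {
      secretable <- unique(unlist(lapply(organisms, function(o) o@secretion$product)))
      if (kind == "auxotroph" && length(secretable) == 0L)
        secretable <- names(byproducts) # degenerate all-auxotroph request
      organisms[[length(organisms) + 1L]] <-
        makeOrganism(kind, idx, secretable)
    }
  }
  CommunityModel(organisms, byproducts, pool)
}
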