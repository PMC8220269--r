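#' @include nutrient-pool.R
NULL

#' Organism specifications
#'
#' An `OrganismSpec` parameterizes one member of a consumer-resource
#' community: which substrates (pool nutrients or byproduct metabolites) it
#' can take up and at what Monod kinetics, the biomass yield on each, which
#' fraction of each consumed substrate's carbon it re-emits as which byproduct
#' metabolite, and which metabolites must be present for it to grow at all
#' (auxotrophy gate).
#'
#' @slot id organism identifier.
#' @slot uptake `data.frame` with columns `substrate`, `vmax`
#'   (mmol gDW^-1 h^-1) and `km` (mM).
#' @slot yield named numeric, gDW produced per mmol of each consumable
#'   substrate.
#' @slot secretion `data.frame` with columns `substrate`, `product`,
#'   `fraction`: the fraction of carbon consumed from `substrate` re-emitted
#'   as `product`. Fractions lie in `[0,1]` and sum to at most 1 per
#'   substrate.
#' @slot requiredCofactors character vector of metabolite ids that must all
#'   be present (amount above a small tolerance) for any growth or uptake.
#' @name OrganismSpec-class
#' @exportClass OrganismSpec
setClass("OrganismSpec", representation(
  id = "character", uptake = "data.frame", yield = "numeric",
  secretion = "data.frame", requiredCofactors = "character"))

setValidity("OrganismSpec", function(object) {
  up <- object@uptake
  if (nrow(up) && !all(c("substrate", "vmax", "km") %in% names(up)))
    return("uptake needs columns substrate, vmax, km")
  if (nrow(up) && (any(up$vmax < 0) || any(up$km <= 0)))
    return("vmax must be >= 0 and km > 0")
  if (nrow(up) && anyDuplicated(up$substrate))
    return("duplicate uptake substrate")
  if (any(object@yield < 0)) return("yields must be >= 0")
  if (!all(names(object@yield) %in% up$substrate))
    return("yield named for a substrate not in uptake")
  sec <- object@secretion
  if (nrow(sec)) {
    if (!all(c("substrate", "product", "fraction") %in% names(sec)))
      return("secretion needs columns substrate, product, fraction")
    if (any(sec$fraction < 0) || any(sec$fraction > 1))
      return("secretion fractions must lie in [0,1]")
    sums <- tapply(sec$fraction, sec$substrate, sum)
    if (any(sums > 1 + 1e-12))
      return("secretion fractions sum to more than 1 for a substrate")
    if (!all(sec$substrate %in% up$substrate))
      return("secretion from a substrate the organism does not consume")
  }
  TRUE
})

#' @rdname OrganismSpec-class
#' @param id organism identifier.
#' @param uptake,yield,secretion,requiredCofactors see slots above.
#' @export
OrganismSpec <- function(id, uptake, yield = numeric(0),
                         secretion = NULL, requiredCofactors = character(0)) {
  if (is.null(secretion))
    secretion <- data.frame(substrate = character(0), product = character(0),
                            fraction = numeric(0), stringsAsFactors = FALSE)
  new("OrganismSpec", id = as.character(id), uptake = uptake,
      yield = yield, secretion = secretion,
      requiredCofactors = as.character(requiredCofactors))
}

setMethod("show", "OrganismSpec", function(object) {
  cat(sprintf("OrganismSpec '%s': %d substrates, %d secretion routes%s\n",
              object@id, nrow(object@uptake), nrow(object@secretion),
              if (length(object@requiredCofactors))
                paste0(", requires ", paste(object@requiredCofactors, collapse = "+"))
              else ""))
})

#' Community models
#'
#' A `CommunityModel` bundles the organisms, the nutrient pool they live on
#' and the byproduct metabolites they can secrete and cross-feed (with their
#' carbon counts, needed for the carbon bookkeeping of the simulator).
#'
#' @slot organisms list of [OrganismSpec-class].
#' @slot byproducts named numeric: carbon atoms per molecule for each
#'   byproduct metabolite id.
#' @slot pool the [NutrientPool-class] of primary nutrients.
#' @name CommunityModel-class
#' @exportClass CommunityModel
setClass("CommunityModel", representation(
  organisms = "list", byproducts = "numeric", pool = "NutrientPool"))

setValidity("CommunityModel", function(object) {
  ids <- vapply(object@organisms, function(o) o@id, character(1))
  if (anyDuplicated(ids)) return("duplicate organism ids")
  mets <- c(nutrientIds(object@pool), names(object@byproducts))
  for (o in object@organisms) {
    if (!all(o@uptake$substrate %in% mets))
      return(sprintf("organism '%s' consumes an undeclared substrate", o@id))
    if (!all(o@secretion$product %in% names(object@byproducts)))
      return(sprintf("organism '%s' secretes an undeclared byproduct", o@id))
    if (!all(o@requiredCofactors %in% mets))
      return(sprintf("organism '%s' requires an undeclared cofactor", o@id))
  }
  if (length(object@byproducts) && any(object@byproducts < 1))
    return("byproduct carbon counts must be >= 1")
  clash <- intersect(names(object@byproducts), nutrientIds(object@pool))
  if (length(clash))
    return(sprintf("byproduct ids clash with pool nutrient ids: %s",
                   paste(clash, collapse = ", ")))
  TRUE
})

#' @rdname CommunityModel-class
#' @param organisms list of [OrganismSpec-class].
#' @param byproducts named numeric of byproduct carbon atoms.
#' @param pool a [NutrientPool-class].
#' @export
CommunityModel <- function(organisms, byproducts, pool) {
  new("CommunityModel", organisms = organisms,
      byproducts = byproducts, pool = pool)
}

#' @describeIn CommunityModel Organism ids, in model order.
#' @param community a [CommunityModel-class].
#' @export
organismIds <- function(community)
  vapply(community@organisms, function(o) o@id, character(1))

setMethod("show", "CommunityModel", function(object) {
  cat(sprintf("CommunityModel: %d organisms on %d nutrients, %d byproducts\n",
              length(object@organisms), poolSize(object@pool),
              length(object@byproducts)))
  cat("  organisms:", paste(organismIds(object), collapse = ", "), "\n")
})

#' Read / write a community specification file
#'
#' The on-disk format is YAML with top-level keys `byproducts` (metabolite id
#' to carbon atoms), `pool` (list of id/name/carbon_atoms records) and
#' `organisms` (one entry per organism with `uptake`, `yield`, `secretion` and
#' `required_cofactors` blocks). Write-then-read round-trips the model.
#'
#' @param file path to the YAML file.
#' @return `readCommunitySpec` returns a [CommunityModel-class].
#' @export
readCommunitySpec <- function(file) {
  doc <- yaml::read_yaml(file)
  pool <- NutrientPool(
    id = vapply(doc$pool, `[[`, character(1), "id"),
    name = vapply(doc$pool, `[[`, character(1), "name"),
    carbon_atoms = vapply(doc$pool, `[[`, numeric(1), "carbon_atoms"))
  byproducts <- unlist(doc$byproducts)
  if (is.null(byproducts)) byproducts <- setNames(numeric(0), character(0))
  organisms <- lapply(doc$organisms, function(o) {
    up <- do.call(rbind, lapply(o$uptake, function(u)
      data.frame(substrate = u$substrate, vmax = u$vmax, km = u$km,
                 stringsAsFactors = FALSE)))
    if (is.null(up)) up <- data.frame(substrate = character(0), vmax = numeric(0),
                                      km = numeric(0), stringsAsFactors = FALSE)
    sec <- do.call(rbind, lapply(o$secretion, function(s)
      data.frame(substrate = s$substrate, product = s$product,
                 fraction = s$fraction, stringsAsFactors = FALSE)))
    yield <- unlist(o$yield)
    if (is.null(yield)) yield <- setNames(numeric(0), character(0))
    OrganismSpec(o$id, up, yield, sec,
                 requiredCofactors = as.character(unlist(o$required_cofactors)))
  })
  CommunityModel(organisms, byproducts, pool)
}

#' @rdname readCommunitySpec
#' @param community a [CommunityModel-class] to serialize.
#' @export
writeCommunitySpec <- function(community, file) {
  poolTab <- community@pool@nutrients
  doc <- list(
    byproducts = as.list(community@byproducts),
    pool = lapply(seq_len(nrow(poolTab)), function(i)
      list(id = poolTab$id[i], name = poolTab$name[i],
           carbon_atoms = poolTab$carbon_atoms[i])),
    organisms = lapply(community@organisms, function(o) {
      list(id = o@id,
           uptake = lapply(seq_len(nrow(o@uptake)), function(i)
             list(substrate = o@uptake$substrate[i], vmax = o@uptake$vmax[i],
                  km = o@uptake$km[i])),
           yield = as.list(o@yield),
           secretion = lapply(seq_len(nrow(o@secretion)), function(i)
             list(substrate = o@secretion$substrate[i],
                  product = o@secretion$product[i],
                  fraction = o@secretion$fraction[i])),
           required_cofactors = as.list(o@requiredCofactors))
    }))
  yaml::write_yaml(doc, file, precision = 17)
  invisible(file)
}
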