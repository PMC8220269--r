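#' Nutrient pools
#'
#' A `NutrientPool` is the ordered list of candidate limiting nutrients
#' (typically carbon sources) from which environments are assembled. Each
#' nutrient carries an id, a display name and its number of carbon atoms per
#' molecule, which drives the equimolar carbon arithmetic of
#' [buildMedium()]. The list order is stable and defines the canonical
#' nutrient indexing used for reproducible environment enumeration.
#'
#' @slot nutrients `data.frame` with columns `id` (character, unique),
#'   `name` (character) and `carbon_atoms` (integer >= 1).
#' @name NutrientPool-class
#' @exportClass NutrientPool
setClass("NutrientPool", representation(nutrients = "data.frame"))

setValidity("NutrientPool", function(object) {
  tab <- object@nutrients
  need <- c("id", "name", "carbon_atoms")
  if (!all(need %in% names(tab)))
    return(sprintf("nutrient table must have columns %s",
                   paste(need, collapse = ", ")))
  if (anyDuplicated(tab$id))
    return("nutrient ids must be unique within a pool")
  if (any(tab$carbon_atoms < 1) || any(tab$carbon_atoms != round(tab$carbon_atoms)))
    return("carbon_atoms must be positive integers")
  TRUE
})

#' Construct a nutrient pool
#'
#' @param id character vector of unique nutrient identifiers.
#' @param name display names; defaults to `id`.
#' @param carbon_atoms integer vector, carbon atoms per molecule (>= 1).
#' @return A [NutrientPool-class] object.
#' @examples
#' pool <- NutrientPool(c("glc", "ace"), carbon_atoms = c(6, 2))
#' poolSize(pool)
#' @export
NutrientPool <- function(id, name = id, carbon_atoms) {
  new("NutrientPool", nutrients = data.frame(
    id = as.character(id), name = as.character(name),
    carbon_atoms = as.integer(carbon_atoms), stringsAsFactors = FALSE))
}

#' @describeIn NutrientPool Number of nutrients in the pool.
#' @param pool a [NutrientPool-class].
#' @export
poolSize <- function(pool) nrow(pool@nutrients)

#' @describeIn NutrientPool Canonical (ordered) nutrient ids.
#' @export
nutrientIds <- function(pool) pool@nutrients$id

#' @describeIn NutrientPool Carbon atoms per molecule, named by nutrient id;
#'   optionally restricted to `ids`.
#' @param ids optional character vector of nutrient ids to look up.
#' @export
carbonAtoms <- function(pool, ids = NULL) {
  atoms <- setNames(pool@nutrients$carbon_atoms, pool@nutrients$id)
  if (is.null(ids)) return(atoms)
  missing <- setdiff(ids, names(atoms))
  if (length(missing))
    stop("unknown nutrient id(s): ", paste(missing, collapse = ", "))
  atoms[ids]
}

setMethod("show", "NutrientPool", function(object) {
  cat(sprintf("NutrientPool with %d nutrients\n", poolSize(object)))
  n <- min(poolSize(object), 6L)
  print(utils::head(object@nutrients, n))
  if (poolSize(object) > n) cat(sprintf("... and %d more\n", poolSize(object) - n))
})

#' Read / write a nutrient pool CSV
#'
#' The on-disk format is a CSV with header `id,name,carbon_atoms`.
#'
#' @param file path to the CSV file.
#' @return `readNutrientPool` returns a [NutrientPool-class];
#'   `writeNutrientPool` returns `file` invisibly.
#' @export
readNutrientPool <- function(file) {
  tab <- read.csv(file, stringsAsFactors = FALSE)
  for (col in c("id", "name", "carbon_atoms"))
    if (!col %in% names(tab))
      stop(sprintf("nutrient pool file '%s' is missing column '%s'", file, col))
  NutrientPool(tab$id, tab$name, tab$carbon_atoms)
}

#' @rdname readNutrientPool
#' @param pool a [NutrientPool-class] to serialize.
#' @export
writeNutrientPool <- function(pool, file) {
  write.csv(pool@nutrients, file, row.names = FALSE, quote = FALSE)
  invisible(file)
}
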