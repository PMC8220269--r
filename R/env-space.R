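#' @include nutrient-pool.R
NULL

#' Combinatorial environment spaces
#'
#' An `EnvironmentSpace` describes the admissible environments over a nutrient
#' pool: subsets of at most (or exactly) `maxNutrients` nutrients, optionally
#' including the empty (base-medium-only) environment. Environments themselves
#' are represented as sorted character vectors of nutrient ids; two
#' environments are equal iff their id sets are equal.
#'
#' @slot pool a [NutrientPool-class].
#' @slot maxNutrients integer, the size bound N.
#' @slot sizeRule `"upto"` (subsets of size <= N) or `"exact"` (size == N).
#' @slot includeEmpty logical; whether the empty environment is admissible
#'   (only meaningful under the `"upto"` rule or N = 0).
#' @name EnvironmentSpace-class
#' @exportClass EnvironmentSpace
setClass("EnvironmentSpace", representation(
  pool = "NutrientPool", maxNutrients = "integer",
  sizeRule = "character", includeEmpty = "logical"))

setValidity("EnvironmentSpace", function(object) {
  if (!object@sizeRule %in% c("upto", "exact"))
    return("sizeRule must be 'upto' or 'exact'")
  n <- poolSize(object@pool)
  if (object@maxNutrients < 1L || object@maxNutrients > n)
    return(sprintf("maxNutrients must be in 1..%d (pool size)", n))
  TRUE
})

#' Construct an environment space
#'
#' Defaults reproduce the benchmark-style space: subsets of up to N nutrients
#' with the empty environment included.
#'
#' @param pool a [NutrientPool-class].
#' @param maxNutrients the maximum (or exact) number of nutrients N.
#' @param sizeRule `"upto"` or `"exact"`.
#' @param includeEmpty whether the empty environment belongs to the space.
#' @return An [EnvironmentSpace-class].
#' @examples
#' pool <- NutrientPool(letters[1:5], carbon_atoms = rep(3, 5))
#' space <- EnvironmentSpace(pool, maxNutrients = 2)
#' countEnvironments(5, 2)              # 16: sum_{k=0..2} C(5,k)
#' @export
EnvironmentSpace <- function(pool, maxNutrients,
                             sizeRule = c("upto", "exact"),
                             includeEmpty = TRUE) {
  sizeRule <- match.arg(sizeRule)
  new("EnvironmentSpace", pool = pool, maxNutrients = as.integer(maxNutrients),
      sizeRule = sizeRule, includeEmpty = isTRUE(includeEmpty))
}

setMethod("show", "EnvironmentSpace", function(object) {
  cat(sprintf(
    "EnvironmentSpace: %s %d of %d nutrients%s (%s environments)\n",
    if (object@sizeRule == "upto") "up to" else "exactly",
    object@maxNutrients, poolSize(object@pool),
    if (object@includeEmpty && object@sizeRule == "upto") ", incl. empty" else "",
    format(countEnvironments(poolSize(object@pool), object@maxNutrients,
                             object@sizeRule, object@includeEmpty),
           big.mark = " ")))
})

#' Count admissible environments in closed form
#'
#' Computes the number of nutrient subsets by binomial sums; nothing is
#' enumerated, so arbitrarily large spaces can be counted instantly. All
#' subsets of 20 nutrients number 2^20 = 1 048 576; subsets of up to 4 of 20
#' (empty included) number 6196; subsets of exactly 3 of 154 number 596 904.
#'
#' @param pool_size number of nutrients in the pool.
#' @param k subset-size bound (meaning set by `sizeRule`).
#' @param sizeRule `"upto"` (sizes 0..k or 1..k, see `includeEmpty`) or
#'   `"exact"` (size k only).
#' @param includeEmpty under `"upto"`, whether the size-0 subset counts.
#' @return the count, as a double (exact for all counts below 2^53).
#' @examples
#' countEnvironments(20, 4)                        # 6196
#' countEnvironments(154, 3, "exact", FALSE)       # 596904
#' countEnvironments(20, 20)                       # 1048576
#' @export
countEnvironments <- function(pool_size, k, sizeRule = c("upto", "exact"),
                              includeEmpty = TRUE) {
  sizeRule <- match.arg(sizeRule)
  if (k < 0 || k > pool_size)
    stop(sprintf("k = %s outside 0..pool_size = %s", k, pool_size))
  if (sizeRule == "exact") return(choose(pool_size, k))
  lo <- if (includeEmpty) 0L else 1L
  if (k < lo) return(0)
  sum(choose(pool_size, lo:k))
}

countSpace <- function(space) {
  countEnvironments(poolSize(space@pool), space@maxNutrients,
                    space@sizeRule, space@includeEmpty)
}

#' Stable environment identifier
#'
#' The id of an environment is its sorted nutrient-id set joined by `"+"`,
#' or `"empty"` for the base-medium-only environment. Ids are order-free:
#' permutations of the same set map to the same id.
#'
#' @param env character vector of nutrient ids (an environment).
#' @return a single string.
#' @export
environmentId <- function(env) {
  if (length(env) == 0L) return("empty")
  paste(sort(unique(as.character(env))), collapse = "+")
}

# Canonical sort key: size first, then lexicographic on canonical pool
# indices. Used for deterministic enumeration order and fitness tie-breaks.
canonicalKey <- function(env, pool) {
  idx <- match(env, nutrientIds(pool))
  if (anyNA(idx)) stop("environment contains nutrients not in the pool")
  idx <- sort(idx)
  sprintf("%03d|%s", length(idx), paste(sprintf("%04d", idx), collapse = ","))
}

# Normalize an environment to its canonical (pool-index-sorted) form and
# check admissibility against a space.
normalizeEnvironment <- function(env, space) {
  env <- unique(as.character(env))
  ids <- nutrientIds(space@pool)
  idx <- match(env, ids)
  if (anyNA(idx)) stop("environment contains nutrients not in the pool: ",
                       paste(env[is.na(idx)], collapse = ", "))
  env <- ids[sort(idx)]
  n <- length(env)
  ok <- if (space@sizeRule == "exact") n == space@maxNutrients
        else n <= space@maxNutrients && (n > 0L || space@includeEmpty)
  if (!ok) stop(sprintf("environment of size %d not admissible in this space", n))
  env
}

#' Enumerate all environments of a space
#'
#' Environments are returned in canonical order: by subset size, then
#' lexicographically on canonical nutrient indices. Enumeration refuses to
#' materialize spaces larger than `cap`, protecting against accidentally
#' expanding spaces meant for on-demand search (such as the 596 904
#' environments of exactly 3 out of 154 nutrients).
#'
#' @param space an [EnvironmentSpace-class].
#' @param cap refuse enumeration if the closed-form count exceeds this.
#' @return list of environments (sorted character vectors; the empty
#'   environment is `character(0)`).
#' @examples
#' pool <- NutrientPool(c("a", "b"), carbon_atoms = c(1, 1))
#' enumerateEnvironments(EnvironmentSpace(pool, 2))
#' @export
enumerateEnvironments <- function(space, cap = 100000) {
  count <- countSpace(space)
  if (count > cap)
    stop(sprintf(
      "space holds %s environments, above the enumeration cap of %s; %s",
      format(count, big.mark = " "), format(cap, big.mark = " "),
      "raise `cap` explicitly or use on-demand evaluation"))
  ids <- nutrientIds(space@pool)
  sizes <- if (space@sizeRule == "exact") space@maxNutrients else
    seq.int(if (space@includeEmpty) 0L else 1L, space@maxNutrients)
  out <- vector("list", count)
  pos <- 0L
  for (k in sizes) {
    if (k == 0L) { pos <- pos + 1L; out[[pos]] <- character(0); next }
    sets <- combn(seq_along(ids), k)
    for (j in seq_len(ncol(sets))) {
      pos <- pos + 1L
      out[[pos]] <- ids[sets[, j]]
    }
  }
  stopifnot(pos == count)
  out
}

#' Draw a random admissible environment
#'
#' The subset size is drawn uniformly from 1..N (`"upto"` rule) or fixed at N
#' (`"exact"` rule), then a uniform subset of that size is drawn. Uniformity
#' over sizes keeps populations from being biased toward large nutrient sets.
#' Randomness comes from R's global RNG stream, so draws are reproducible
#' under `set.seed()`. The empty environment is never drawn.
#'
#' @param space an [EnvironmentSpace-class].
#' @return an environment (sorted character vector of nutrient ids).
#' @export
randomEnvironment <- function(space) {
  ids <- nutrientIds(space@pool)
  k <- if (space@sizeRule == "exact") space@maxNutrients
       else sample.int(space@maxNutrients, 1L)
  ids[sort(sample.int(length(ids), k))]
}

#' Enumerate a space to CSV
#'
#' Writes the canonical environment table (`env_id`, `nutrients`
#' semicolon-joined, `size`) and returns the count. With `countOnly = TRUE`
#' nothing is materialized or written; only the closed-form count is returned,
#' which is how spaces too large to enumerate are interrogated.
#'
#' @param pool a [NutrientPool-class] or path to a pool CSV.
#' @param k,sizeRule,includeEmpty as in [countEnvironments()].
#' @param file output CSV path, or `NULL` to skip writing.
#' @param countOnly if `TRUE`, only count.
#' @param cap enumeration guard, as in [enumerateEnvironments()].
#' @return the environment count, invisibly a list with `count` and `table`.
#' @export
enumerateToCsv <- function(pool, k, sizeRule = c("upto", "exact"),
                           includeEmpty = TRUE, file = NULL,
                           countOnly = FALSE, cap = 100000) {
  sizeRule <- match.arg(sizeRule)
  if (is.character(pool)) pool <- readNutrientPool(pool)
  count <- countEnvironments(poolSize(pool), k, sizeRule, includeEmpty)
  if (countOnly) return(invisible(list(count = count, table = NULL)))
  space <- EnvironmentSpace(pool, k, sizeRule, includeEmpty)
  envs <- enumerateEnvironments(space, cap = cap)
  tab <- data.frame(
    env_id = vapply(envs, environmentId, character(1)),
    nutrients = vapply(envs, paste, character(1), collapse = ";"),
    size = lengths(envs), stringsAsFactors = FALSE)
  if (!is.null(file)) write.csv(tab, file, row.names = FALSE, quote = FALSE)
  invisible(list(count = count, table = tab))
}
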