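#' @include nutrient-pool.R
NULL

#' Medium specification and construction
#'
#' A `MediumSpec` fixes how an environment (a set of nutrient ids) is turned
#' into concrete nutrient amounts on top of a non-limiting base medium. In the
#' default equimolar-carbon mode every nutrient gets the same molar amount x,
#' chosen so the summed carbon equals `totalCarbonMM` mmol C per litre in
#' `volumeUl` microlitres (50 mM C in 400 ul gives 0.02 mmol C total). In
#' override mode every nutrient gets a fixed molar amount regardless of its
#' carbon content, the scheme used for large exploratory spaces where each
#' carbon source is supplied at 5e-4 mmol.
#'
#' @slot totalCarbonMM total carbon concentration, mM C.
#' @slot volumeUl culture volume, microlitres.
#' @slot overrideMmol fixed mmol per nutrient, or `NA` for equimolar-carbon
#'   mode.
#' @name MediumSpec-class
#' @exportClass MediumSpec
setClass("MediumSpec", representation(
  totalCarbonMM = "numeric", volumeUl = "numeric", overrideMmol = "numeric"))

setValidity("MediumSpec", function(object) {
  if (object@totalCarbonMM <= 0) return("totalCarbonMM must be positive")
  if (object@volumeUl <= 0) return("volumeUl must be positive")
  if (!is.na(object@overrideMmol) && object@overrideMmol <= 0)
    return("overrideMmol must be positive when set")
  TRUE
})

#' @rdname MediumSpec-class
#' @param totalCarbonMM total carbon concentration in mM C (default 50).
#' @param volumeUl culture volume in microlitres (default 400).
#' @param overrideMmol fixed mmol per nutrient (default `NA`, equimolar mode).
#' @export
MediumSpec <- function(totalCarbonMM = 50, volumeUl = 400, overrideMmol = NA_real_) {
  new("MediumSpec", totalCarbonMM = as.numeric(totalCarbonMM),
      volumeUl = as.numeric(volumeUl), overrideMmol = as.numeric(overrideMmol))
}

setMethod("show", "MediumSpec", function(object) {
  if (is.na(object@overrideMmol))
    cat(sprintf("MediumSpec: equimolar, %g mM C in %g ul (%g mmol C total)\n",
                object@totalCarbonMM, object@volumeUl, totalCarbonMmol(object)))
  else
    cat(sprintf("MediumSpec: fixed %g mmol per nutrient in %g ul\n",
                object@overrideMmol, object@volumeUl))
})

# Total mmol of carbon implied by the equimolar mode.
totalCarbonMmol <- function(spec) spec@totalCarbonMM * spec@volumeUl * 1e-6

#' Build the nutrient amounts of an environment
#'
#' @param env an environment (character vector of nutrient ids; may be empty).
#' @param spec a [MediumSpec-class].
#' @param pool the [NutrientPool-class] supplying carbon counts.
#' @return named numeric vector of mmol per nutrient (length 0 for the empty
#'   environment: base medium only).
#' @examples
#' pool <- NutrientPool(c("glc", "ace"), carbon_atoms = c(6, 2))
#' buildMedium("glc", MediumSpec(), pool)           # 0.02/6 mmol
#' buildMedium(c("glc", "ace"), MediumSpec(), pool) # each 0.02/8 mmol
#' @export
buildMedium <- function(env, spec, pool) {
  env <- sort(unique(as.character(env)))
  if (length(env) == 0L) return(setNames(numeric(0), character(0)))
  atoms <- carbonAtoms(pool, env)
  if (!is.na(spec@overrideMmol))
    return(setNames(rep(spec@overrideMmol, length(env)), env))
  x <- totalCarbonMmol(spec) / sum(atoms)
  setNames(rep(x, length(env)), env)
}
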