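#' @include nutrient-pool.R
NULL

#' Community phenotype summaries
#'
#' A `PhenotypeSummary` packages every community-level quantity the objective
#' families consume: per-organism final biomass and relative abundance,
#' species richness, Shannon entropy (bits), the metabolic-exchange records
#' (donor, receiver, metabolite, amount), community-wide secretion totals per
#' metabolite and the total flux directed at each organism.
#'
#' @slot organisms character vector of organism ids.
#' @slot finalBiomass named numeric, gDW per organism.
#' @slot abundances named numeric, relative abundances (sum 1, or all 0 for an
#'   extinct community).
#' @slot richness integer, organisms above the presence threshold.
#' @slot entropy numeric, Shannon entropy in bits.
#' @slot exchanges `data.frame` with columns donor, receiver, metabolite,
#'   amount_mmol (net transfers over the whole run; donor != receiver).
#' @slot nExchanges integer, distinct directed (donor, receiver, metabolite)
#'   triples.
#' @slot secretionTotals named numeric, community-wide cumulative secretion
#'   per metabolite (mmol).
#' @slot fluxTo named numeric, total mmol absorbed from other organisms, per
#'   organism.
#' @name PhenotypeSummary-class
#' @exportClass PhenotypeSummary
setClass("PhenotypeSummary", representation(
  organisms = "character", finalBiomass = "numeric", abundances = "numeric",
  richness = "integer", entropy = "numeric", exchanges = "data.frame",
  nExchanges = "integer", secretionTotals = "numeric", fluxTo = "numeric"))

setMethod("show", "PhenotypeSummary", function(object) {
  cat(sprintf(
    "PhenotypeSummary: %d organisms, richness %d, entropy %.3f bits, %d exchanges\n",
    length(object@organisms), object@richness, object@entropy, object@nExchanges))
})

emptyExchangeFrame <- function() {
  data.frame(donor = character(0), receiver = character(0),
             metabolite = character(0), amount_mmol = numeric(0),
             stringsAsFactors = FALSE)
}

#' Relative abundances from final biomass
#'
#' Each organism's biomass divided by the community total. The all-zero input
#' (an extinct community) yields the reserved all-zero vector rather than NaN.
#'
#' @param final_biomass numeric vector of per-organism biomass (gDW, >= 0).
#' @return numeric vector of the same length (and names), summing to 1 unless
#'   all inputs are zero.
#' @export
relativeAbundances <- function(final_biomass) {
  if (any(final_biomass < 0)) stop("biomass must be non-negative")
  total <- sum(final_biomass)
  if (total == 0) return(final_biomass * 0)
  final_biomass / total
}

#' Shannon entropy of a community (bits)
#'
#' H = -sum_i p_i log2 p_i over organism relative abundances; zero-abundance
#' terms contribute 0. Larger H means more even representation.
#'
#' @param p relative abundance vector.
#' @return entropy in bits, in `[0, log2(length(p))]`.
#' @examples
#' shannonEntropy(rep(0.25, 4))   # 2
#' shannonEntropy(c(1, 0, 0))     # 0
#' @export
shannonEntropy <- function(p) {
  pos <- p[p > 0]
  if (length(pos) == 0L) return(0)
  -sum(pos * log2(pos))
}

#' Species richness
#'
#' Number of organisms whose relative abundance exceeds a presence threshold.
#' The default threshold of 0 counts any organism with positive biomass.
#'
#' @param p relative abundance vector.
#' @param presence_threshold abundance strictly above this counts as present.
#' @return integer count.
#' @export
speciesRichness <- function(p, presence_threshold = 0) {
  if (presence_threshold < 0) stop("presence_threshold must be >= 0")
  sum(p > presence_threshold)
}

#' Count metabolic exchanges
#'
#' One exchange is the transfer of a unique metabolite from one organism to
#' another: distinct (donor, receiver, metabolite) triples, regardless of how
#' many records or how much material they comprise. With
#' `directed = FALSE`, A->B and B->A of the same metabolite collapse to one
#' (unordered-pair counting, the convention behind the C(n,2) x m cap).
#'
#' @param records exchange `data.frame` with columns donor, receiver,
#'   metabolite (amounts ignored).
#' @param directed count directed triples (default) or unordered pairs.
#' @return integer count.
#' @export
countExchanges <- function(records, directed = TRUE) {
  if (nrow(records) == 0L) return(0L)
  pair <- if (directed) paste(records$donor, records$receiver)
          else paste(pmin(records$donor, records$receiver),
                     pmax(records$donor, records$receiver))
  length(unique(paste(pair, records$metabolite)))
}

#' Maximum possible number of exchanges
#'
#' If each of n organisms transfers each of m metabolites to each other
#' organism (one net direction per unordered pair), the cap is C(n,2) x m;
#' 13 organisms and 737 extracellular metabolites give 57 486.
#'
#' @param n_organisms number of organisms (cap is 0 below 2).
#' @param n_metabolites number of exchangeable metabolites.
#' @return integer-valued count.
#' @export
maxPossibleExchanges <- function(n_organisms, n_metabolites) {
  if (n_organisms < 2) return(0)
  choose(n_organisms, 2) * n_metabolites
}

#' Total metabolic flux directed at an organism
#'
#' @param records exchange `data.frame` (columns donor, receiver, metabolite,
#'   amount_mmol).
#' @param organism_id the receiving organism.
#' @param organisms optional character vector of known organism ids, used to
#'   validate `organism_id` (receivers absent from `records` legitimately
#'   have zero flux).
#' @return mmol received from all other organisms.
#' @export
fluxToOrganism <- function(records, organism_id, organisms = NULL) {
  known <- unique(c(organisms, records$donor, records$receiver))
  if (!organism_id %in% known)
    stop(sprintf("unknown organism '%s'", organism_id))
  sum(records$amount_mmol[records$receiver == organism_id])
}

#' Community-wide secretion of a metabolite
#'
#' @param secretion_totals named numeric of cumulative secretion per
#'   metabolite (as in a [PhenotypeSummary-class]).
#' @param metabolite_id the metabolite of interest.
#' @return mmol secreted by all organisms over the run.
#' @export
secretionTotal <- function(secretion_totals, metabolite_id) {
  if (!metabolite_id %in% names(secretion_totals))
    stop(sprintf("metabolite '%s' unknown to this simulation", metabolite_id))
  unname(secretion_totals[[metabolite_id]])
}

#' Assemble a PhenotypeSummary from its parts
#'
#' Mostly internal glue used by the simulator and the mapping reader; exported
#' because lookup evaluators over external datasets need it too.
#'
#' @param finalBiomass named numeric of per-organism gDW.
#' @param exchanges exchange record `data.frame` (may be empty).
#' @param secretionTotals named numeric per metabolite.
#' @param presenceThreshold see [speciesRichness()].
#' @param nExchanges override for the directed exchange count (used when
#'   records themselves are unavailable, e.g. a counts-only lookup table).
#' @param fluxTo optional named per-organism absorbed totals (recomputed from
#'   `exchanges` when `NULL`).
#' @return a [PhenotypeSummary-class].
#' @export
PhenotypeSummary <- function(finalBiomass, exchanges = emptyExchangeFrame(),
                             secretionTotals = numeric(0),
                             presenceThreshold = 0,
                             nExchanges = NULL, fluxTo = NULL) {
  organisms <- names(finalBiomass)
  p <- relativeAbundances(finalBiomass)
  if (is.null(fluxTo)) {
    fluxTo <- setNames(numeric(length(organisms)), organisms)
    if (nrow(exchanges) > 0L) {
      got <- tapply(exchanges$amount_mmol, exchanges$receiver, sum)
      fluxTo[names(got)] <- got
    }
  }
  if (is.null(nExchanges)) nExchanges <- countExchanges(exchanges)
  new("PhenotypeSummary", organisms = organisms, finalBiomass = finalBiomass,
      abundances = p, richness = as.integer(speciesRichness(p, presenceThreshold)),
      entropy = shannonEntropy(p), exchanges = exchanges,
      nExchanges = as.integer(nExchanges), secretionTotals = secretionTotals,
      fluxTo = fluxTo)
}

#' @describeIn PhenotypeSummary Relative abundance vector.
#' @param summary a [PhenotypeSummary-class].
#' @export
abundances <- function(summary) summary@abundances

#' @describeIn PhenotypeSummary Exchange records.
#' @export
exchangeRecords <- function(summary) summary@exchanges
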