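#' @include metrics.R
NULL

#' Objective families
#'
#' An `Objective` maps a [PhenotypeSummary-class] to a scalar fitness. Six
#' families are available: `entropy` (community Shannon entropy),
#' `organism_abundance` (relative abundance of a focal organism),
#' `total_exchanges` (number of directed metabolic exchanges),
#' `flux_to_organism` (total mmol directed at a focal organism),
#' `metabolite_secretion` (community-wide secretion of a focal metabolite) and
#' `target_composition` (sum squared error to a target abundance vector,
#' minimized). Internally fitness always follows an always-maximize
#' convention: for minimize-direction objectives the raw value is negated, so
#' the search engine is objective-agnostic while logs keep the raw value.
#'
#' @slot family one of the six family names.
#' @slot direction `"maximize"` or `"minimize"`.
#' @slot params named list: `organism` for the organism families,
#'   `metabolite` for secretion, `target` (named or unnamed numeric summing
#'   to 1) for target composition.
#' @name Objective-class
#' @exportClass Objective
setClass("Objective", representation(
  family = "character", direction = "character", params = "list"))

objectiveFamilies <- c("entropy", "organism_abundance", "total_exchanges",
                       "flux_to_organism", "metabolite_secretion",
                       "target_composition")

setValidity("Objective", function(object) {
  if (!object@family %in% objectiveFamilies)
    return(sprintf("unknown objective family '%s'; valid: %s", object@family,
                   paste(objectiveFamilies, collapse = ", ")))
  if (!object@direction %in% c("maximize", "minimize"))
    return("direction must be 'maximize' or 'minimize'")
  need <- switch(object@family,
                 organism_abundance = "organism",
                 flux_to_organism = "organism",
                 metabolite_secretion = "metabolite",
                 target_composition = "target", NULL)
  if (!is.null(need) && is.null(object@params[[need]]))
    return(sprintf("family '%s' needs parameter '%s'", object@family, need))
  if (object@family == "target_composition") {
    t <- object@params$target
    if (abs(sum(t) - 1) > 1e-9) return("target abundances must sum to 1")
  }
  TRUE
})

#' @rdname Objective-class
#' @param family objective family name.
#' @param direction optional; defaults to `"minimize"` for
#'   `target_composition` and `"maximize"` otherwise.
#' @param organism,metabolite,target family-specific parameters.
#' @examples
#' Objective("entropy")
#' Objective("target_composition", target = c(0.90, 0.05, 0.05))
#' @export
Objective <- function(family, direction = NULL, organism = NULL,
                      metabolite = NULL, target = NULL) {
  if (is.null(direction))
    direction <- if (identical(family, "target_composition")) "minimize"
                 else "maximize"
  new("Objective", family = family, direction = direction,
      params = Filter(Negate(is.null),
                      list(organism = organism, metabolite = metabolite,
                           target = target)))
}

setMethod("show", "Objective", function(object) {
  extra <- vapply(object@params, function(p) paste(format(p), collapse = ","),
                  character(1))
  cat(sprintf("Objective: %s (%s)%s\n", object@family, object@direction,
              if (length(extra)) paste0(" [",
                paste(names(extra), extra, sep = "=", collapse = "; "), "]")
              else ""))
})

#' Sum squared error to a target composition
#'
#' @param p achieved relative abundance vector.
#' @param target target abundances (same length).
#' @return `sum((p - target)^2)`, uniquely minimized at `p == target`.
#' @examples
#' sseToTarget(c(1, 0, 0), c(0.9, 0.05, 0.05))   # 0.015
#' @export
sseToTarget <- function(p, target) {
  if (length(p) != length(target))
    stop("abundance and target vectors differ in length")
  sum((p - target)^2)
}

# Raw objective value for a summary (sign as the family defines it).
rawObjective <- function(objective, summary) {
  prm <- objective@params
  switch(objective@family,
    entropy = summary@entropy,
    organism_abundance = {
      if (!prm$organism %in% summary@organisms)
        stop(sprintf("unknown organism '%s'", prm$organism))
      unname(summary@abundances[[prm$organism]])
    },
    total_exchanges = as.numeric(summary@nExchanges),
    flux_to_organism = {
      if (!prm$organism %in% summary@organisms)
        stop(sprintf("unknown organism '%s'", prm$organism))
      unname(summary@fluxTo[[prm$organism]])
    },
    metabolite_secretion = secretionTotal(summary@secretionTotals, prm$metabolite),
    target_composition = {
      t <- prm$target
      p <- if (!is.null(names(t))) summary@abundances[names(t)]
           else summary@abundances
      sseToTarget(as.numeric(p), as.numeric(t))
    })
}

#' Score a phenotype under an objective
#'
#' @param objective an [Objective-class].
#' @param summary a [PhenotypeSummary-class].
#' @return named numeric `c(raw = , fitness = )`: the raw family value, and
#'   the always-maximize fitness (raw negated for minimize objectives).
#' @export
scoreSummary <- function(objective, summary) {
  raw <- rawObjective(objective, summary)
  fit <- if (objective@direction == "minimize") -raw else raw
  c(raw = raw, fitness = fit)
}
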