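#' @include community.R metrics.R medium.R
NULL

#' Simulation configuration
#'
#' Parameters of the explicit-Euler consumer-resource integration. Defaults
#' follow the benchmark growth setting: 24 h at a 0.01 h timestep with a
#' first-order death rate of 0.1 h^-1. The exploratory target-composition
#' setting uses `deathRate = 0` and a 1e-6 gDW inoculum per organism.
#'
#' @slot duration hours.
#' @slot timestep hours per Euler step.
#' @slot deathRate first-order biomass decay, h^-1 (may be 0).
#' @slot inoculumPerOrganism starting biomass per organism, gDW.
#' @slot volumeUl culture volume in microlitres (converts amounts to
#'   concentrations for Monod terms).
#' @slot carbonPerGDW mmol of carbon per gDW of biomass, used only for the
#'   carbon-conservation audit.
#' @name SimulationConfig-class
#' @exportClass SimulationConfig
setClass("SimulationConfig", representation(
  duration = "numeric", timestep = "numeric", deathRate = "numeric",
  inoculumPerOrganism = "numeric", volumeUl = "numeric",
  carbonPerGDW = "numeric"))

setValidity("SimulationConfig", function(object) {
  if (object@duration <= 0) return("duration must be positive")
  if (object@timestep <= 0 || object@timestep > object@duration)
    return("timestep must satisfy 0 < timestep <= duration")
  if (object@deathRate < 0) return("deathRate must be >= 0")
  if (object@inoculumPerOrganism <= 0) return("inoculum must be positive")
  TRUE
})

#' @rdname SimulationConfig-class
#' @param duration,timestep,deathRate,inoculumPerOrganism,volumeUl,carbonPerGDW
#'   see slots.
#' @export
SimulationConfig <- function(duration = 24, timestep = 0.01, deathRate = 0.1,
                             inoculumPerOrganism = 3.45e-7, volumeUl = 400,
                             carbonPerGDW = 40) {
  new("SimulationConfig", duration = duration, timestep = timestep,
      deathRate = deathRate, inoculumPerOrganism = inoculumPerOrganism,
      volumeUl = volumeUl, carbonPerGDW = carbonPerGDW)
}

setMethod("show", "SimulationConfig", function(object) {
  cat(sprintf(
    "SimulationConfig: %g h at dt=%g h, death %g/h, inoculum %g gDW/organism\n",
    object@duration, object@timestep, object@deathRate,
    object@inoculumPerOrganism))
})

#' Simulation results
#'
#' Full trajectories and accounting from one community simulation:
#' biomass and metabolite time series, the net exchange records, per-organism
#' secretion totals and the carbon audit.
#'
#' @slot organisms,metabolites,times dimension labels.
#' @slot biomassTraj organisms x timepoints matrix, gDW.
#' @slot metaboliteTraj metabolites x timepoints matrix, mmol.
#' @slot exchanges `data.frame` donor/receiver/metabolite/amount_mmol (net
#'   over the run, donor != receiver, positive amounts only).
#' @slot secretionByOrganism organisms x byproducts matrix of cumulative
#'   secretion, mmol.
#' @slot carbonAudit named numeric: carbon (mmol C) in biomass, medium,
#'   byproducts, removed by death and respired, at the final timepoint.
#' @slot config the [SimulationConfig-class] used.
#' @name SimulationResult-class
#' @exportClass SimulationResult
setClass("SimulationResult", representation(
  organisms = "character", metabolites = "character", times = "numeric",
  biomassTraj = "matrix", metaboliteTraj = "matrix", exchanges = "data.frame",
  secretionByOrganism = "matrix", carbonAudit = "numeric",
  config = "SimulationConfig"))

setMethod("show", "SimulationResult", function(object) {
  fb <- finalBiomass(object)
  cat(sprintf(
    "SimulationResult: %d organisms over %g h; total final biomass %.3g gDW; %d exchange routes\n",
    length(object@organisms), max(object@times), sum(fb), nrow(object@exchanges)))
})

#' @describeIn SimulationResult Final per-organism biomass (named, gDW).
#' @param result a [SimulationResult-class].
#' @export
finalBiomass <- function(result)
  setNames(result@biomassTraj[, ncol(result@biomassTraj)], result@organisms)

#' Inoculum arithmetic
#'
#' Converts an optical-density-calibrated cell count and per-cell dry mass
#' into total and per-organism inoculum biomass. The defaults correspond to
#' OD600 0.05 in 400 ul: 1.6e7 cells at 2.8e-13 gDW per cell, split equally
#' over 13 organisms (4.48e-6 gDW total, 3.45e-7 gDW each).
#'
#' @param cells_at_od cell count at the working optical density and volume.
#' @param cell_mass gDW per cell.
#' @param n_organisms number of organisms sharing the inoculum equally.
#' @return list with `total` and `per_organism` (gDW).
#' @export
inoculumAmounts <- function(cells_at_od = 1.6e7, cell_mass = 2.8e-13,
                            n_organisms = 13) {
  if (n_organisms < 1) stop("n_organisms must be >= 1")
  total <- cells_at_od * cell_mass
  list(total = total, per_organism = total / n_organisms)
}

#' Growth-cessation test
#'
#' An organism is deemed to have stopped growing when its growth-curve
#' derivative was positive at least once during the run (it grew at all) and
#' is at or below zero at the end. Forward differences with a small zero
#' tolerance stand in for the derivative. Organisms that never grew fail the
#' first clause and return `FALSE`; callers interested in them should test
#' `everGrew` separately.
#'
#' @param trajectory numeric biomass time series (>= 2 points).
#' @param tol absolute per-step change treated as zero (gDW).
#' @return logical.
#' @export
growthStopped <- function(trajectory, tol = 1e-12) {
  if (length(trajectory) < 2L) stop("trajectory needs at least 2 points")
  d <- diff(trajectory)
  any(d > tol) && d[length(d)] <= tol
}

#' @rdname growthStopped
#' @export
everGrew <- function(trajectory, tol = 1e-12) any(diff(trajectory) > tol)

# Presence tolerance for the auxotrophy gate (mmol).
.cofactorTol <- 1e-12

#' Simulate community growth in one environment
#'
#' Explicit-Euler integration of a Monod consumer-resource model with
#' cross-feeding. Per step, each ungated organism demands substrate at
#' `vmax * B * s/(Km + s) * dt`; when total demand exceeds availability all
#' consumers are rationed proportionally, so amounts never go negative.
#' Consumed carbon splits into biomass (via the yield) and secreted byproducts
#' (via the secretion fractions); any remainder is booked as respired. An
#' organism with a missing required cofactor neither grows nor takes anything
#' up. Death removes biomass at `deathRate` per hour. Byproduct absorption is
#' attributed to donor organisms in proportion to their cumulative secretion
#' of that metabolite up to the previous step; self-transfers are not counted
#' as exchanges. The integration is deterministic: identical inputs give
#' identical results.
#'
#' @param community a [CommunityModel-class].
#' @param medium named numeric of initial nutrient amounts (mmol), as from
#'   [buildMedium()].
#' @param config a [SimulationConfig-class].
#' @return a [SimulationResult-class].
#' @export
simulateCommunity <- function(community, medium, config = SimulationConfig()) {
  orgs <- community@organisms
  orgIds <- organismIds(community)
  nOrg <- length(orgs)
  prodIds <- names(community@byproducts)

  unknown <- setdiff(names(medium), nutrientIds(community@pool))
  if (length(unknown))
    stop("medium contains nutrients not in the community's pool: ",
         paste(unknown, collapse = ", "))

  # State metabolites: the supplied nutrients plus every byproduct.
  metIds <- c(names(medium), prodIds)
  nMet <- length(metIds)
  atoms <- c(carbonAtoms(community@pool, names(medium)), community@byproducts)

  # Kinetic matrices over organisms x state metabolites. Substrates an
  # organism consumes but that are absent from this environment simply never
  # appear in the state and are ignored.
  Vmax <- matrix(0, nOrg, nMet, dimnames = list(orgIds, metIds))
  Km <- matrix(1, nOrg, nMet)
  Yield <- matrix(0, nOrg, nMet)
  Frac <- lapply(prodIds, function(p) matrix(0, nOrg, nMet))
  names(Frac) <- prodIds
  cofactorIdx <- vector("list", nOrg)
  for (i in seq_len(nOrg)) {
    o <- orgs[[i]]
    here <- o@uptake$substrate %in% metIds
    if (any(here)) {
      j <- match(o@uptake$substrate[here], metIds)
      Vmax[i, j] <- o@uptake$vmax[here]
      Km[i, j] <- o@uptake$km[here]
      y <- o@yield[o@uptake$substrate[here]]
      y[is.na(y)] <- 0
      Yield[i, j] <- y
    }
    if (nrow(o@secretion)) {
      for (r in seq_len(nrow(o@secretion))) {
        s <- o@secretion$substrate[r]
        if (s %in% metIds)
          Frac[[o@secretion$product[r]]][i, match(s, metIds)] <-
            o@secretion$fraction[r]
      }
    }
    cofactorIdx[[i]] <- match(o@requiredCofactors, metIds) # NA = never present
  }
  prodPos <- match(prodIds, metIds)

  nSteps <- round(config@duration / config@timestep)
  dt <- config@timestep
  volL <- config@volumeUl * 1e-6
  gamma <- config@carbonPerGDW

  B <- rep(config@inoculumPerOrganism, nOrg)
  M <- as.numeric(c(medium, setNames(rep(0, length(prodIds)), prodIds)))
  biomassTraj <- matrix(NA_real_, nOrg, nSteps + 1L,
                        dimnames = list(orgIds, NULL))
  metTraj <- matrix(NA_real_, nMet, nSteps + 1L, dimnames = list(metIds, NULL))
  biomassTraj[, 1L] <- B
  metTraj[, 1L] <- M

  cumSec <- matrix(0, nOrg, length(prodIds), dimnames = list(orgIds, prodIds))
  exch <- if (length(prodIds))
    array(0, dim = c(nOrg, nOrg, length(prodIds)),
          dimnames = list(orgIds, orgIds, prodIds)) else NULL
  deathC <- 0
  respC <- 0
  deathRate <- config@deathRate

  gated <- which(lengths(cofactorIdx) > 0L)
  neverGrows <- gated[vapply(cofactorIdx[gated], anyNA, logical(1))]
  gate <- rep(1, nOrg)
  gate[neverGrows] <- 0
  checkGate <- setdiff(gated, neverGrows)

  for (step in seq_len(nSteps)) {
    # Auxotrophy gate: all required cofactors present above tolerance.
    for (i in checkGate)
      gate[i] <- if (all(M[cofactorIdx[[i]]] > .cofactorTol)) 1 else 0

    conc <- M / volL                       # mM
    concM <- matrix(conc, nOrg, nMet, byrow = TRUE)
    monod <- concM / (Km + concM)
    demand <- Vmax * monod * (B * gate) * dt
    totDemand <- colSums(demand)
    scale <- ifelse(totDemand > M & totDemand > 0, M / totDemand, 1)
    U <- sweep(demand, 2, scale, "*")      # realized uptake, mmol

    carbonUptake <- sweep(U, 2, atoms, "*")
    growth <- rowSums(U * Yield)

    # Secretion: carbon fraction of each consumed substrate, converted to
    # mmol of the product.
    secretedC <- 0
    if (length(prodIds)) {
      secByOrg <- matrix(0, nOrg, length(prodIds))
      for (pi in seq_along(prodIds)) {
        cFlux <- rowSums(carbonUptake * Frac[[prodIds[pi]]])
        secByOrg[, pi] <- cFlux / atoms[prodPos[pi]]
        secretedC <- secretedC + sum(cFlux)
      }
      # Attribute byproduct absorption to donors by cumulative secretion.
      for (pi in seq_along(prodIds)) {
        taken <- U[, prodPos[pi]]
        if (any(taken > 0)) {
          donorTotal <- sum(cumSec[, pi])
          if (donorTotal > 0) {
            w <- cumSec[, pi] / donorTotal
            exch[, , pi] <- exch[, , pi] + outer(w, taken)
          }
        }
      }
      cumSec <- cumSec + secByOrg
    }

    death <- deathRate * B * dt
    deathC <- deathC + sum(death) * gamma
    respC <- respC + sum(carbonUptake) - sum(growth) * gamma - secretedC

    M <- M - colSums(U)
    if (any(M < -1e-9)) stop("internal error: negative metabolite amount")
    M[M < 0] <- 0
    if (length(prodIds)) M[prodPos] <- M[prodPos] + colSums(secByOrg)
    B <- B + growth - death

    biomassTraj[, step + 1L] <- B
    metTraj[, step + 1L] <- M
  }

  records <- emptyExchangeFrame()
  if (length(prodIds)) {
    hit <- which(exch > 1e-15, arr.ind = TRUE)
    if (nrow(hit)) {
      keep <- hit[, 1] != hit[, 2]        # self-transfers are not exchanges
      hit <- hit[keep, , drop = FALSE]
      if (nrow(hit))
        records <- data.frame(
          donor = orgIds[hit[, 1]], receiver = orgIds[hit[, 2]],
          metabolite = prodIds[hit[, 3]],
          amount_mmol = exch[hit], stringsAsFactors = FALSE)
    }
  }

  audit <- c(
    biomass = sum(B) * gamma,
    medium = sum(M[setdiff(seq_len(nMet), prodPos)] *
                   atoms[setdiff(seq_len(nMet), prodPos)]),
    byproducts = if (length(prodIds)) sum(M[prodPos] * atoms[prodPos]) else 0,
    death = deathC, respired = respC)

  new("SimulationResult", organisms = orgIds, metabolites = metIds,
      times = seq(0, by = dt, length.out = nSteps + 1L),
      biomassTraj = biomassTraj, metaboliteTraj = metTraj,
      exchanges = records, secretionByOrganism = cumSec,
      carbonAudit = audit, config = config)
}

#' Summarize a simulation into a PhenotypeSummary
#'
#' @param result a [SimulationResult-class].
#' @param presenceThreshold see [speciesRichness()].
#' @return a [PhenotypeSummary-class].
#' @export
summarizePhenotype <- function(result, presenceThreshold = 0) {
  sec <- colSums(result@secretionByOrganism)
  if (is.null(names(sec))) sec <- setNames(numeric(0), character(0))
  PhenotypeSummary(finalBiomass(result), exchanges = result@exchanges,
                   secretionTotals = sec,
                   presenceThreshold = presenceThreshold)
}
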