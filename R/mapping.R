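#' @include simulate.R env-space.R
NULL

#' Generate an exhaustive environment-phenotype mapping
#'
#' Simulates the community in every environment of an enumerable space and
#' collects the results into a `SummarizedExperiment`: organisms as rows,
#' environments (in canonical order) as columns, with `biomass`, `abundance`
#' and `fluxTo` assays, per-environment summary statistics in `colData`
#' (richness, Shannon entropy, exchange counts, growth-cessation counts) and
#' the secretion matrix plus full exchange records in `metadata`. Such
#' mappings provide the known optimum against which search performance is
#' benchmarked.
#'
#' @param community a [CommunityModel-class].
#' @param space an enumerable [EnvironmentSpace-class] over the same pool.
#' @param mediumSpec a [MediumSpec-class].
#' @param config a [SimulationConfig-class].
#' @param presenceThreshold see [speciesRichness()].
#' @param cap enumeration guard, as in [enumerateEnvironments()].
#' @return a [SummarizedExperiment::SummarizedExperiment].
#' @export
generateMapping <- function(community, space, mediumSpec = MediumSpec(),
                            config = SimulationConfig(),
                            presenceThreshold = 0, cap = 100000) {
  envs <- enumerateEnvironments(space, cap = cap)
  orgIds <- organismIds(community)
  mets <- names(community@byproducts)
  nEnv <- length(envs)
  biomass <- matrix(0, length(orgIds), nEnv, dimnames = list(orgIds, NULL))
  abundance <- biomass
  fluxTo <- biomass
  secretion <- matrix(0, length(mets), nEnv, dimnames = list(mets, NULL))
  cd <- data.frame(
    env_id = vapply(envs, environmentId, character(1)),
    nutrients = vapply(envs, paste, character(1), collapse = ";"),
    size = lengths(envs), richness = integer(nEnv), entropy = numeric(nEnv),
    n_exchanges = integer(nEnv), n_exchanges_unordered = integer(nEnv),
    total_biomass = numeric(nEnv), n_stopped_growing = integer(nEnv),
    n_never_grew = integer(nEnv), stringsAsFactors = FALSE)
  exchangeList <- vector("list", nEnv)

  for (j in seq_len(nEnv)) {
    medium <- buildMedium(envs[[j]], mediumSpec, community@pool)
    res <- simulateCommunity(community, medium, config)
    s <- summarizePhenotype(res, presenceThreshold)
    biomass[, j] <- s@finalBiomass
    abundance[, j] <- s@abundances
    fluxTo[, j] <- s@fluxTo
    if (length(mets)) secretion[, j] <- s@secretionTotals[mets]
    cd$richness[j] <- s@richness
    cd$entropy[j] <- s@entropy
    cd$n_exchanges[j] <- s@nExchanges
    cd$n_exchanges_unordered[j] <- countExchanges(s@exchanges, directed = FALSE)
    cd$total_biomass[j] <- sum(s@finalBiomass)
    stopped <- apply(res@biomassTraj, 1, growthStopped)
    grew <- apply(res@biomassTraj, 1, everGrew)
    cd$n_stopped_growing[j] <- sum(stopped)
    cd$n_never_grew[j] <- sum(!grew)
    exchangeList[[j]] <- s@exchanges
  }
  names(exchangeList) <- cd$env_id
  colnames(secretion) <- cd$env_id
  se <- SummarizedExperiment(
    assays = list(biomass = biomass, abundance = abundance, fluxTo = fluxTo),
    colData = S4Vectors::DataFrame(cd),
    metadata = list(secretion = secretion, exchanges = exchangeList,
                    pool = community@pool@nutrients,
                    presenceThreshold = presenceThreshold))
  colnames(se) <- cd$env_id
  se
}

#' Rebuild PhenotypeSummary objects from a mapping
#'
#' @param mapping a mapping `SummarizedExperiment` from [generateMapping()]
#'   or [readMapping()].
#' @return named list of [PhenotypeSummary-class], keyed by `env_id`.
#' @export
mappingSummaries <- function(mapping) {
  cd <- as.data.frame(colData(mapping))
  biomass <- assay(mapping, "biomass")
  fluxTo <- assay(mapping, "fluxTo")
  secretion <- metadata(mapping)$secretion
  exchanges <- metadata(mapping)$exchanges
  thr <- metadata(mapping)$presenceThreshold
  if (is.null(thr)) thr <- 0
  out <- vector("list", ncol(mapping))
  for (j in seq_len(ncol(mapping))) {
    rec <- if (!is.null(exchanges)) exchanges[[cd$env_id[j]]] else NULL
    if (is.null(rec)) rec <- emptyExchangeFrame()
    out[[j]] <- PhenotypeSummary(
      setNames(biomass[, j], rownames(biomass)), exchanges = rec,
      secretionTotals = if (!is.null(secretion) && nrow(secretion))
        setNames(secretion[, j], rownames(secretion)) else numeric(0),
      presenceThreshold = thr,
      nExchanges = cd$n_exchanges[j],
      fluxTo = setNames(fluxTo[, j], rownames(fluxTo)))
  }
  names(out) <- cd$env_id
  out
}

#' Write / read a mapping to CSV
#'
#' The main CSV has columns `env_id`, `nutrients` (semicolon-joined),
#' per-organism final biomass (`biomass_<org>`) and relative abundance
#' (`abundance_<org>`), `richness`, `entropy`, `n_exchanges`, plus
#' per-organism directed-flux (`fluxto_<org>`) and per-metabolite secretion
#' (`secretion_<met>`) columns so that every objective family can be scored
#' from the file alone. Exchange records go to a companion CSV with columns
#' `env_id,donor,receiver,metabolite,amount_mmol`. Write-then-read
#' round-trips all quantities.
#'
#' @param mapping a mapping `SummarizedExperiment`.
#' @param file main CSV path.
#' @param exchanges_file optional companion CSV path for exchange records.
#' @return `file`, invisibly.
#' @export
writeMapping <- function(mapping, file, exchanges_file = NULL) {
  cd <- as.data.frame(colData(mapping))
  biomass <- t(assay(mapping, "biomass"))
  abundance <- t(assay(mapping, "abundance"))
  fluxTo <- t(assay(mapping, "fluxTo"))
  colnames(biomass) <- paste0("biomass_", colnames(biomass))
  colnames(abundance) <- paste0("abundance_", colnames(abundance))
  colnames(fluxTo) <- paste0("fluxto_", colnames(fluxTo))
  tab <- cbind(cd[c("env_id", "nutrients")], biomass, abundance,
               cd[c("richness", "entropy", "n_exchanges",
                    "n_exchanges_unordered", "total_biomass")], fluxTo)
  secretion <- metadata(mapping)$secretion
  if (!is.null(secretion) && nrow(secretion)) {
    sec <- t(secretion)
    colnames(sec) <- paste0("secretion_", colnames(sec))
    tab <- cbind(tab, sec)
  }
  write.csv(tab, file, row.names = FALSE)
  if (!is.null(exchanges_file)) {
    ex <- metadata(mapping)$exchanges
    recs <- do.call(rbind, lapply(names(ex), function(id) {
      if (nrow(ex[[id]]) == 0L) return(NULL)
      cbind(env_id = id, ex[[id]])
    }))
    if (is.null(recs))
      recs <- cbind(env_id = character(0), emptyExchangeFrame())
    write.csv(recs, exchanges_file, row.names = FALSE)
  }
  invisible(file)
}

#' @rdname writeMapping
#' @export
readMapping <- function(file, exchanges_file = NULL) {
  tab <- read.csv(file, stringsAsFactors = FALSE)
  tab$nutrients[is.na(tab$nutrients)] <- ""
  pick <- function(prefix) {
    cols <- grep(paste0("^", prefix, "_"), names(tab), value = TRUE)
    m <- t(as.matrix(tab[cols]))
    rownames(m) <- sub(paste0("^", prefix, "_"), "", cols)
    colnames(m) <- tab$env_id
    m
  }
  biomass <- pick("biomass"); abundance <- pick("abundance")
  fluxTo <- pick("fluxto"); secretion <- pick("secretion")
  exchanges <- NULL
  if (!is.null(exchanges_file)) {
    recs <- read.csv(exchanges_file, stringsAsFactors = FALSE)
    exchanges <- lapply(tab$env_id, function(id) {
      sub <- recs[recs$env_id == id, c("donor", "receiver", "metabolite",
                                       "amount_mmol")]
      rownames(sub) <- NULL
      sub
    })
    names(exchanges) <- tab$env_id
  }
  cdCols <- c("env_id", "nutrients", "richness", "entropy", "n_exchanges",
              "n_exchanges_unordered", "total_biomass")
  cd <- tab[intersect(cdCols, names(tab))]
  cd$size <- ifelse(cd$nutrients == "", 0L,
                    lengths(strsplit(cd$nutrients, ";", fixed = TRUE)))
  se <- SummarizedExperiment(
    assays = list(biomass = biomass, abundance = abundance, fluxTo = fluxTo),
    colData = S4Vectors::DataFrame(cd),
    metadata = list(secretion = secretion, exchanges = exchanges,
                    presenceThreshold = 0))
  colnames(se) <- cd$env_id
  se
}
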