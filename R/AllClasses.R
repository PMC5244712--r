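#' @import methods
#' @importClassesFrom Matrix dgCMatrix
NULL

.REACTION_CATEGORIES <- c("biomass", "macromolecule", "exchange",
                          "transport", "metabolic")

#' Genome-scale metabolic model
#'
#' An S4 container for a constraint-based metabolic model: a metabolite
#' table (with chemical formula and charge for balance checking), a
#' reaction table (bounds in mmol/gDW/h, gene-protein-reaction rules,
#' functional category and evidence confidence) and the sparse
#' stoichiometric matrix \eqn{S} (metabolites x reactions).  The +/-1000
#' flux-bound sentinel is stored literally, never replaced by infinity, so
#' model files round-trip unchanged.
#'
#' @slot metabolites data.frame with columns \code{id}, \code{name},
#'   \code{formula} (Hill string, \code{NA} if unknown, \code{""} if
#'   massless), \code{charge}, \code{compartment}.
#' @slot reactions data.frame with columns \code{id}, \code{name},
#'   \code{lower}, \code{upper}, \code{gpr}, \code{category} (one of
#'   biomass, macromolecule, exchange, transport, metabolic),
#'   \code{confidence} (1, 2 or 4, or \code{NA}).
#' @slot S \linkS4class{dgCMatrix}, rows follow \code{metabolites$id},
#'   columns follow \code{reactions$id}.
#' @slot genes character vector of gene identifiers; every gene must be
#'   referenced by at least one GPR.
#'
#' @seealso [MetabolicModel()] for construction, [readModelTable()],
#'   [readSBMLModel()] for import.
#' @export
setClass("MetabolicModel",
  slots = c(metabolites = "data.frame", reactions = "data.frame",
            S = "dgCMatrix", genes = "character"))

setValidity("MetabolicModel", function(object) {
  met <- object@metabolites; rxn <- object@reactions; S <- object@S
  msg <- character(0)
  needM <- c("id", "name", "formula", "charge", "compartment")
  needR <- c("id", "name", "lower", "upper", "gpr", "category", "confidence")
  if (!all(needM %in% names(met)))
    return(paste("metabolite table lacks columns:",
                 paste(setdiff(needM, names(met)), collapse = ", ")))
  if (!all(needR %in% names(rxn)))
    return(paste("reaction table lacks columns:",
                 paste(setdiff(needR, names(rxn)), collapse = ", ")))
  if (anyDuplicated(met$id)) msg <- c(msg, "duplicate metabolite ids")
  if (anyDuplicated(rxn$id)) msg <- c(msg, "duplicate reaction ids")
  if (!identical(dim(S), c(nrow(met), nrow(rxn))))
    msg <- c(msg, "S dimensions do not match metabolite/reaction tables")
  if (any(rxn$lower > rxn$upper + 1e-12))
    msg <- c(msg, "reaction with lower bound above upper bound")
  if (!all(rxn$category %in% .REACTION_CATEGORIES))
    msg <- c(msg, paste("invalid reaction category; must be one of",
                        paste(.REACTION_CATEGORIES, collapse = ", ")))
  conf <- rxn$confidence[!is.na(rxn$confidence)]
  if (!all(conf %in% c(1, 2, 4)))
    msg <- c(msg, "confidence must be 1, 2 or 4")
  ex <- which(rxn$category == "exchange")
  if (length(ex)) {
    touched <- Matrix::colSums(S[, ex, drop = FALSE] != 0)
    if (any(touched != 1))
      msg <- c(msg, paste("exchange reaction touching != 1 metabolite:",
                          paste(rxn$id[ex][touched != 1], collapse = ", ")))
  }
  used <- unique(unlist(lapply(rxn$gpr, gprGenes)))
  if (length(setdiff(object@genes, used)))
    msg <- c(msg, paste("gene(s) not referenced by any GPR:",
                        paste(setdiff(object@genes, used), collapse = ", ")))
  if (length(setdiff(used, object@genes)))
    msg <- c(msg, paste("GPR references undeclared gene(s):",
                        paste(setdiff(used, object@genes), collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' Steady-state flux solution
#'
#' Result of one flux balance optimization: the flux vector \eqn{v}
#' (mmol/gDW/h; h^-1 for the biomass reaction), the objective value and
#' the solver status.  Accepted solutions satisfy \eqn{\|S v\|_\infty}
#' within solver tolerance.
#'
#' @slot fluxes named numeric flux vector (empty when not optimal).
#' @slot objectiveValue objective at the optimum (\code{NA} otherwise).
#' @slot objectiveReaction id of the objective reaction.
#' @slot status one of \code{"optimal"}, \code{"infeasible"},
#'   \code{"unbounded"}.
#' @export
setClass("FluxSolution",
  slots = c(fluxes = "numeric", objectiveValue = "numeric",
            objectiveReaction = "character", status = "character"))

setValidity("FluxSolution", function(object) {
  if (!object@status %in% c("optimal", "infeasible", "unbounded"))
    return("status must be optimal, infeasible or unbounded")
  TRUE
})

#' Cell-type constraint set
#'
#' The bound overrides that turn the shared metabolic model into a
#' diazotroph or photoautotroph submodel: the carbon source and its uptake
#' cap, the fixed nitrogenase flux, the photosystem II bound, the shared
#' 80 uE photon budget, non-growth maintenance ATP, and the exchange-id
#' sets for allowed uptakes, allowed exports, seawater nutrients
#' (uptake-only) and freely exchanged species (water, protons).
#'
#' @slot name \code{"diazotroph"} or \code{"photoautotroph"}.
#' @slot carbonUptake carbon uptake in mmol C/gDW/h (carrier: glycogen for
#'   the diazotroph, CO2 for the photoautotroph).
#' @slot nitrogenaseFlux fixed nitrogenase flux, mmol/gDW/h.
#' @slot psiiUpper upper bound on photosystem II flux (0 disables PSII).
#' @slot photonBudget total photon uptake cap shared by PSI and PSII (uE).
#' @slot maintenanceAtp lower bound on the ATP-hydrolysis maintenance
#'   reaction, mmol ATP/gDW/h.
#' @slot uptakes,exports,seawater,free exchange reaction ids.
#' @slot relaxed logical; \code{TRUE} releases the fixed carbon/nitrogenase
#'   rates to inequality bounds and opens the partner-supplied substrate
#'   (the nutrient-unlimited variant used for independent optima and dFBA).
#' @slot ids named list mapping the roles \code{photon}, \code{psii},
#'   \code{nitrogenase}, \code{maintenance}, \code{carbonExchange},
#'   \code{glycogenExchange}, \code{nh4Exchange}, \code{biomass} to
#'   reaction ids in the model.
#' @export
setClass("CellTypeConstraints",
  slots = c(name = "character", carbonUptake = "numeric",
            nitrogenaseFlux = "numeric", psiiUpper = "numeric",
            photonBudget = "numeric", maintenanceAtp = "numeric",
            uptakes = "character", exports = "character",
            seawater = "character", free = "character",
            relaxed = "logical", ids = "list"))

setValidity("CellTypeConstraints", function(object) {
  msg <- character(0)
  if (!object@name %in% c("diazotroph", "photoautotroph"))
    return("name must be 'diazotroph' or 'photoautotroph'")
  if (!object@relaxed) {
    if (object@name == "diazotroph" &&
        !(object@psiiUpper == 0 && object@nitrogenaseFlux > 0))
      msg <- c(msg, "diazotroph requires psiiUpper == 0 and fixed nitrogenase > 0")
    if (object@name == "photoautotroph" && object@nitrogenaseFlux != 0)
      msg <- c(msg, "photoautotroph requires nitrogenase flux 0")
  }
  if (object@photonBudget < 0) msg <- c(msg, "photon budget must be >= 0")
  need <- c("photon", "psii", "nitrogenase", "maintenance",
            "carbonExchange", "glycogenExchange", "nh4Exchange", "biomass")
  if (!all(need %in% names(object@ids)))
    msg <- c(msg, paste("ids must name:", paste(need, collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' Two-phenotype population simulation trace
#'
#' Ordered record of a population dynamic-FBA run: per-step biomasses,
#' medium concentrations, per-step growth rates, exchange fluxes and the
#' differentiation-allocation bookkeeping, plus the terminal status.
#'
#' @slot states data.frame with one row per time step (columns \code{t},
#'   \code{X_DZ}, \code{X_PA}, \code{f_DZ}, \code{C_glycogen},
#'   \code{C_NH4}, \code{mu_t}, exchange fluxes, failure flag).
#' @slot allocations data.frame of per-step allocation records
#'   (deficient metabolite, alpha, X_delta, recipient).
#' @slot status \code{"completed"} or \code{"died"}.
#' @slot params list of run settings (dt, horizon, grace, inoculum, seeds).
#' @export
setClass("PopulationTrace",
  slots = c(states = "data.frame", allocations = "data.frame",
            status = "character", params = "list"))

setValidity("PopulationTrace", function(object) {
  st <- object@states
  if (!object@status %in% c("completed", "died"))
    return("status must be 'completed' or 'died'")
  if (nrow(st) > 1 && any(diff(st$t) <= 0))
    return("time must be strictly increasing")
  TRUE
})
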