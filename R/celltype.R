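#' Construct a cell-type constraint set
#'
#' Defaults follow the published physiological constraints for
#' \emph{T. erythraeum}: carbon uptake 0.927 mmol C/gDW/h (glycogen for
#' the diazotroph, CO2 for the photoautotroph), nitrogenase flux fixed at
#' 0.132 mmol/gDW/h in the diazotroph (an alternative printed value of
#' 0.206 can be selected explicitly) and zero in the photoautotroph, PSII
#' disabled in the diazotroph, a shared 80 uE photon budget, and
#' calibrated maintenance demands of 64.3 (photoautotroph) and 67.2
#' (diazotroph) mmol ATP/gDW/h.
#'
#' @param name \code{"diazotroph"} or \code{"photoautotroph"}.
#' @param ids named list of role -> reaction id (\code{photon},
#'   \code{psii}, \code{nitrogenase}, \code{maintenance},
#'   \code{carbonExchange}, \code{glycogenExchange}, \code{nh4Exchange},
#'   \code{biomass}).
#' @param carbonUptake,nitrogenaseFlux,psiiUpper,photonBudget,maintenanceAtp
#'   numeric overrides of the defaults above.
#' @param uptakes,exports,seawater,free exchange-id sets: allowed uptakes
#'   (\code{[-1000, 0]}), allowed exports (\code{[0, 1000]}), seawater
#'   nutrients (uptake-only) and freely exchanged species.
#' @param relaxed start in the nutrient-unlimited variant.
#' @return a \linkS4class{CellTypeConstraints}.
#' @seealso [applyCellType()], [unconstrainedVariant()]
#' @export
cellTypeConstraints <- function(name = c("diazotroph", "photoautotroph"),
                                ids,
                                carbonUptake = 0.927,
                                nitrogenaseFlux = if (name == "diazotroph")
                                  0.132 else 0,
                                psiiUpper = if (name == "diazotroph")
                                  0 else 1000,
                                photonBudget = 80,
                                maintenanceAtp = if (name == "diazotroph")
                                  67.2 else 64.3,
                                uptakes = character(0),
                                exports = character(0),
                                seawater = character(0),
                                free = character(0),
                                relaxed = FALSE) {
  name <- match.arg(name)
  force(nitrogenaseFlux); force(psiiUpper); force(maintenanceAtp)
  new("CellTypeConstraints", name = name, carbonUptake = carbonUptake,
      nitrogenaseFlux = nitrogenaseFlux, psiiUpper = psiiUpper,
      photonBudget = photonBudget, maintenanceAtp = maintenanceAtp,
      uptakes = uptakes, exports = exports, seawater = seawater,
      free = free, relaxed = relaxed, ids = ids)
}

#' Apply a cell-type constraint set to a model
#'
#' Produces the diazotroph or photoautotroph submodel by overriding
#' bounds on the shared network: seawater exchanges become uptake-only
#' \code{[-1000, 0]}; the allowed-uptake set opens to \code{[-1000, 0]}
#' and the allowed-export set to \code{[0, 1000]}; PSII is capped (zero
#' for the diazotroph); nitrogenase is pinned (to its measured rate in
#' the diazotroph, to zero in the photoautotroph); the designated carbon
#' source is constrained (CO2 pinned at -0.927 for the photoautotroph,
#' glycogen uptake capped at carbonUptake/6 glucose units for the
#' diazotroph); the photon exchange is capped at the shared budget so
#' PSI + PSII together can never exceed it; and the maintenance reaction
#' receives its ATP-hydrolysis lower bound.  In the relaxed variant the
#' carbon and nitrogenase pins become inequality bounds and the
#' partner-supplied substrate (glycogen or ammonium) opens fully.
#' The operation is idempotent.
#'
#' @param model a \linkS4class{MetabolicModel}.
#' @param constraints a \linkS4class{CellTypeConstraints}.
#' @return the constrained \linkS4class{MetabolicModel}.
#' @export
applyCellType <- function(model, constraints) {
  ct <- constraints
  ids <- ct@ids
  allIds <- unique(c(ct@uptakes, ct@exports, ct@seawater, ct@free,
                     unlist(ids, use.names = FALSE)))
  .rxnIndex(model, allIds)   # errors on any absent reaction
  m <- model
  if (length(ct@seawater)) bounds(m, ct@seawater) <- c(-1000, 0)
  if (length(ct@uptakes)) bounds(m, ct@uptakes) <- c(-1000, 0)
  if (length(ct@exports)) bounds(m, ct@exports) <- c(0, 1000)
  if (length(ct@free)) bounds(m, ct@free) <- c(-1000, 1000)
  bounds(m, ids$photon) <- c(-ct@photonBudget, 0)
  bounds(m, ids$psii) <- c(0, ct@psiiUpper)
  if (ct@name == "diazotroph") {
    bounds(m, ids$nitrogenase) <-
      if (ct@relaxed) c(0, 1000)
      else rep(ct@nitrogenaseFlux, 2)
    bounds(m, ids$glycogenExchange) <-
      if (ct@relaxed) c(-1000, 0) else c(-ct@carbonUptake / 6, 0)
  } else {
    bounds(m, ids$nitrogenase) <- c(0, 0)
    bounds(m, ids$carbonExchange) <-
      if (ct@relaxed) c(-1000, 0) else rep(-ct@carbonUptake, 2)
    if (ct@relaxed) bounds(m, ids$nh4Exchange) <- c(-1000, 0)
  }
  ub <- bounds(m, ids$maintenance)[1, "upper"]
  bounds(m, ids$maintenance) <- c(ct@maintenanceAtp,
                                  max(ub, ct@maintenanceAtp))
  m
}

#' Nutrient-unlimited variant of a constraint set
#'
#' Returns a copy of the constraint set with the partner-supplied
#' substrate (glycogen for the diazotroph, ammonium for the
#' photoautotroph) opened to unrestricted uptake and the fixed carbon /
#' nitrogenase rates released to inequality bounds.  Used to compute the
#' independent optima of each cell type and as the operating mode of the
#' population dynamic FBA, where uptake is limited by the partner's
#' actual production rather than by fixed laboratory rates.
#'
#' @param constraints a \linkS4class{CellTypeConstraints}.
#' @return a relaxed \linkS4class{CellTypeConstraints} (idempotent).
#' @export
unconstrainedVariant <- function(constraints) {
  constraints@relaxed <- TRUE
  constraints
}
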