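## Two-phenotype population dynamic FBA with deficiency-driven cell
## differentiation.  Each time step runs the photoautotroph first (it must
## supply the glycogen the diazotrophs drew in the previous step, scaled
## by a predictive growth factor), then the diazotroph (its glycogen
## uptake capped by the carbon the photoautotrophs actually fixed and by
## what the medium holds), integrates batch-reactor growth, and finally
## redistributes the step's biomass increment between the two cell types
## in proportion to any metabolite shortage.

#' Predictive glycogen supply requirement (photoautotroph step)
#'
#' The glycogen export the photoautotroph population must provide this
#' step: last step's diazotroph consumption scaled by the predictive
#' factor \eqn{(\mu^{DZ}\Delta t + 1)} and by the biomass ratio
#' \eqn{X^{DZ}/X^{PA}}.  Expressed per gDW of photoautotroph.
#'
#' @param prevGlyUptakeDZ previous-step diazotroph glycogen uptake flux
#'   (negative, mmol/gDW/h).
#' @param prevMuDZ previous-step diazotroph growth rate (h^-1).
#' @param X named biomass vector \code{c(DZ = , PA = )} (g DW/L).
#' @param dt step length (h).
#' @return required export flux, mmol/gDW(PA)/h (0 when nothing was
#'   consumed or there are no photoautotrophs).
#' @export
requiredGlycogenSupply <- function(prevGlyUptakeDZ, prevMuDZ, X, dt = 1) {
  if (is.null(prevGlyUptakeDZ) || X[["PA"]] <= 0) return(0)
  (max(prevMuDZ, 0) * dt + 1) * abs(min(prevGlyUptakeDZ, 0)) *
    X[["DZ"]] / X[["PA"]]
}

#' Predictive ammonium supply requirement (diazotroph step)
#'
#' The ammonium export the diazotroph population must provide this step:
#' the photoautotrophs' consumption at this time point scaled by the
#' predictive factor \eqn{(\mu^{PA}\Delta t + 1)} and by the biomass
#' ratio \eqn{X^{PA}/X^{DZ}} -- the nitrogen-side mirror of
#' [requiredGlycogenSupply()], implementing the bi-objective coupling in
#' which the diazotroph's role is to provision fixed nitrogen.
#'
#' @param vNH4PA photoautotroph ammonium exchange flux this step
#'   (negative = uptake, mmol/gDW/h).
#' @param muPA photoautotroph growth rate this step (h^-1).
#' @param X named biomass vector \code{c(DZ = , PA = )} (g DW/L).
#' @param dt step length (h).
#' @return required export flux, mmol/gDW(DZ)/h.
#' @export
requiredAmmoniumSupply <- function(vNH4PA, muPA, X, dt = 1) {
  if (X[["DZ"]] <= 0) return(0)
  (max(muPA, 0) * dt + 1) * abs(min(vNH4PA, 0)) * X[["PA"]] / X[["DZ"]]
}

#' Diazotroph glycogen uptake cap from photoautotroph carbon fixation
#'
#' Glycogen carries six carbons, so the diazotroph population may draw at
#' most one sixth of the photoautotrophs' CO2 uptake, scaled by the
#' diazotroph fraction: \eqn{|v| \le |v_{CO2}^{PA}| / (6 f_{DZ})}.
#'
#' @param vCO2PA photoautotroph CO2 exchange flux (negative = uptake).
#' @param fDZ diazotroph biomass fraction.
#' @return uptake cap in glucose-equivalent mmol/gDW(DZ)/h.
#' @export
glycogenUptakeCap <- function(vCO2PA, fDZ) {
  if (fDZ <= 0) return(0)
  abs(min(vCO2PA, 0)) / (6 * fDZ)
}

.zeroStep <- function(...) {
  base <- list(feasible = FALSE, mu = 0, v = NULL, vGly = 0, vCO2 = 0,
               vNH4 = 0, vN2 = 0, glyDemand = 0, nh4Demand = 0, muDemand = 0,
               required = 0, supplied = 0, warm = NULL)
  extra <- list(...)
  if (length(extra)) utils::modifyList(base, extra, keep.null = TRUE)
  else base
}

#' One photoautotroph time step
#'
#' Maximizes glycogen supply up to the predictive requirement, pins the
#' achieved supply as a floor, then maximizes growth.  When the full
#' requirement is not attainable the step supplies its best effort and
#' the shortfall surfaces as a glycogen deficiency in the allocation
#' stage.  An infeasible submodel is recorded as a zero-growth step
#' (which counts toward the death rule).
#'
#' @param paModel photoautotroph submodel (relaxed constraints applied).
#' @param ids role id list (see \linkS4class{CellTypeConstraints}).
#' @param X named biomass vector \code{c(DZ=, PA=)} (g DW/L).
#' @param C named medium vector \code{c(glycogen=, nh4=)} (mmol/L).
#' @param prev previous-step summary (\code{$vGlyDZ}, \code{$muDZ}) or
#'   \code{NULL} on the first step.
#' @param dt step length (h).
#' @param graceActive if \code{TRUE}, uptake is not limited by medium
#'   stocks (the grace-period cache) and no supply is forced.
#' @param warm optional LP warm start.
#' @param nh4Unlimited,glyUnlimited treat the ammonium (PA) or glycogen
#'   (DZ) medium pool as replete, ignoring availability caps
#'   (nutrient-excess scenarios).
#' @return list with \code{feasible}, \code{mu}, flux summaries
#'   (\code{vGly}, \code{vCO2}, \code{vNH4}), the replete-medium demand
#'   (\code{nh4Demand} / \code{glyDemand}), \code{required},
#'   \code{supplied} and \code{warm}.
#' @export
stepPhotoautotroph <- function(paModel, ids, X, C, prev = NULL, dt = 1,
                               graceActive = FALSE, warm = NULL,
                               nh4Unlimited = FALSE) {
  if (X[["PA"]] <= 0)
    return(.zeroStep(warm = warm))
  req <- if (is.null(prev)) 0
         else requiredGlycogenSupply(prev$vGlyDZ, prev$muDZ, X, dt)
  m <- paModel
  supplied <- 0
  if (req > 0) {
    ms <- m
    bounds(ms, ids$glycogenExchange) <- c(0, min(req, 1000))
    sup <- solveFBA(ms, ids$glycogenExchange, warm = warm)
    if (solutionStatus(sup) == "optimal") {
      supplied <- max(0, objectiveValue(sup))
      warm <- attr(sup, "warm")
    }
    bounds(m, ids$glycogenExchange) <- c(supplied, min(req, 1000))
  }
  ## demand solution: what the cells would draw were the medium replete
  sol <- solveFBA(m, ids$biomass, warm = warm)
  if (solutionStatus(sol) != "optimal")
    return(.zeroStep(required = req, warm = warm))
  warm <- attr(sol, "warm")
  nh4Demand <- abs(min(fluxes(sol)[[ids$nh4Exchange]], 0))
  muDemand <- max(0, objectiveValue(sol))
  if (!graceActive && !nh4Unlimited) {
    cap <- C[["nh4"]] / (X[["PA"]] * dt)
    if (cap < nh4Demand - 1e-12) {
      bounds(m, ids$nh4Exchange) <- c(-min(1000, cap), 0)
      solR <- solveFBA(m, ids$biomass, warm = warm)
      if (solutionStatus(solR) != "optimal")
        return(.zeroStep(nh4Demand = nh4Demand, required = req,
                         supplied = supplied, warm = warm))
      sol <- solR
      warm <- attr(solR, "warm")
    }
  }
  v <- fluxes(sol)
  list(feasible = TRUE, mu = max(0, objectiveValue(sol)), v = v,
       vGly = v[[ids$glycogenExchange]], vCO2 = v[[ids$carbonExchange]],
       vNH4 = v[[ids$nh4Exchange]], vN2 = 0, nh4Demand = nh4Demand,
       muDemand = muDemand, required = req, supplied = supplied,
       warm = warm)
}

#' One diazotroph time step
#'
#' Caps glycogen uptake by the photoautotrophs' fixed carbon
#' ([glycogenUptakeCap()]) and by what the medium plus this step's supply
#' hold; then maximizes ammonium export up to the community's predictive
#' requirement ([requiredAmmoniumSupply()]), pins the achieved supply as
#' a floor, and maximizes growth -- the bi-objective coupling in which
#' the photoautotroph grows while the diazotroph provisions fixed
#' nitrogen and grows with what remains.
#'
#' @inheritParams stepPhotoautotroph
#' @param dzModel diazotroph submodel (relaxed constraints applied).
#' @param paStep result of [stepPhotoautotroph()] for this time point.
#' @param fDZ current diazotroph biomass fraction.
#' @return list as in [stepPhotoautotroph()] with \code{vN2} (nitrogenase
#'   flux) included.
#' @export
stepDiazotroph <- function(dzModel, ids, X, C, paStep, fDZ, dt = 1,
                           graceActive = FALSE, warm = NULL,
                           glyUnlimited = FALSE) {
  if (X[["DZ"]] <= 0)
    return(.zeroStep(warm = warm))
  reqN <- requiredAmmoniumSupply(-paStep$nh4Demand, paStep$muDemand,
                                 X, dt)
  ## primary objective: provision the community's fixed-nitrogen demand
  ## (up to capacity), then grow with whatever remains
  runAt <- function(cap, warm) {
    m <- dzModel
    bounds(m, ids$glycogenExchange) <- c(-cap, 0)
    suppliedN <- 0
    if (reqN > 0) {
      ms <- m
      bounds(ms, ids$nh4Exchange) <- c(0, min(reqN, 1000))
      sup <- solveFBA(ms, ids$nh4Exchange, warm = warm)
      if (solutionStatus(sup) == "optimal") {
        suppliedN <- max(0, objectiveValue(sup))
        warm <- attr(sup, "warm")
      }
      bounds(m, ids$nh4Exchange) <- c(suppliedN, 1000)
    }
    sol <- solveFBA(m, ids$biomass, warm = warm)
    if (solutionStatus(sol) != "optimal")
      return(list(ok = FALSE, supplied = suppliedN, warm = warm))
    list(ok = TRUE, sol = sol, supplied = suppliedN,
         warm = attr(sol, "warm"))
  }
  capDemand <- if (glyUnlimited) 1000
               else min(glycogenUptakeCap(paStep$vCO2, fDZ), 1000)
  dem <- runAt(capDemand, warm)
  if (!dem$ok)
    return(.zeroStep(required = reqN, supplied = dem$supplied,
                         warm = dem$warm))
  glyDemand <- abs(min(fluxes(dem$sol)[[ids$glycogenExchange]], 0))
  capAvail <- if (graceActive || glyUnlimited) Inf else {
    avail <- C[["glycogen"]] + max(paStep$vGly, 0) * X[["PA"]] * dt
    avail / (X[["DZ"]] * dt)
  }
  res <- if (capAvail < glyDemand - 1e-12)
    runAt(min(capDemand, capAvail), dem$warm) else dem
  if (!res$ok)
    return(.zeroStep(glyDemand = glyDemand, required = reqN,
                         supplied = res$supplied, warm = res$warm))
  v <- fluxes(res$sol)
  list(feasible = TRUE, mu = max(0, objectiveValue(res$sol)), v = v,
       vGly = v[[ids$glycogenExchange]], vCO2 = v[[ids$carbonExchange]],
       vNH4 = v[[ids$nh4Exchange]], vN2 = v[[ids$nitrogenase]],
       glyDemand = glyDemand, required = reqN, supplied = res$supplied,
       warm = res$warm)
}

#' Deficiency-driven differentiation allocation
#'
#' Redistributes the step's uncorrected biomass increments between cell
#' types.  For each cross-fed metabolite in shortage (population
#' consumption exceeding production), a differentiation pool is drawn
#' from the deficiency-generating consumers in proportion to the
#' shortage -- the allocation coefficient
#' \eqn{\alpha = (C^T_{prod} + C^T_{cons})/C^T_{cons}} on signed totals,
#' clamped to [0, 1] -- weighted by each consumer's portion coefficient
#' \eqn{\sigma}, and dealt to the metabolite's producers by their
#' \eqn{\sigma}.  If no metabolite is deficient, the entire surplus
#' (the diazotroph increment) is allocated to photoautotroph production.
#' Allocation only redistributes the current increment: a cell type can
#' lose at most what it gained this period, and total biomass is
#' conserved exactly.
#'
#' @param dXprime named uncorrected increments \code{c(DZ=, PA=)}
#'   (g DW/L, non-negative).
#' @param currencyFluxes list per metabolite (\code{glycogen},
#'   \code{nh4}) of named per-type exchange fluxes (mmol/gDW/h, negative
#'   = consumption).
#' @param XfPrime named uncorrected end-of-step biomasses (g DW/L).
#' @param X0 named start-of-step biomasses (g DW/L).
#' @param dt step length (h).
#' @param tol consumption below this is treated as zero.
#' @return list with \code{Xf} (corrected final biomasses) and
#'   \code{records} (one row per processed metabolite: \code{metabolite},
#'   \code{alpha}, \code{Xdelta}, \code{from}, \code{to},
#'   \code{sigmaFrom}, \code{sigmaTo}).
#' @export
allocateDifferentiation <- function(dXprime, currencyFluxes, XfPrime, X0,
                                    dt = 1, tol = 1e-12) {
  types <- names(dXprime)
  stopifnot(all(dXprime >= -1e-12))
  avail <- pmax(dXprime, 0)
  Xf <- X0 + pmax(dXprime, 0)
  rec <- list()
  anyDeficit <- FALSE
  for (mName in names(currencyFluxes)) {
    v <- currencyFluxes[[mName]][types]
    consAmt <- pmax(-v, 0) * XfPrime * dt   # per-type consumption totals
    prodAmt <- pmax(v, 0) * XfPrime * dt
    consT <- sum(consAmt); prodT <- sum(prodAmt)
    if (consT <= tol) next                   # nothing consumed: no shortage
    if (prodT >= consT - tol) next           # no deficiency
    anyDeficit <- TRUE
    alpha <- min(1, max(0, (prodT - consT) / (-consT)))
    consumers <- types[consAmt > tol]
    sigmaFrom <- consAmt[consumers] / consT
    producers <- types[prodAmt > tol]
    if (!length(producers)) {
      ## structural producers of this currency; differentiation can only
      ## reinforce an existing population, never create one from nothing
      cand <- setdiff(types, consumers)
      producers <- cand[XfPrime[cand] > tol]
      if (!length(producers)) next
      sigmaTo <- stats::setNames(rep(1 / length(producers),
                                     length(producers)), producers)
    } else sigmaTo <- prodAmt[producers] / prodT
    draw <- pmin(alpha * sigmaFrom * dXprime[consumers], avail[consumers])
    Xdelta <- sum(draw)
    avail[consumers] <- avail[consumers] - draw
    Xf[consumers] <- Xf[consumers] - draw
    Xf[producers] <- Xf[producers] + sigmaTo * Xdelta
    avail[producers] <- avail[producers] + sigmaTo * Xdelta
    rec[[length(rec) + 1L]] <- data.frame(
      metabolite = mName, alpha = alpha, Xdelta = Xdelta,
      from = paste(consumers, collapse = "+"),
      to = paste(producers, collapse = "+"),
      sigmaFrom = sum(sigmaFrom), sigmaTo = sum(sigmaTo),
      stringsAsFactors = FALSE)
  }
  if (!anyDeficit && avail[["DZ"]] > tol) {
    ## surplus-only period: all diazotroph excess goes to the
    ## photoautotrophs, which drive biomass production
    mv <- avail[["DZ"]]
    Xf[["DZ"]] <- Xf[["DZ"]] - mv
    Xf[["PA"]] <- Xf[["PA"]] + mv
    rec[[length(rec) + 1L]] <- data.frame(
      metabolite = "surplus", alpha = 1, Xdelta = mv,
      from = "DZ", to = "PA", sigmaFrom = 1, sigmaTo = 1,
      stringsAsFactors = FALSE)
  }
  list(Xf = Xf,
       records = if (length(rec)) do.call(rbind, rec)
                 else data.frame(metabolite = character(0),
                                 alpha = numeric(0), Xdelta = numeric(0),
                                 from = character(0), to = character(0),
                                 sigmaFrom = numeric(0),
                                 sigmaTo = numeric(0)))
}

#' Simulate the two-phenotype population
#'
#' Batch-reactor dynamic FBA over the horizon: photoautotroph step,
#' diazotroph step, exponential biomass update
#' \eqn{X'_f = X_0 e^{\mu \Delta t}}, deficiency-driven allocation, and
#' medium update.  During the first \code{grace} steps cells may draw
#' substrates beyond the medium stocks (the seed cache); a step is
#' flagged failing when the population gains essentially no biomass or
#' consumes a cross-fed currency it does not itself produce, and after
#' \code{grace} consecutive failing steps the population is declared
#' dead at the next step -- nonviable inocula (all-photoautotroph,
#' all-diazotroph, or no energy) terminate after exactly
#' \code{grace + 1} steps.
#'
#' @param toy result of [makeToyModel()], or any list with \code{model},
#'   \code{diazotroph}, \code{photoautotroph}.
#' @param inoculum named initial biomasses \code{c(DZ=, PA=)} (g DW/L).
#' @param horizon simulated time (h).
#' @param dt step length (h).
#' @param grace grace period length in steps.
#' @param seeds named initial medium amounts \code{c(glycogen=, nh4=)}
#'   (mmol/L); default: one step of inoculum consumption at unconstrained
#'   growth.
#' @param excess currencies (\code{"nh4"}, \code{"glycogen"}) treated as
#'   replete in the medium (nitrogen-source scenarios).
#' @return a \linkS4class{PopulationTrace}.
#' @export
simulatePopulation <- function(toy, inoculum, horizon = 400, dt = 1,
                               grace = 3, seeds = NULL,
                               excess = character(0)) {
  stopifnot(all(c("DZ", "PA") %in% names(inoculum)),
            all(inoculum >= 0), dt > 0)
  ids <- toy$diazotroph@ids
  dzModel <- applyCellType(toy$model, unconstrainedVariant(toy$diazotroph))
  paModel <- applyCellType(toy$model,
                           unconstrainedVariant(toy$photoautotroph))
  if (is.null(seeds)) seeds <- .defaultSeeds(dzModel, paModel, ids,
                                             inoculum, dt)
  X <- inoculum[c("DZ", "PA")]
  C <- c(glycogen = unname(seeds[["glycogen"]]),
         nh4 = unname(seeds[["nh4"]]))
  nSteps <- ceiling(horizon / dt)
  rows <- vector("list", nSteps)
  allocs <- list()
  prev <- NULL
  failStreak <- 0L
  status <- "completed"
  warmPA <- NULL; warmDZ <- NULL
  for (k in seq_len(nSteps)) {
    t <- k * dt
    if (failStreak >= grace) {
      ## unable to produce metabolites or biomass throughout the grace
      ## window: terminate
      rows[[k]] <- .traceRow(t, X, C, mu = 0, pa = .zeroStep(),
                             dz = .zeroStep(), amounts = numeric(4),
                             borrowed = c(0, 0), fail = TRUE)
      status <- "died"
      rows <- rows[seq_len(k)]
      break
    }
    graceActive <- k <= grace
    fDZ <- if (sum(X) > 0) X[["DZ"]] / sum(X) else 0
    pa <- stepPhotoautotroph(paModel, ids, X, C, prev, dt, graceActive,
                             warmPA, nh4Unlimited = "nh4" %in% excess)
    warmPA <- pa$warm
    dz <- stepDiazotroph(dzModel, ids, X, C, pa, fDZ, dt, graceActive,
                         warmDZ, glyUnlimited = "glycogen" %in% excess)
    warmDZ <- dz$warm
    mu <- c(DZ = dz$mu, PA = pa$mu)
    XfP <- X * exp(mu * dt)
    dXp <- XfP - X
    ## deficiency is judged against demand (what cells would draw were
    ## the medium replete), not against availability-capped uptake --
    ## a starving population must register as deficient
    al <- allocateDifferentiation(
      dXp,
      list(glycogen = c(DZ = -dz$glyDemand, PA = pa$vGly),
           nh4 = c(DZ = dz$vNH4, PA = -pa$nh4Demand)),
      XfP, X, dt)
    if (nrow(al$records)) {
      al$records$t <- t
      allocs[[length(allocs) + 1L]] <- al$records
    }
    ## medium bookkeeping on start-of-step biomasses (the basis of the
    ## uptake caps); grace-period overdrafts are recorded as borrowing
    prodGly <- max(pa$vGly, 0) * X[["PA"]] * dt
    consGly <- abs(min(dz$vGly, 0)) * X[["DZ"]] * dt
    prodNH4 <- max(dz$vNH4, 0) * X[["DZ"]] * dt
    consNH4 <- abs(min(pa$vNH4, 0)) * X[["PA"]] * dt
    newGly <- C[["glycogen"]] + prodGly -
      if ("glycogen" %in% excess) 0 else consGly
    newNH4 <- C[["nh4"]] + prodNH4 -
      if ("nh4" %in% excess) 0 else consNH4
    borrowed <- c(glycogen = max(0, -newGly), nh4 = max(0, -newNH4))
    C <- c(glycogen = max(0, newGly), nh4 = max(0, newNH4))
    totalGrowth <- sum(al$Xf) - sum(X)
    demGly <- dz$glyDemand * X[["DZ"]] * dt
    demNH4 <- pa$nh4Demand * X[["PA"]] * dt
    fail <- totalGrowth <= 1e-9 * max(sum(X), 1e-12) ||
      (!"glycogen" %in% excess && demGly > 1e-9 && prodGly <= 1e-9) ||
      (!"nh4" %in% excess && demNH4 > 1e-9 && prodNH4 <= 1e-9)
    failStreak <- if (fail) failStreak + 1L else 0L
    muT <- if (sum(X) > 0) log(sum(al$Xf) / sum(X)) / dt else 0
    rows[[k]] <- .traceRow(t, al$Xf, C, muT, pa, dz,
                           amounts = c(prodGly, consGly, prodNH4,
                                       consNH4),
                           borrowed = borrowed, fail = fail)
    X <- al$Xf
    prev <- list(vGlyDZ = dz$vGly, muDZ = dz$mu)
  }
  states <- do.call(rbind, rows)
  rownames(states) <- NULL
  new("PopulationTrace", states = states,
      allocations = if (length(allocs)) do.call(rbind, allocs)
                    else data.frame(),
      status = status,
      params = list(inoculum = inoculum, horizon = horizon, dt = dt,
                    grace = grace, seeds = seeds, excess = excess))
}

.traceRow <- function(t, X, C, mu, pa, dz, amounts, borrowed, fail) {
  data.frame(t = t, X_DZ = unname(X[["DZ"]]), X_PA = unname(X[["PA"]]),
             f_DZ = if (sum(X) > 0) unname(X[["DZ"]] / sum(X)) else NA_real_,
             C_glycogen = unname(C[["glycogen"]]),
             C_NH4 = unname(C[["nh4"]]),
             mu_t = mu, mu_PA = pa$mu, mu_DZ = dz$mu,
             v_gly_PA = pa$vGly, v_gly_DZ = dz$vGly,
             v_nh4_PA = pa$vNH4, v_nh4_DZ = dz$vNH4,
             v_co2_PA = pa$vCO2, v_n2_DZ = dz$vN2,
             gly_produced = amounts[1], gly_consumed = amounts[2],
             nh4_produced = amounts[3], nh4_consumed = amounts[4],
             borrowed_gly = unname(borrowed[1]),
             borrowed_nh4 = unname(borrowed[2]),
             fail = fail)
}

.defaultSeeds <- function(dzModel, paModel, ids, inoculum, dt) {
  gly <- 0; nh4 <- 0
  if (inoculum[["DZ"]] > 0) {
    m <- dzModel
    sol <- solveFBA(m, ids$biomass)
    if (solutionStatus(sol) == "optimal")
      gly <- abs(min(fluxes(sol)[[ids$glycogenExchange]], 0)) *
        inoculum[["DZ"]] * dt
  }
  if (inoculum[["PA"]] > 0) {
    sol <- solveFBA(paModel, ids$biomass)
    if (solutionStatus(sol) == "optimal")
      nh4 <- abs(min(fluxes(sol)[[ids$nh4Exchange]], 0)) *
        inoculum[["PA"]] * dt
  }
  c(glycogen = gly, nh4 = nh4)
}
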