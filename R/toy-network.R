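#' Parameters for the reduced two-cell-type test network
#'
#' The toy network compresses the division of labor into ~20 elementally
#' and charge balanced reactions: photon capture split between PSI
#' (ATP-generating) and PSII (NADPH/O2-generating), a lumped Calvin-cycle
#' carbon fixation, glycogen polymerization/degradation on a 6-carbon
#' glucose-equivalent currency, nitrogenase (N2 -> 2 NH4+ at 16 ATP per
#' N2, i.e. 8 ATP per N), ammonium and glycogen transport/exchange, an
#' ATP-hydrolysis maintenance reaction and a lumped biomass drain with a
#' stated C:N ratio.
#'
#' @param atpPerGlycogen total ATP-equivalents a photoautotroph spends per
#'   glycogen unit (Calvin ATP + NADPH at respiratory ATP value +
#'   polymerization ATP); default 64.
#' @param atpPerN2 ATP per N2 fixed by nitrogenase (16, i.e. 8 per N).
#' @param cnRatio biomass molar C:N ratio (default 6.6, the marine
#'   Redfield value).
#' @param carbonMassFraction g C per g DW in biomass (default 0.458).
#' @param photonsPerAtp,photonsPerNadph photons per ATP (PSI) and per
#'   NADPH (PSII).
#' @param respAtpPerGlucose ATP yield of fully respiring one glucose.
#' @param gamAtp growth-associated maintenance, mmol ATP per g DW formed.
#' @param maintenance named numeric: non-growth maintenance ATP demand
#'   (mmol/gDW/h) per cell type.
#' @param carbonUptake,nitrogenaseFlux,photonBudget physiological
#'   constraint values passed into the generated constraint sets.
#' @param glycogenTransportCap capacity of the glycogen importer in
#'   glucose-equivalent mmol/gDW/h (the uptake direction of the
#'   transporter); defaults to the measured carbon uptake rate
#'   (carbonUptake/6), so per-cell uptake can never exceed physiology
#'   even under relaxed exchange bounds.  Export is not capped.
#' @return a validated parameter list of class \code{"ToyNetworkParams"}.
#' @export
toyNetworkParams <- function(atpPerGlycogen = 64, atpPerN2 = 16,
                             cnRatio = 6.6, carbonMassFraction = 0.458,
                             photonsPerAtp = 2, photonsPerNadph = 2,
                             respAtpPerGlucose = 30, gamAtp = 30,
                             maintenance = c(diazotroph = 36,
                                             photoautotroph = 32),
                             carbonUptake = 0.927,
                             nitrogenaseFlux = 0.132,
                             photonBudget = 80,
                             glycogenTransportCap = carbonUptake / 6) {
  p <- list(atpPerGlycogen = atpPerGlycogen, atpPerN2 = atpPerN2,
            cnRatio = cnRatio, carbonMassFraction = carbonMassFraction,
            photonsPerAtp = photonsPerAtp,
            photonsPerNadph = photonsPerNadph,
            respAtpPerGlucose = respAtpPerGlucose, gamAtp = gamAtp,
            maintenance = maintenance, carbonUptake = carbonUptake,
            nitrogenaseFlux = nitrogenaseFlux,
            photonBudget = photonBudget,
            glycogenTransportCap = glycogenTransportCap)
  num <- unlist(p[setdiff(names(p), "maintenance")])
  if (any(!is.finite(num)) || any(num <= 0))
    stop("all toy network parameters must be positive")
  if (any(maintenance < 0) ||
      !all(c("diazotroph", "photoautotroph") %in% names(maintenance)))
    stop("maintenance must name non-negative diazotroph and photoautotroph values")
  if (atpPerN2 < 5)
    stop("atpPerN2 below 5 cannot be proton-balanced in this network")
  p$polymerAtp <- atpPerGlycogen - 18 - respAtpPerGlucose
  if (p$polymerAtp < 1)
    stop("atpPerGlycogen too small: must exceed Calvin ATP (18) plus the ",
         "ATP value of 12 NADPH (respAtpPerGlucose)")
  class(p) <- "ToyNetworkParams"
  p
}

#' Generate the reduced two-cell-type model
#'
#' Emits a fully balanced \linkS4class{MetabolicModel} plus matched
#' diazotroph and photoautotroph constraint sets.  By construction the
#' model passes [checkBalances()] (no mechanistic imbalance),
#' [findDeadEnds()] (every species both producible and consumable) and
#' [detectFutileCycles()] (no internal loop can carry flux with closed
#' exchanges).
#'
#' @param params a [toyNetworkParams()] list.
#' @return list with elements \code{model}, \code{diazotroph},
#'   \code{photoautotroph} (the two \linkS4class{CellTypeConstraints})
#'   and \code{composition} (the generator's declared category counts).
#' @export
makeToyModel <- function(params = toyNetworkParams()) {
  stopifnot(inherits(params, "ToyNetworkParams"))
  p <- params
  met <- data.frame(
    id = c("photon", "atp", "adp", "pi", "h", "h2o", "nadph", "nadp",
           "o2", "co2", "n2", "nh4_c", "nh4_e", "glc", "glyc_c",
           "glyc_e"),
    name = c("photon", "ATP", "ADP", "orthophosphate", "proton", "water",
             "NADPH", "NADP+", "dioxygen", "carbon dioxide",
             "dinitrogen", "ammonium", "ammonium (external)",
             "glucose", "glycogen unit", "glycogen unit (external)"),
    formula = c("", "C10H12N5O13P3", "C10H12N5O10P2", "HO4P", "H", "H2O",
                "C21H26N7O17P3", "C21H25N7O17P3", "O2", "CO2", "N2",
                "H4N", "H4N", "C6H12O6", "C6H10O5", "C6H10O5"),
    charge = c(0L, -4L, -3L, -2L, 1L, 0L, -4L, -3L, 0L, 0L, 0L, 1L, 1L,
               0L, 0L, 0L),
    compartment = c("e", rep("c", 11), "e", "c", "c", "e"),
    stringsAsFactors = FALSE)

  nP <- p$polymerAtp; aN <- p$atpPerN2
  k <- p$respAtpPerGlucose; g <- p$gamAtp
  bioC <- 1000 * p$carbonMassFraction / 12.011   # mmol C per g DW
  bioGlc <- bioC / 6
  bioNH4 <- bioC / p$cnRatio
  pa <- p$photonsPerAtp; pn <- p$photonsPerNadph

  stoich <- list(
    PSI = c(photon = -pa, adp = -1, pi = -1, h = -1, atp = 1, h2o = 1),
    PSII = c(photon = -pn, h2o = -1, nadp = -1, nadph = 1, h = 1,
             o2 = 0.5),
    CALVIN = c(co2 = -6, nadph = -12, atp = -18, h2o = -12, glc = 1,
               nadp = 12, adp = 18, pi = 18, h = 6),
    GLYSYN = c(glc = -1, atp = -nP, h2o = -(nP - 1), glyc_c = 1,
               adp = nP, pi = nP, h = nP),
    GLYDEG = c(glyc_c = -1, h2o = -1, glc = 1),
    RESP = c(glc = -1, o2 = -6, adp = -k, pi = -k, h = -k, co2 = 6,
             h2o = 6 + k, atp = k),
    OPP = c(glc = -1, nadp = -12, h2o = -6, co2 = 6, nadph = 12, h = 12),
    NITROGENASE = c(n2 = -1, nadph = -3, atp = -aN, h2o = -aN,
                    nh4_c = 2, nadp = 3, adp = aN, pi = aN, h = aN - 5),
    EN_ATP = c(atp = -1, h2o = -1, adp = 1, pi = 1, h = 1),
    BIOMASS = c(glc = -bioGlc, nh4_c = -bioNH4, atp = -g, h2o = -g,
                adp = g, pi = g, h = g),
    T_GLYC = c(glyc_c = -1, glyc_e = 1),
    T_NH4 = c(nh4_c = -1, nh4_e = 1),
    EX_photon = c(photon = -1),
    EX_glyc = c(glyc_e = -1),
    EX_nh4 = c(nh4_e = -1),
    EX_co2 = c(co2 = -1),
    EX_o2 = c(o2 = -1),
    EX_n2 = c(n2 = -1),
    EX_h2o = c(h2o = -1),
    EX_h = c(h = -1))

  ids <- names(stoich)
  cat_of <- ifelse(grepl("^EX_", ids), "exchange",
            ifelse(ids %in% c("T_GLYC", "T_NH4"), "transport",
            ifelse(ids == "BIOMASS", "biomass", "metabolic")))
  gpr <- stats::setNames(rep("", length(ids)), ids)
  gpr[c("PSI", "PSII", "CALVIN")] <-
    c("psaA and psaB", "psbA and psbD", "rbcL and rbcS")
  gpr[c("GLYSYN", "GLYDEG", "RESP", "OPP")] <-
    c("glgA", "glgP", "cox1 or cyd1", "zwf")
  gpr["NITROGENASE"] <- "nifH and nifD and nifK"
  gpr[c("T_GLYC", "T_NH4")] <- c("mstA", "amt1")
  rev <- ids %in% c("T_GLYC", "T_NH4") | grepl("^EX_", ids)
  rxn <- data.frame(
    id = ids, name = ids,
    lower = ifelse(rev, -1000, 0), upper = 1000,
    gpr = unname(gpr),
    category = cat_of,
    confidence = ifelse(cat_of == "metabolic", 2L,
                 ifelse(cat_of == "transport", 4L, NA_integer_)),
    stringsAsFactors = FALSE)
  rxn$lower[rxn$id == "EX_photon"] <- -1000
  rxn$upper[rxn$id == "EX_photon"] <- 0
  rxn$lower[rxn$id == "T_GLYC"] <- -p$glycogenTransportCap
  model <- MetabolicModel(met, rxn, stoich)

  roleIds <- list(photon = "EX_photon", psii = "PSII",
                  nitrogenase = "NITROGENASE", maintenance = "EN_ATP",
                  carbonExchange = "EX_co2", glycogenExchange = "EX_glyc",
                  nh4Exchange = "EX_nh4", biomass = "BIOMASS")
  dz <- cellTypeConstraints(
    "diazotroph", ids = roleIds,
    carbonUptake = p$carbonUptake, nitrogenaseFlux = p$nitrogenaseFlux,
    photonBudget = p$photonBudget,
    maintenanceAtp = unname(p$maintenance["diazotroph"]),
    uptakes = c("EX_n2", "EX_glyc", "EX_o2"),
    exports = c("EX_nh4", "EX_co2"),
    free = c("EX_h2o", "EX_h"))
  paCT <- cellTypeConstraints(
    "photoautotroph", ids = roleIds,
    carbonUptake = p$carbonUptake, nitrogenaseFlux = 0,
    photonBudget = p$photonBudget,
    maintenanceAtp = unname(p$maintenance["photoautotroph"]),
    uptakes = "EX_nh4",
    exports = c("EX_n2", "EX_glyc", "EX_o2"),
    free = c("EX_h2o", "EX_h"))
  list(model = model, diazotroph = dz, photoautotroph = paCT,
       composition = c(biomass = 1L, macromolecule = 0L, exchange = 8L,
                       transport = 2L,
                       metabolic = sum(cat_of == "metabolic")))
}

#' Brute-force equilibrium oracle for the toy network
#'
#' Scans trichome compositions f_DZ over (0, 1) and, at each fraction,
#' solves the coupled two-cell steady state as one linear program:
#' both submodels at steady state with relaxed (nutrient-unlimited)
#' bounds, glycogen supply equal to demand, ammonium supply at least
#' demand, and both cell types growing at a common rate, maximized.  The
#' returned fraction is the grid argmax of that common growth rate; the
#' scan is the package's independent reference for what the population
#' dynamic FBA should converge to.
#'
#' @param toy result of [makeToyModel()] (or a compatible list).
#' @param step fine grid resolution on f_DZ (default 1e-4).
#' @param coarse coarse pre-scan resolution (default 0.01); the fine scan
#'   refines around the coarse optimum.
#' @return list with \code{fDZ} (equilibrium diazotroph fraction),
#'   \code{growth} (common growth rate, h^-1), \code{viable} (logical)
#'   and \code{profile} (data.frame of the coarse scan: \code{f},
#'   \code{mu}).
#' @export
analyticEquilibrium <- function(toy, step = 1e-4, coarse = 0.01) {
  dzModel <- applyCellType(toy$model, unconstrainedVariant(toy$diazotroph))
  paModel <- applyCellType(toy$model,
                           unconstrainedVariant(toy$photoautotroph))
  S <- .denseS(toy$model)
  m <- nrow(S); n <- ncol(S)
  rid <- reactions(toy$model)$id
  jGly <- match(toy$diazotroph@ids$glycogenExchange, rid)
  jNH4 <- match(toy$diazotroph@ids$nh4Exchange, rid)
  jBio <- match(toy$diazotroph@ids$biomass, rid)
  paB <- reactions(paModel); dzB <- reactions(dzModel)
  lower <- c(paB$lower, dzB$lower, 0)
  upper <- c(paB$upper, dzB$upper, 1e6)
  zeroRow <- numeric(2 * n + 1)
  base <- rbind(cbind(S, matrix(0, m, n + 1)),
                cbind(matrix(0, m, n), S, 0))
  muAt <- local({
    warm <- NULL
    function(f) {
      ## total specific biomass production; differentiation allocation
      ## redistributes the increment freely between the two cell types,
      ## so no per-type balanced-growth constraint is imposed
      cost <- numeric(2 * n + 1)
      cost[jBio] <- (1 - f); cost[n + jBio] <- f
      glyRow <- zeroRow
      glyRow[jGly] <- (1 - f); glyRow[n + jGly] <- f
      nh4Row <- zeroRow
      nh4Row[jNH4] <- (1 - f); nh4Row[n + jNH4] <- f
      nh4Row[2 * n + 1] <- -1
      A <- rbind(base, glyRow, nh4Row)
      res <- solveLP(cost, A, lower = lower, upper = upper, warm = warm)
      if (res$status == "optimal") { warm <<- res$stat; res$objective }
      else NA_real_
    }
  })
  fs <- seq(coarse, 1 - coarse, by = coarse)
  mus <- vapply(fs, muAt, numeric(1))
  profile <- data.frame(f = fs, mu = mus)
  ok <- which(is.finite(mus) & mus > 1e-9)
  if (!length(ok))
    return(list(fDZ = NA_real_, growth = NA_real_, viable = FALSE,
                profile = profile))
  fBest <- fs[ok[which.max(mus[ok])]]
  fine <- seq(max(step, fBest - coarse), min(1 - step, fBest + coarse),
              by = step)
  musF <- vapply(fine, muAt, numeric(1))
  okF <- which(is.finite(musF))
  best <- okF[which.max(musF[okF])]
  list(fDZ = fine[best], growth = musF[best], viable = TRUE,
       profile = profile)
}
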