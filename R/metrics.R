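#' Growth and nitrogen-release metrics of a population trace
#'
#' Computes the per-step growth rate \eqn{\mu_t = \ln(\Sigma X_t /
#' \Sigma X_{t-1}) / \Delta t}, the total growth rate
#' \eqn{\mu_T = \ln(\Sigma X_f / \Sigma X_0) / \Delta t_{total}}, the
#' fraction of fixed nitrogen released to the environment
#' \eqn{Y_{N \to Env} = \Delta C_{NH_4^+} / C_{NH_4^+, prod}}
#' (accumulated medium ammonium over total ammonium produced), and the
#' equilibrium diazotroph fraction as the mean fraction over the final
#' window of the run.  A dead population reports zero nitrogen release
#' (death is assumed before any sustained leakage).
#'
#' @param trace a \linkS4class{PopulationTrace}.
#' @param window fraction of the trace (from the end) averaged for the
#'   equilibrium composition (default 0.1, at least 5 steps).
#' @return list with \code{mu_t} (vector), \code{muTotal},
#'   \code{doublingTime} (h), \code{YNEnv}, \code{equilibriumFDZ},
#'   \code{status}.
#' @export
computeMetrics <- function(trace, window = 0.1) {
  st <- traceStates(trace)
  if (!nrow(st)) stop("empty trace")
  X0 <- sum(trace@params$inoculum)
  died <- traceStatus(trace) == "died"
  if (X0 <= 0)
    return(list(mu_t = st$mu_t, muTotal = NA_real_,
                doublingTime = NA_real_, YNEnv = 0,
                equilibriumFDZ = NA_real_, status = "died"))
  n <- nrow(st)
  Xf <- st$X_DZ[n] + st$X_PA[n]
  tTot <- st$t[n]
  muT <- log(Xf / X0) / tTot
  prodNH4 <- sum(st$nh4_produced)
  dC <- st$C_NH4[n] - trace@params$seeds[["nh4"]]
  Y <- if (died || prodNH4 <= 0) 0 else min(1, max(0, dC / prodNH4))
  w <- max(5L, ceiling(window * n))
  eq <- if (died) NA_real_ else mean(st$f_DZ[max(1, n - w + 1):n])
  list(mu_t = st$mu_t, muTotal = muT,
       doublingTime = log(2) / muT, YNEnv = Y,
       equilibriumFDZ = eq, status = traceStatus(trace))
}

#' Ensemble of randomized inocula
#'
#' Runs the population dynamic FBA from \code{n} randomized inocula:
#' both cell-type biomasses drawn independently and uniformly, the
#' initial fraction arising as their ratio.  Summarizes each run's total
#' growth rate, nitrogen release and equilibrium composition, with death
#' coded per the grace rule.
#'
#' @param toy result of [makeToyModel()].
#' @param n number of iterations.
#' @param horizon,dt,grace passed to [simulatePopulation()].
#' @param seed RNG seed for reproducibility.
#' @param biomassMax upper bound of the uniform biomass draws (g DW/L).
#' @return data.frame with one row per iteration: \code{X0_DZ},
#'   \code{X0_PA}, \code{f0}, \code{muTotal}, \code{YNEnv},
#'   \code{equilibriumFDZ}, \code{status}.
#' @export
runEnsemble <- function(toy, n = 1000, horizon = 400, dt = 1, grace = 3,
                        seed = NULL, biomassMax = 5e-3) {
  if (!is.null(seed)) set.seed(seed)
  xdz <- stats::runif(n, 0, biomassMax)
  xpa <- stats::runif(n, 0, biomassMax)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    tr <- simulatePopulation(toy, c(DZ = xdz[i], PA = xpa[i]),
                             horizon = horizon, dt = dt, grace = grace)
    mt <- computeMetrics(tr)
    out[[i]] <- data.frame(
      X0_DZ = xdz[i], X0_PA = xpa[i], f0 = xdz[i] / (xdz[i] + xpa[i]),
      muTotal = if (mt$status == "died") 0 else mt$muTotal,
      YNEnv = mt$YNEnv, equilibriumFDZ = mt$equilibriumFDZ,
      status = mt$status, stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Growth on alternative nitrogen sources
#'
#' Re-runs the population simulation from a given inoculum with the
#' chosen nitrogen source in excess (its medium availability treated as
#' replete).  For the reduced network the supported sources are
#' \code{"N2"} (the baseline: dinitrogen is already unrestricted) and
#' \code{"NH4"}; a source with no exchange reaction in the model is an
#' error -- add one with [addDiffusionTransporter()] first.
#'
#' @param toy result of [makeToyModel()].
#' @param source nitrogen source name.
#' @param inoculum named \code{c(DZ=, PA=)}; default: the oracle
#'   equilibrium composition scaled to \code{totalBiomass}.
#' @param totalBiomass total inoculum biomass when derived from the
#'   equilibrium composition (g DW/L).
#' @param horizon,dt,grace passed to [simulatePopulation()].
#' @return list with \code{source}, \code{muTotal}, \code{metrics} and
#'   \code{trace}.
#' @export
nitrogenSourceScenario <- function(toy, source = c("N2", "NH4"),
                                   inoculum = NULL, totalBiomass = 1e-3,
                                   horizon = 400, dt = 1, grace = 3) {
  source <- match.arg(source)
  if (is.null(inoculum)) {
    eq <- analyticEquilibrium(toy, step = 1e-3)
    if (!eq$viable) stop("no viable equilibrium composition for this toy")
    inoculum <- c(DZ = eq$fDZ, PA = 1 - eq$fDZ) * totalBiomass
  }
  excess <- if (source == "NH4") "nh4" else character(0)
  tr <- simulatePopulation(toy, inoculum, horizon = horizon, dt = dt,
                           grace = grace, excess = excess)
  mt <- computeMetrics(tr)
  list(source = source,
       muTotal = if (mt$status == "died") 0 else mt$muTotal,
       metrics = mt, trace = tr)
}

#' Add a diffusion-style transporter and exchange for a metabolite
#'
#' Temporarily extends a model so an extra nutrient can be fed: adds an
#' external species, a (optionally ATP-dependent, for actively
#' transported compounds such as urea) transport reaction and an
#' exchange reaction.
#'
#' @param model a \linkS4class{MetabolicModel}.
#' @param metabolite internal metabolite id to connect.
#' @param atpCost mmol ATP hydrolysed per mmol transported (0 =
#'   passive diffusion).
#' @param energyIds named list of the ATP-hydrolysis species ids
#'   (\code{atp}, \code{adp}, \code{pi}, \code{h}, \code{h2o}).
#' @return the extended \linkS4class{MetabolicModel}; the new exchange is
#'   named \code{EX_<metabolite>_diff}.
#' @export
addDiffusionTransporter <- function(model, metabolite, atpCost = 0,
                                    energyIds = list(atp = "atp",
                                                     adp = "adp",
                                                     pi = "pi", h = "h",
                                                     h2o = "h2o")) {
  .metIndex(model, metabolite)
  met <- metabolites(model); rxn <- reactions(model)
  S <- stoichiometry(model)
  extId <- paste0(metabolite, "_ext")
  row <- met[met$id == metabolite, ]
  row$id <- extId; row$compartment <- "e"
  tStoich <- stats::setNames(c(-1, 1), c(extId, metabolite))
  if (atpCost > 0) {
    e <- energyIds
    .metIndex(model, unlist(e))
    add <- stats::setNames(c(-atpCost, -atpCost, atpCost, atpCost,
                             atpCost),
                           c(e$atp, e$h2o, e$adp, e$pi, e$h))
    tStoich <- c(tStoich, add)
  }
  stoich <- c(
    stats::setNames(lapply(seq_len(ncol(S)), function(j) {
      col <- S[, j]; col[col != 0]
    }), rxn$id),
    stats::setNames(list(tStoich,
                         stats::setNames(-1, extId)),
                    c(paste0("T_", metabolite, "_diff"),
                      paste0("EX_", metabolite, "_diff"))))
  rxn2 <- rbind(rxn,
                data.frame(id = names(stoich)[length(stoich) - 1:0],
                           name = c(paste("diffusion transport:",
                                          metabolite),
                                    paste("exchange:", metabolite)),
                           lower = c(if (atpCost > 0) 0 else -1000, -1000),
                           upper = c(1000, 1000),
                           gpr = "", category = c("transport", "exchange"),
                           confidence = NA_integer_))
  MetabolicModel(rbind(met, row), rxn2, stoich)
}
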