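## Steady-state linear-program machinery: FBA, FVA, maintenance-energy
## calibration and gene/reaction essentiality.

.denseS <- function(model) as.matrix(stoichiometry(model))

#' Flux balance analysis
#'
#' Solves \eqn{\max_v\ c^\top v} subject to \eqn{S v = 0},
#' \eqn{lb \le v \le ub}, with \eqn{c} the indicator of the objective
#' reaction.  Infeasible or unbounded programs are reported in the
#' solution status, never silently zeroed.  Because genome-scale models
#' are underdetermined, a single optimum is one of many; flux-level
#' claims should be assessed with [runFVA()].
#'
#' @param model a \linkS4class{MetabolicModel}.
#' @param objective objective reaction id (e.g. the biomass reaction).
#' @param sense \code{"max"} (default) or \code{"min"}.
#' @param warm optional warm-start status from a previous solution on the
#'   same model structure.
#' @return a \linkS4class{FluxSolution}.
#' @export
solveFBA <- function(model, objective, sense = c("max", "min"),
                     warm = NULL) {
  sense <- match.arg(sense)
  rxn <- reactions(model)
  idx <- .rxnIndex(model, objective)
  cost <- numeric(nrow(rxn)); cost[idx] <- 1
  res <- solveLP(cost, .denseS(model), lower = rxn$lower, upper = rxn$upper,
                 sense = sense, warm = warm)
  if (res$status != "optimal")
    return(new("FluxSolution", fluxes = numeric(0),
               objectiveValue = NA_real_, objectiveReaction = objective,
               status = res$status))
  v <- stats::setNames(res$x, rxn$id)
  sol <- new("FluxSolution", fluxes = v, objectiveValue = res$objective,
             objectiveReaction = objective, status = "optimal")
  attr(sol, "warm") <- res$stat
  sol
}

#' Maximum steady-state mass-balance residual of a solution
#'
#' @param model a \linkS4class{MetabolicModel}.
#' @param solution a \linkS4class{FluxSolution}.
#' @return \eqn{\|S v\|_\infty} in mmol/gDW/h.
#' @export
massBalanceResidual <- function(model, solution) {
  if (solutionStatus(solution) != "optimal") return(NA_real_)
  max(abs(.denseS(model) %*% fluxes(solution)[reactions(model)$id]))
}

#' Flux variability analysis
#'
#' For each requested reaction, minimizes and maximizes its flux subject
#' to the steady-state constraints and (optionally) to the objective
#' staying at a stated fraction of its optimum, quantifying the latitude
#' left by alternate optima.
#'
#' @param model a \linkS4class{MetabolicModel}.
#' @param reactions reaction ids to scan (default: all).
#' @param objective objective reaction id; required unless
#'   \code{fractionOfOptimum} is \code{NULL}.
#' @param fractionOfOptimum objective retention fraction (default 1.0, the
#'   "same solution" setting); \code{NULL} drops the objective constraint
#'   entirely (used by the closed-exchange futile-cycle screen).
#' @return data.frame with columns \code{id}, \code{min}, \code{max}.
#' @export
runFVA <- function(model, reactions = NULL, objective = NULL,
                   fractionOfOptimum = 1.0) {
  rxn <- model@reactions
  if (is.null(reactions)) reactions <- rxn$id
  .rxnIndex(model, reactions)
  A <- .denseS(model)
  lower <- rxn$lower; upper <- rxn$upper
  b <- numeric(nrow(A))
  n <- ncol(A)
  if (!is.null(fractionOfOptimum)) {
    if (is.null(objective))
      stop("objective reaction needed when fractionOfOptimum is set")
    base <- solveFBA(model, objective)
    if (solutionStatus(base) != "optimal")
      stop("FVA requires a feasible optimum (status: ",
           solutionStatus(base), ")")
    opt <- objectiveValue(base)
    ## append row c'v - s = 0 with slack s >= fraction * optimum
    cost <- numeric(n); cost[.rxnIndex(model, objective)] <- 1
    A <- rbind(cbind(A, 0), c(cost, -1))
    floorVal <- fractionOfOptimum * opt - 1e-9
    lower <- c(lower, floorVal)
    upper <- c(upper, max(floorVal, 1e7))
    b <- numeric(nrow(A))
    n <- n + 1L
  }
  out <- data.frame(id = reactions, min = NA_real_, max = NA_real_)
  warm <- NULL
  for (k in seq_along(reactions)) {
    j <- .rxnIndex(model, reactions[k])
    cost <- numeric(n); cost[j] <- 1
    lo <- solveLP(cost, A, b, lower, upper, sense = "min", warm = warm)
    if (lo$status != "optimal") stop("FVA subproblem ", reactions[k],
                                     " (min): ", lo$status)
    warm <- lo$stat
    hi <- solveLP(cost, A, b, lower, upper, sense = "max", warm = warm)
    if (hi$status != "optimal") stop("FVA subproblem ", reactions[k],
                                     " (max): ", hi$status)
    warm <- hi$stat
    out$min[k] <- lo$objective; out$max[k] <- hi$objective
  }
  ## tidy numerical noise so that min <= max exactly
  swap <- out$min > out$max
  if (any(swap)) {
    mid <- (out$min[swap] + out$max[swap]) / 2
    out$min[swap] <- mid; out$max[swap] <- mid
  }
  out
}

#' Calibrate non-growth maintenance energy
#'
#' Adjusts the lower bound of the ATP-hydrolysis maintenance reaction by
#' bisection until the predicted growth rate matches a measured growth
#' rate, mirroring the standard fitting of non-growth-associated
#' maintenance against physiological data.  Growth is monotone
#' non-increasing in the maintenance demand.
#'
#' @param model a \linkS4class{MetabolicModel} (cell-type constraints
#'   already applied).
#' @param objective biomass reaction id.
#' @param maintenance maintenance reaction id (ATP + H2O -> ADP + H + Pi).
#' @param targetGrowth measured growth rate, h^-1.
#' @param bracket numeric length-2 search interval for the maintenance
#'   flux, mmol ATP/gDW/h; growth at the ends must straddle the target.
#' @param tol convergence tolerance on \eqn{|growth - target|} (h^-1).
#' @param maxit maximum bisection steps.
#' @return list with \code{maintenance} (the calibrated flux),
#'   \code{growth} (growth at that flux) and \code{iterations}.
#' @export
calibrateMaintenance <- function(model, objective, maintenance,
                                 targetGrowth, bracket = c(0, 500),
                                 tol = 1e-6, maxit = 200L) {
  growthAt <- function(m) {
    mod <- model
    ub <- bounds(mod, maintenance)[1, "upper"]
    bounds(mod, maintenance) <- c(m, max(m, ub))
    sol <- solveFBA(mod, objective)
    if (solutionStatus(sol) != "optimal") 0 else objectiveValue(sol)
  }
  gLow <- growthAt(bracket[1]); gHigh <- growthAt(bracket[2])
  if (targetGrowth > gLow + tol || targetGrowth < gHigh - tol)
    stop(sprintf(paste0("target growth %.6g h^-1 outside achievable range ",
                        "[%.6g, %.6g] for maintenance in [%g, %g]"),
                 targetGrowth, gHigh, gLow, bracket[1], bracket[2]))
  lo <- bracket[1]; hi <- bracket[2]
  g <- gLow; m <- lo
  for (it in seq_len(maxit)) {
    m <- (lo + hi) / 2
    g <- growthAt(m)
    if (abs(g - targetGrowth) <= tol) break
    if (g > targetGrowth) lo <- m else hi <- m
  }
  if (abs(g - targetGrowth) > tol)
    stop("maintenance calibration did not converge to tolerance")
  list(maintenance = m, growth = g, iterations = it)
}

#' Gene and reaction essentiality
#'
#' Gene mode evaluates every reaction's GPR with the gene removed and
#' disables reactions whose rule becomes false; reaction mode pins each
#' reaction to \code{[0, 0]}.  Growth is re-optimized for every knockout
#' (an infeasible knockout counts as zero growth).  Classification:
#' \code{essential} when knockout growth < \code{essentialTol};
#' \code{growth-reducing} when below \code{reducingFraction} of wild type;
#' \code{neutral} otherwise.
#'
#' @param model a \linkS4class{MetabolicModel} with constraints applied.
#' @param objective biomass reaction id.
#' @param mode \code{"gene"} or \code{"reaction"}.
#' @param targets ids to knock out (default: all genes / all reactions
#'   except the objective).
#' @param essentialTol,reducingFraction classification thresholds.
#' @return data.frame with columns \code{id}, \code{growth},
#'   \code{class}; attribute \code{wildtype} holds wild-type growth.
#' @export
essentiality <- function(model, objective, mode = c("gene", "reaction"),
                         targets = NULL, essentialTol = 1e-6,
                         reducingFraction = 0.99) {
  mode <- match.arg(mode)
  rxn <- reactions(model)
  wt <- solveFBA(model, objective)
  if (solutionStatus(wt) != "optimal")
    stop("wild-type model is ", solutionStatus(wt))
  wtg <- objectiveValue(wt)
  warm <- attr(wt, "warm")
  if (is.null(targets))
    targets <- if (mode == "gene") modelGenes(model)
               else setdiff(rxn$id, objective)
  growth <- numeric(length(targets))
  for (k in seq_along(targets)) {
    mod <- model
    off <- if (mode == "gene") {
      rxn$id[!vapply(rxn$gpr, evalGPR, logical(1),
                     knockedOut = targets[k])]
    } else targets[k]
    if (length(off)) {
      bounds(mod, off) <- c(0, 0)
      sol <- solveFBA(mod, objective, warm = warm)
      growth[k] <- if (solutionStatus(sol) == "optimal")
        max(0, objectiveValue(sol)) else 0
    } else growth[k] <- wtg
  }
  cls <- ifelse(growth < essentialTol, "essential",
                ifelse(growth < reducingFraction * wtg,
                       "growth-reducing", "neutral"))
  out <- data.frame(id = targets, growth = growth, class = cls,
                    stringsAsFactors = FALSE)
  attr(out, "wildtype") <- wtg
  out
}
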