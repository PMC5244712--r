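#' Structural statistics of a model
#'
#' Counts reactions by functional category (the categories partition the
#' reaction set), plus gene and metabolite counts.
#'
#' @param model a \linkS4class{MetabolicModel}.
#' @return list with \code{reactions}, \code{metabolites}, \code{genes} and
#'   \code{byCategory} (named integer vector over all five categories).
#' @export
modelStatistics <- function(model) {
  rxn <- reactions(model)
  byCat <- vapply(.REACTION_CATEGORIES,
                  function(ct) sum(rxn$category == ct), integer(1))
  list(reactions = nrow(rxn),
       metabolites = nrow(metabolites(model)),
       genes = length(modelGenes(model)),
       byCategory = byCat)
}

#' Element and charge balance check
#'
#' Verifies conservation of every element and of charge across each
#' mechanistic reaction.  Biomass, macromolecule-summary and exchange
#' reactions are intentionally unbalanced and are excluded by category;
#' reactions touching a metabolite with unknown formula are flagged
#' \code{"uncheckable"} rather than \code{"unbalanced"}.
#'
#' @param model a \linkS4class{MetabolicModel}.
#' @param tol absolute tolerance on per-element imbalance.
#' @return data.frame with columns \code{id}, \code{status}
#'   (\code{unbalanced}/\code{uncheckable}) and a list-column
#'   \code{imbalance} of named per-element (+\code{charge}) residuals;
#'   zero rows when the model is clean.
#' @export
checkBalances <- function(model, tol = 1e-6) {
  met <- metabolites(model); rxn <- reactions(model)
  S <- stoichiometry(model)
  counts <- lapply(met$formula, function(f)
    tryCatch(parseFormula(f), error = function(e) NULL))
  check <- which(rxn$category %in% c("metabolic", "transport"))
  out <- list()
  for (j in check) {
    col <- S[, j]; idx <- which(col != 0)
    if (any(vapply(counts[idx], is.null, logical(1)))) {
      out[[length(out) + 1L]] <- list(id = rxn$id[j], status = "uncheckable",
                                      imbalance = numeric(0))
      next
    }
    imb <- .combineCounts(counts[idx], col[idx])
    dq <- sum(met$charge[idx] * col[idx])
    if (abs(dq) > tol) imb <- c(imb, charge = dq)
    imb <- imb[abs(imb) > tol]
    if (length(imb))
      out[[length(out) + 1L]] <- list(id = rxn$id[j], status = "unbalanced",
                                      imbalance = imb)
  }
  data.frame(id = vapply(out, `[[`, character(1), "id"),
             status = vapply(out, `[[`, character(1), "status"),
             imbalance = I(lapply(out, `[[`, "imbalance")),
             stringsAsFactors = FALSE)
}

#' Dead-end metabolites and the reactions they strand
#'
#' A metabolite is a dead end when, given the directions allowed by the
#' reaction bounds, it can only ever be produced or only ever be consumed;
#' every reaction forced through such a metabolite is stranded (can never
#' carry steady-state flux).  The check is directional: an irreversible
#' reaction only produces on its product side.
#'
#' @param model a \linkS4class{MetabolicModel}.
#' @param iterative propagate: removing stranded reactions can strand
#'   further metabolites (default \code{FALSE}, the single-pass count).
#' @return list with \code{metabolites} (dead-end metabolite ids) and
#'   \code{reactions} (ids of stranded reactions).
#' @export
findDeadEnds <- function(model, iterative = FALSE) {
  rxn <- reactions(model)
  S <- stoichiometry(model)
  active <- rep(TRUE, nrow(rxn))
  deadMets <- character(0)
  repeat {
    Sa <- S[, active, drop = FALSE]
    lb <- rxn$lower[active]; ub <- rxn$upper[active]
    canProd <- ((Sa > 0) %*% Matrix::Diagonal(x = as.numeric(ub > 0))) +
               ((Sa < 0) %*% Matrix::Diagonal(x = as.numeric(lb < 0)))
    canCons <- ((Sa < 0) %*% Matrix::Diagonal(x = as.numeric(ub > 0))) +
               ((Sa > 0) %*% Matrix::Diagonal(x = as.numeric(lb < 0)))
    nProd <- Matrix::rowSums(canProd > 0)
    nCons <- Matrix::rowSums(canCons > 0)
    touched <- Matrix::rowSums(Sa != 0) > 0
    dead <- touched & xor(nProd == 0, nCons == 0)
    newDead <- setdiff(metabolites(model)$id[dead], deadMets)
    if (!length(newDead)) break
    deadMets <- union(deadMets, newDead)
    strand <- Matrix::colSums(
      S[metabolites(model)$id %in% deadMets, , drop = FALSE] != 0) > 0
    active <- active & !strand
    if (!iterative) break
  }
  strand <- Matrix::colSums(
    S[metabolites(model)$id %in% deadMets, , drop = FALSE] != 0) > 0
  list(metabolites = deadMets, reactions = rxn$id[strand])
}

#' Detect futile (type III) cycles
#'
#' Closes every exchange reaction to \code{[0, 0]} and runs flux
#' variability analysis over the internal reactions with no objective
#' requirement.  Any reaction whose flux interval has width above
#' tolerance participates in an internal loop able to carry flux with no
#' exchange with the environment, which is thermodynamically infeasible.
#'
#' @param model a \linkS4class{MetabolicModel}.
#' @param tol interval-width tolerance (mmol/gDW/h).
#' @return character vector of loop-capable reaction ids (empty = clean).
#'   If the closed model is infeasible (a symptom of inconsistent fixed
#'   bounds, since all-zero flux is otherwise always available), an empty
#'   result is returned with a warning.
#' @export
detectFutileCycles <- function(model, tol = 1e-6) {
  rxn <- reactions(model)
  ex <- rxn$id[rxn$category == "exchange"]
  closed <- model
  if (length(ex)) bounds(closed, ex) <- c(0, 0)
  ## fixed nonzero bounds can make even the closed model infeasible
  lb <- reactions(closed)$lower; ub <- reactions(closed)$upper
  if (any(lb > tol) || any(ub < -tol)) {
    probe <- solveLP(numeric(nrow(rxn)), stoichiometry(closed),
                     lower = lb, upper = ub)
    if (probe$status != "optimal") {
      warning("closed-exchange model infeasible; check fixed bounds")
      return(character(0))
    }
  }
  internal <- rxn$id[rxn$category != "exchange"]
  fva <- runFVA(closed, reactions = internal, fractionOfOptimum = NULL)
  fva$id[(fva$max - fva$min) > tol]
}
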