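#' Construct a MetabolicModel
#'
#' @param metabolites data.frame with columns \code{id}, \code{name},
#'   \code{formula}, \code{charge}, \code{compartment} (missing optional
#'   columns are filled with defaults).
#' @param reactions data.frame with columns \code{id}, \code{name},
#'   \code{lower}, \code{upper}, \code{gpr}, \code{category},
#'   \code{confidence}.
#' @param stoichiometry named list, one element per reaction (in reaction
#'   table order), each a named numeric vector of metabolite coefficients
#'   (negative = substrate).
#' @return a validated \linkS4class{MetabolicModel}.
#' @examples
#' met <- data.frame(id = c("a", "b"))
#' rxn <- data.frame(id = c("EX_a", "R1"),
#'                   lower = c(-1000, 0), upper = c(1000, 1000),
#'                   category = c("exchange", "metabolic"))
#' mod <- MetabolicModel(met, rxn,
#'                       list(EX_a = c(a = -1), R1 = c(a = -1, b = 1)))
#' @export
MetabolicModel <- function(metabolites, reactions, stoichiometry) {
  metabolites <- .fillMetaboliteDefaults(metabolites)
  reactions <- .fillReactionDefaults(reactions)
  if (length(stoichiometry) != nrow(reactions))
    stop("need one stoichiometry entry per reaction")
  if (is.null(names(stoichiometry)))
    names(stoichiometry) <- reactions$id
  bad <- setdiff(unique(unlist(lapply(stoichiometry, names))),
                 metabolites$id)
  if (length(bad)) {
    culprit <- reactions$id[vapply(stoichiometry, function(s)
      any(names(s) %in% bad), logical(1))][1]
    stop("reaction '", culprit, "' references undeclared metabolite(s): ",
         paste(bad, collapse = ", "))
  }
  i <- as.integer(unlist(lapply(stoichiometry, function(s)
    match(names(s), metabolites$id))) %||% integer(0))
  j <- rep(seq_along(stoichiometry),
           vapply(stoichiometry, length, integer(1)))
  x <- as.numeric(unlist(stoichiometry, use.names = FALSE) %||% numeric(0))
  S <- Matrix::sparseMatrix(i = i, j = j, x = x,
                            dims = c(nrow(metabolites), nrow(reactions)),
                            dimnames = list(metabolites$id, reactions$id))
  new("MetabolicModel", metabolites = metabolites, reactions = reactions,
      S = methods::as(S, "CsparseMatrix"), genes = .collectGenes(reactions$gpr))
}

.fillMetaboliteDefaults <- function(met) {
  met <- as.data.frame(met, stringsAsFactors = FALSE)
  n <- nrow(met)
  if (is.null(met$name)) met$name <- met$id
  if (is.null(met$formula)) met$formula <- rep(NA_character_, n)
  if (is.null(met$charge)) met$charge <- rep(0L, n)
  if (is.null(met$compartment)) met$compartment <- rep("c", n)
  met$charge[is.na(met$charge)] <- 0L
  rownames(met) <- NULL
  met[c("id", "name", "formula", "charge", "compartment")]
}

.fillReactionDefaults <- function(rxn) {
  rxn <- as.data.frame(rxn, stringsAsFactors = FALSE)
  n <- nrow(rxn)
  if (is.null(rxn$name)) rxn$name <- rxn$id
  if (is.null(rxn$gpr)) rxn$gpr <- rep("", n)
  rxn$gpr[is.na(rxn$gpr)] <- ""
  if (is.null(rxn$category)) rxn$category <- rep("metabolic", n)
  if (is.null(rxn$confidence)) rxn$confidence <- rep(NA_integer_, n)
  rownames(rxn) <- NULL
  rxn[c("id", "name", "lower", "upper", "gpr", "category", "confidence")]
}

.collectGenes <- function(gprs) {
  g <- unique(unlist(lapply(gprs, gprGenes)))
  if (is.null(g)) character(0) else sort(g)
}

## ---- accessors --------------------------------------------------------

#' @describeIn MetabolicModel metabolite table accessor
#' @param object,model a \code{MetabolicModel}
#' @export
setGeneric("metabolites", function(object) standardGeneric("metabolites"))
#' @export
setMethod("metabolites", "MetabolicModel", function(object) object@metabolites)

#' @describeIn MetabolicModel reaction table accessor
#' @export
setGeneric("reactions", function(object) standardGeneric("reactions"))
#' @export
setMethod("reactions", "MetabolicModel", function(object) object@reactions)

#' @describeIn MetabolicModel sparse stoichiometric matrix accessor
#' @export
setGeneric("stoichiometry", function(object) standardGeneric("stoichiometry"))
#' @export
setMethod("stoichiometry", "MetabolicModel", function(object) object@S)

#' @describeIn MetabolicModel gene id accessor
#' @export
setGeneric("modelGenes", function(object) standardGeneric("modelGenes"))
#' @export
setMethod("modelGenes", "MetabolicModel", function(object) object@genes)

#' Get or set reaction flux bounds
#'
#' @param object a \linkS4class{MetabolicModel}.
#' @param id reaction id(s); default all reactions.
#' @return \code{bounds()}: two-column matrix (lower, upper) with one row
#'   per requested reaction.
#' @export
setGeneric("bounds", function(object, id = NULL) standardGeneric("bounds"))
#' @export
setMethod("bounds", "MetabolicModel", function(object, id = NULL) {
  rxn <- object@reactions
  if (is.null(id)) id <- rxn$id
  idx <- .rxnIndex(object, id)
  cbind(lower = rxn$lower[idx], upper = rxn$upper[idx],
        deparse.level = 0) |>
    (\(m) { rownames(m) <- id; m })()
})

#' @rdname bounds
#' @param value numeric length-2 (applied to every \code{id}) or an
#'   n x 2 matrix of (lower, upper).
#' @export
setGeneric("bounds<-", function(object, id = NULL, value)
  standardGeneric("bounds<-"))
#' @export
setMethod("bounds<-", "MetabolicModel", function(object, id = NULL, value) {
  if (is.null(id)) id <- object@reactions$id
  idx <- .rxnIndex(object, id)
  value <- matrix(as.numeric(value), ncol = 2,
                  nrow = length(idx), byrow = is.null(dim(value)))
  if (any(value[, 1] > value[, 2] + 1e-12))
    stop("conflicting fixed bounds: lower > upper for ",
         paste(id[value[, 1] > value[, 2] + 1e-12], collapse = ", "))
  object@reactions$lower[idx] <- value[, 1]
  object@reactions$upper[idx] <- value[, 2]
  object
})

.rxnIndex <- function(model, id) {
  idx <- match(id, model@reactions$id)
  if (anyNA(idx))
    stop("unknown reaction id(s): ", paste(id[is.na(idx)], collapse = ", "))
  idx
}

.metIndex <- function(model, id) {
  idx <- match(id, model@metabolites$id)
  if (anyNA(idx))
    stop("unknown metabolite id(s): ", paste(id[is.na(idx)], collapse = ", "))
  idx
}

## ---- show methods -----------------------------------------------------

setMethod("show", "MetabolicModel", function(object) {
  st <- modelStatistics(object)
  cat("MetabolicModel with", st$reactions, "reactions,",
      st$metabolites, "metabolites,", st$genes, "genes\n")
  cat("  categories:",
      paste(names(st$byCategory), st$byCategory, sep = ":",
            collapse = "  "), "\n")
})

setMethod("show", "FluxSolution", function(object) {
  cat("FluxSolution (", object@status, ")\n", sep = "")
  if (object@status == "optimal")
    cat("  objective [", object@objectiveReaction, "] = ",
        format(object@objectiveValue, digits = 6), "\n", sep = "")
})

setMethod("show", "CellTypeConstraints", function(object) {
  cat("CellTypeConstraints:", object@name,
      if (object@relaxed) "(relaxed)" else "(strict)", "\n")
  cat("  carbon uptake:", object@carbonUptake, "mmol C/gDW/h;",
      "nitrogenase:", object@nitrogenaseFlux, "; PSII <=",
      object@psiiUpper, "\n")
  cat("  photons <=", object@photonBudget, "uE; maintenance >=",
      object@maintenanceAtp, "mmol ATP/gDW/h\n")
})

setMethod("show", "PopulationTrace", function(object) {
  n <- nrow(object@states)
  cat("PopulationTrace:", n, "steps, status:", object@status, "\n")
  if (n) {
    last <- object@states[n, ]
    cat("  final f_DZ =", format(last$f_DZ, digits = 4),
        " total X =", format(last$X_DZ + last$X_PA, digits = 4), "g/L\n")
  }
})

## ---- flux solution accessors -----------------------------------------

#' @describeIn solveFBA flux vector accessor
#' @export
setGeneric("fluxes", function(object) standardGeneric("fluxes"))
#' @export
setMethod("fluxes", "FluxSolution", function(object) object@fluxes)

#' @describeIn solveFBA objective value accessor
#' @export
setGeneric("objectiveValue", function(object) standardGeneric("objectiveValue"))
#' @export
setMethod("objectiveValue", "FluxSolution", function(object)
  object@objectiveValue)

#' @describeIn solveFBA solver status accessor
#' @export
setGeneric("solutionStatus", function(object) standardGeneric("solutionStatus"))
#' @export
setMethod("solutionStatus", "FluxSolution", function(object) object@status)

#' @describeIn simulatePopulation per-step state table accessor
#' @export
setGeneric("traceStates", function(object) standardGeneric("traceStates"))
#' @export
setMethod("traceStates", "PopulationTrace", function(object) object@states)

#' @describeIn simulatePopulation per-step allocation records accessor
#' @export
setGeneric("traceAllocations", function(object)
  standardGeneric("traceAllocations"))
#' @export
setMethod("traceAllocations", "PopulationTrace", function(object)
  object@allocations)

#' @describeIn simulatePopulation terminal status accessor
#' @export
setGeneric("traceStatus", function(object) standardGeneric("traceStatus"))
#' @export
setMethod("traceStatus", "PopulationTrace", function(object) object@status)
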